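test_that("MMSE staging matches the published cut-offs", {
  expect_equal(as.character(classify_severity(c(21, 20, 9), "3level")),
               c("Mild", "Moderate", "Severe"))
  expect_equal(as.character(classify_severity(c(30, 0), "3level")),
               c("Mild", "Severe"))
  expect_equal(as.character(classify_severity(27, "4level")), "VeryMild")
  expect_equal(as.character(classify_severity(26, "4level")), "Mild")
  expect_error(classify_severity(31), class = "admarkov_domain_error")
  expect_error(classify_severity(-1), class = "admarkov_domain_error")
})

test_that("staging is exhaustive and idempotent over the MMSE range", {
  for (scheme in c("3level", "4level")) {
    s1 <- classify_severity(0:30, scheme)
    expect_false(any(is.na(s1)))
    # idempotent under re-rounding of fractional inputs
    expect_equal(classify_severity(0:30 + 0.4, scheme), s1)
  }
})

make_dirty_registry <- function() {
  d <- function(x) as.Date(x)
  tibble::tribble(
    ~person_id, ~visit_date,     ~visit_type, ~age_at_visit, ~mmse, ~death_date,
    1L, d("2020-01-01"), "baseline", 70,   28L, as.Date(NA),
    1L, d("2020-04-01"), "followup", 70.2, 27L, as.Date(NA),  # 91 d: short interval
    1L, d("2021-01-01"), "followup", 71,   26L, as.Date(NA),
    2L, d("2020-01-01"), "baseline", 75,   28L, as.Date(NA),
    2L, d("2021-01-01"), "followup", 76,   25L, as.Date(NA),
    2L, d("2021-01-01"), "followup", 76,   24L, as.Date(NA),  # duplicate date
    3L, d("2020-01-01"), "followup", 80,   20L, as.Date(NA),  # no baseline
    3L, d("2021-01-01"), "followup", 81,   18L, as.Date(NA),
    4L, d("2020-01-01"), "baseline", 82,   27L, d("2020-06-01"),
    4L, d("2020-07-01"), "followup", 82.5, 26L, d("2020-06-01"), # after death
    5L, d("2020-06-01"), "baseline", 68,   29L, as.Date(NA),
    5L, d("2020-01-01"), "followup", 67.6, 30L, as.Date(NA),  # before baseline
    6L, as.Date(NA),     "baseline", 77,   22L, as.Date(NA),  # bad date
    6L, d("2020-06-01"), "followup", 77.4, 21L, as.Date(NA),  # -> no baseline
    7L, d("2020-01-01"), "baseline", 73,   NA,  as.Date(NA),  # person without MMSE
    7L, d("2021-01-01"), "followup", 74,   NA,  as.Date(NA)
  )
}

test_that("cleaning attributes each defect to exactly one rule", {
  cl <- clean_registry(make_dirty_registry())
  rep <- cl$report
  counts <- setNames(rep$n_rows, rep$rule)
  expect_equal(counts[["short_interval"]], 1L)
  expect_equal(counts[["duplicate_date"]], 1L)
  expect_equal(counts[["no_baseline"]], 3L)   # person 3 (2 rows) + person 6 followup
  expect_equal(counts[["after_death"]], 1L)
  expect_equal(counts[["before_baseline"]], 1L)
  expect_equal(counts[["bad_date"]], 1L)
  expect_equal(counts[["no_mmse"]], 2L)
  # accounting identity: kept + excluded = input rows
  expect_equal(attr(rep, "n_kept") + sum(rep$n_rows),
               nrow(make_dirty_registry()))
  expect_equal(nrow(cl$table), attr(rep, "n_kept"))
})

test_that("cleaning is idempotent and handles the empty table", {
  cl1 <- clean_registry(make_dirty_registry())
  cl2 <- clean_registry(cl1$table)
  expect_equal(sum(cl2$report$n_rows), 0L)
  expect_equal(nrow(cl2$table), nrow(cl1$table))

  empty <- make_dirty_registry()[0, ]
  cl0 <- clean_registry(empty)
  expect_equal(nrow(cl0$table), 0L)
  expect_true(all(cl0$report$n_rows == 0L))
})

test_that("injected defect counts are recovered exactly by the cleaner", {
  p <- generator_params(n_individuals = 300,
                        corrupt = list(short_interval = 5, duplicate_date = 4,
                                       after_death = 3, missing_mmse = 2))
  reg <- generate_registry(p, seed = 11)
  inj <- attr(reg, "injected")
  cl <- clean_registry(reg)
  counts <- setNames(cl$report$n_rows, cl$report$rule)
  persons <- setNames(cl$report$n_persons, cl$report$rule)
  expect_equal(counts[["short_interval"]], inj$short_interval)
  expect_equal(counts[["duplicate_date"]], inj$duplicate_date)
  expect_equal(counts[["after_death"]], inj$after_death)
  expect_equal(persons[["no_mmse"]], inj$missing_mmse)
  expect_equal(counts[["no_mmse"]], inj$missing_mmse_rows)
})

test_that("annual grid interpolation matches the linear oracle", {
  base <- as.Date("2020-01-01")
  # spec-style case: MMSE 28 at month 0, 20 at month 24 -> grid year 1 = 24
  ann <- annualize(c(base, base + round(2 * 365.25)), c(28, 20))
  y1 <- ann$mmse[ann$grid_year == 1]
  expect_equal(y1, 24, tolerance = 0.01)
  # visits exactly on anniversaries are reproduced without error
  dates <- base + c(0, 365.25, 730.5)
  ann2 <- annualize(dates, c(28, 25, 21))
  expect_equal(ann2$mmse, c(28, 25, 21))
  expect_equal(ann2$grid_year, c(0, 1, 2))
})

test_that("forward extrapolation is limited to three months", {
  base <- as.Date("2020-01-01")
  # last visit at month 10: grid year 1 reachable by <= 3-month extrapolation
  ann <- annualize(c(base, base + 304), c(28, 24))
  expect_true(1 %in% ann$grid_year)
  slope <- (24 - 28) / 304
  expect_equal(ann$mmse[ann$grid_year == 1], 24 + slope * (365.25 - 304),
               tolerance = 1e-6)
  # last visit at month 8: grid year 1 out of reach
  ann2 <- annualize(c(base, base + 243), c(28, 24))
  expect_false(1 %in% ann2$grid_year)
  # no backward extrapolation before the first measurement
  ann3 <- annualize(c(base + 200, base + 400), c(25, 24), baseline_date = base)
  expect_false(0 %in% ann3$grid_year)
  # single visit: baseline grid point only
  ann4 <- annualize(base, 26)
  expect_equal(ann4$grid_year, 0)
  expect_equal(ann4$mmse, 26)
})

test_that("interpolated values are clamped to the MMSE range", {
  base <- as.Date("2020-01-01")
  ann <- annualize(c(base, base + 330), c(3, 0))
  expect_true(all(ann$mmse >= 0 & ann$mmse <= 30))
})

test_that("consecutive grid states become transitions, death within a year is terminal", {
  base <- as.Date("2020-01-01")
  ann <- tibble::tibble(
    person_id = c(1L, 1L, 1L, 2L, 2L),
    grid_year = c(0L, 1L, 2L, 0L, 1L),
    mmse = c(28, 26, 15, 28, 27),
    age = c(70, 71, 72, 80, 81),
    death_date = as.Date(c(NA, NA, NA,
                           rep(base + round(365.25 + 180), 2))),
    baseline_date = rep(base, 5)
  )
  tr <- build_transitions(ann, scheme = "3level")
  p1 <- tr[tr$person_id == 1, ]
  expect_equal(as.character(p1$from_state), c("Mild", "Mild", "Moderate"))
  expect_equal(as.character(p1$to_state[1:2]), c("Mild", "Moderate"))
  expect_true(is.na(p1$to_state[3]))  # censored one year after last status
  p2 <- tr[tr$person_id == 2, ]
  expect_equal(as.character(p2$to_state), c("Mild", "Death"))
})

test_that("death more than a year after the last grid point is censoring", {
  base <- as.Date("2020-01-01")
  ann <- tibble::tibble(person_id = 1L, grid_year = 0L, mmse = 25,
                        age = 70, death_date = base + 500,
                        baseline_date = base)
  tr <- build_transitions(ann, scheme = "3level")
  expect_true(is.na(tr$to_state))
})

test_that("transition counts match brute-force enumeration on a clean cohort", {
  reg <- generate_registry(clean_gen_params(800), seed = 13)
  ann <- annualize_registry(clean_registry(reg)$table)
  tr <- build_transitions(ann, scheme = "3level")

  # independent enumeration, person by person
  expected <- 0L
  for (d in split(ann, ann$person_id)) {
    g <- sort(d$grid_year)
    pairs <- sum(diff(g) == 1)
    death <- 0L
    if (!is.na(d$death_date[1])) {
      t_last <- d$baseline_date[1] + max(g) * 365.25
      gap <- as.numeric(d$death_date[1] - t_last)
      # death counts only if the last point has no next grid status
      if (gap >= 0 && gap <= 365.25) death <- 1L
    }
    expected <- expected + pairs + death
  }
  expect_equal(sum(!is.na(tr$to_state)), expected)
})

test_that("transition counts decline with follow-up year", {
  reg <- generate_registry(dropout_gen_params(2000), seed = 17)
  tr <- build_transitions(annualize_registry(clean_registry(reg)$table),
                          scheme = "3level")
  obs <- tr[!is.na(tr$to_state), ]
  counts <- table(obs$grid_year)
  expect_true(all(diff(as.integer(counts)) <= 0))
})
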