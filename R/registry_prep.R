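FOUR_MONTHS_DAYS <- 365.25 / 3
THREE_MONTHS_DAYS <- 365.25 / 4
YEAR_DAYS <- 365.25

#' Clean raw registry records
#'
#' Applies the registry's error filters in a fixed, documented order so that
#' every removed row is attributed to exactly one rule:
#'
#' 1. `bad_date` — rows whose visit date is missing/unparseable;
#' 2. `no_baseline` — all rows of persons without a (dated) baseline
#'    assessment;
#' 3. `before_baseline` — follow-ups dated before the baseline visit;
#' 4. `after_death` — follow-ups dated after the recorded death date;
#' 5. `duplicate_date` — same-date rows within a person (first kept);
#' 6. `short_interval` — rows less than 4 months after the previous *kept*
#'    row of the same person;
#' 7. `no_mmse` — all rows of persons left without any MMSE value.
#'
#' Duplicates are attributed before the short-interval rule (a duplicate has
#' interval zero and would otherwise be swallowed by it); the kept set is the
#' same under either order. The function is idempotent.
#'
#' @param table A registry table (see [generate_registry()]). A `visit_type`
#'   column marking the baseline row is used if present; otherwise each
#'   person's earliest visit is taken as baseline.
#' @return A list with `table` (the cleaned registry, row order preserved)
#'   and `report` (tibble: `rule`, `n_rows`, `n_persons`), plus `n_kept`
#'   as an attribute of the report.
#' @export
clean_registry <- function(table) {
  tab <- as_tibble(table)
  if (!"visit_type" %in% names(tab)) {
    tab <- tab |>
      group_by(.data$person_id) |>
      mutate(visit_type = if_else(.data$visit_date == min(.data$visit_date) &
                                    !duplicated(.data$visit_date),
                                  "baseline", "followup")) |>
      ungroup()
  }
  rules <- c("bad_date", "no_baseline", "before_baseline", "after_death",
             "duplicate_date", "short_interval", "no_mmse")
  if (nrow(tab) == 0) {
    report <- tibble(rule = rules, n_rows = 0L, n_persons = 0L)
    attr(report, "n_kept") <- 0L
    out <- tab
    class(out) <- unique(c("registry_table", class(out)))
    return(list(table = out, report = report))
  }
  cnt_rows <- setNames(integer(length(rules)), rules)
  cnt_pers <- setNames(integer(length(rules)), rules)
  note <- function(rule, drop_idx, persons) {
    cnt_rows[[rule]] <<- cnt_rows[[rule]] + length(drop_idx)
    cnt_pers[[rule]] <<- cnt_pers[[rule]] + length(unique(persons))
  }

  n_in <- nrow(tab)
  keep <- rep(TRUE, n_in)

  bad <- which(is.na(tab$visit_date))
  note("bad_date", bad, tab$person_id[bad])
  keep[bad] <- FALSE

  has_base <- tab |>
    filter(keep) |>
    group_by(.data$person_id) |>
    summarise(ok = any(.data$visit_type == "baseline"), .groups = "drop")
  bad_persons <- has_base$person_id[!has_base$ok]
  idx <- which(keep & tab$person_id %in% bad_persons)
  note("no_baseline", idx, tab$person_id[idx])
  keep[idx] <- FALSE

  base_date <- tab |>
    filter(keep, .data$visit_type == "baseline") |>
    group_by(.data$person_id) |>
    summarise(base = min(.data$visit_date), .groups = "drop")
  bmap <- setNames(base_date$base, base_date$person_id)
  idx <- which(keep & tab$visit_date < bmap[as.character(tab$person_id)])
  note("before_baseline", idx, tab$person_id[idx])
  keep[idx] <- FALSE

  idx <- which(keep & !is.na(tab$death_date) & tab$visit_date > tab$death_date)
  note("after_death", idx, tab$person_id[idx])
  keep[idx] <- FALSE

  ord <- order(tab$person_id, tab$visit_date)
  kept_ord <- ord[keep[ord]]
  dup <- kept_ord[duplicated(data.frame(tab$person_id[kept_ord],
                                        tab$visit_date[kept_ord]))]
  note("duplicate_date", dup, tab$person_id[dup])
  keep[dup] <- FALSE

  # short interval vs previous kept row, per person, chronological
  short <- integer(0)
  for (idxp in split(ord[keep[ord]], tab$person_id[ord[keep[ord]]])) {
    last_kept <- tab$visit_date[idxp[1L]]
    for (j in idxp[-1L]) {
      if (as.numeric(tab$visit_date[j] - last_kept) < FOUR_MONTHS_DAYS) {
        short <- c(short, j)
      } else {
        last_kept <- tab$visit_date[j]
      }
    }
  }
  note("short_interval", short, tab$person_id[short])
  keep[short] <- FALSE

  any_mmse <- tab |>
    filter(keep) |>
    group_by(.data$person_id) |>
    summarise(ok = any(!is.na(.data$mmse)), .groups = "drop")
  bad_persons <- any_mmse$person_id[!any_mmse$ok]
  idx <- which(keep & tab$person_id %in% bad_persons)
  note("no_mmse", idx, tab$person_id[idx])
  keep[idx] <- FALSE

  report <- tibble(rule = rules, n_rows = unname(cnt_rows),
                   n_persons = unname(cnt_pers))
  attr(report, "n_kept") <- sum(keep)
  stopifnot(sum(keep) + sum(report$n_rows) == n_in)
  out <- tab[keep, , drop = FALSE]
  class(out) <- unique(c("registry_table", class(out)))
  list(table = out, report = report)
}

#' Interpolate one person's MMSE onto an annual grid
#'
#' Places MMSE on anniversaries of the baseline date: linear interpolation
#' between bracketing visits inside the observed span, and linear
#' extrapolation from the last two visits for at most 3 months past the last
#' visit. No backward extrapolation before the first MMSE measurement.
#' Values are clamped to `[0, 30]` and kept fractional (round before
#' staging).
#'
#' @param dates Visit dates (`Date`), strictly increasing.
#' @param mmse MMSE values at those visits (`NA` allowed; such visits are
#'   ignored for interpolation).
#' @param baseline_date Anchor of the annual grid; defaults to the first
#'   visit date.
#' @return A tibble with columns `grid_year` (0, 1, 2, ...) and `mmse`
#'   (fractional); grid points that cannot be covered are absent.
#' @export
annualize <- function(dates, mmse, baseline_date = min(dates)) {
  core <- annualize_core(as.numeric(dates - baseline_date), as.numeric(mmse))
  tibble(grid_year = core$grid_year, mmse = core$mmse)
}

#' Annualize a cleaned registry
#'
#' Applies [annualize()] per person (grid anchored at each person's baseline
#' visit) and carries through age and death information.
#'
#' @param table A cleaned registry table.
#' @return A tibble with columns `person_id`, `grid_year`, `mmse`
#'   (fractional), `age` (at the grid point), `death_date`, `baseline_date`.
#' @export
annualize_registry <- function(table) {
  tab <- as_tibble(table)
  parts <- split(seq_len(nrow(tab)), tab$person_id)
  has_vt <- "visit_type" %in% names(tab)
  res <- lapply(parts, function(idx) {
    dates <- tab$visit_date[idx]
    bd <- if (has_vt && any(tab$visit_type[idx] == "baseline")) {
      min(dates[tab$visit_type[idx] == "baseline"])
    } else min(dates)
    j <- idx[which.min(abs(as.numeric(dates - bd)))]
    base_age <- tab$age_at_visit[j] -
      as.numeric(tab$visit_date[j] - bd) / YEAR_DAYS
    ann <- annualize_core(as.numeric(dates - bd), as.numeric(tab$mmse[idx]))
    if (length(ann$grid_year) == 0) return(NULL)
    list(person_id = rep(tab$person_id[idx[1L]], length(ann$grid_year)),
         grid_year = ann$grid_year, mmse = ann$mmse,
         age = base_age + ann$grid_year,
         death_date = rep(tab$death_date[idx[1L]], length(ann$grid_year)),
         baseline_date = rep(bd, length(ann$grid_year)))
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    return(tibble(person_id = integer(), grid_year = integer(),
                  mmse = numeric(), age = numeric(),
                  death_date = as.Date(character()),
                  baseline_date = as.Date(character())))
  }
  tibble(person_id = unlist(lapply(res, `[[`, "person_id")),
         grid_year = unlist(lapply(res, `[[`, "grid_year")),
         mmse = unlist(lapply(res, `[[`, "mmse")),
         age = unlist(lapply(res, `[[`, "age")),
         death_date = as.Date(unlist(lapply(res, function(r)
           as.numeric(r$death_date))), origin = "1970-01-01"),
         baseline_date = as.Date(unlist(lapply(res, function(r)
           as.numeric(r$baseline_date))), origin = "1970-01-01"))
}

# core of annualize() on day offsets; returns plain lists (hot path)
annualize_core <- function(day_offset, mmse) {
  ok <- !is.na(mmse) & !is.na(day_offset)
  d <- day_offset[ok]
  m <- mmse[ok]
  if (length(d) == 0) return(list(grid_year = integer(), mmse = numeric()))
  o <- order(d)
  d <- d[o]; m <- m[o]
  max_reach <- max(d) + THREE_MONTHS_DAYS
  gmax <- floor(max_reach / YEAR_DAYS)
  if (gmax < 0) return(list(grid_year = integer(), mmse = numeric()))
  g <- 0:gmax
  tg <- g * YEAR_DAYS
  val <- rep(NA_real_, length(g))
  inside <- tg >= min(d) & tg <= max(d)
  if (any(inside) && length(d) >= 2) {
    val[inside] <- stats::approx(d, m, xout = tg[inside], ties = "ordered")$y
  } else if (any(inside)) {
    val[inside] <- m[1L]          # single visit landing on the grid
  }
  beyond <- tg > max(d) & tg <= max_reach
  if (any(beyond) && length(d) >= 2) {
    slope <- (m[length(m)] - m[length(m) - 1L]) / (d[length(d)] - d[length(d) - 1L])
    val[beyond] <- m[length(m)] + slope * (tg[beyond] - max(d))
  }
  keep <- !is.na(val)
  list(grid_year = g[keep], mmse = pmin(pmax(val[keep], 0), 30))
}

#' Build annualized state-to-state transitions
#'
#' Consecutive grid years become `(from_state -> to_state)` transitions with
#' the person's age at the from-point. A death within one year after a
#' person's last grid point becomes a transition to Death. Persons are
#' censored one year after their last available MMSE status: grid points with
#' neither a next status nor a death in the following year yield a row with
#' `to_state = NA` (censored), which the censoring model consumes.
#'
#' @param annualized Output of [annualize_registry()].
#' @param scheme Staging scheme passed to [classify_severity()].
#' @return A tibble with columns `person_id`, `grid_year`, `age`,
#'   `from_state`, `to_state` (severity level, `"Death"`, or `NA` when
#'   censored) and `weight` (1; replaced by IPCW downstream).
#' @export
build_transitions <- function(annualized, scheme = c("3level", "4level")) {
  scheme <- match.arg(scheme)
  lev <- c(severity_levels(scheme), "Death")
  ann <- annualized |> arrange(.data$person_id, .data$grid_year)
  n <- nrow(ann)
  if (n == 0) {
    return(tibble(person_id = integer(), grid_year = integer(),
                  age = numeric(),
                  from_state = factor(character(), levels = head(lev, -1L)),
                  to_state = factor(character(), levels = lev), weight = numeric()))
  }
  st <- as.character(classify_severity(ann$mmse, scheme))
  same_person <- c(ann$person_id[-1L] == ann$person_id[-n], FALSE)
  consecutive <- c(ann$grid_year[-1L] == ann$grid_year[-n] + 1L, FALSE)
  has_next <- same_person & consecutive
  to <- rep(NA_character_, n)
  to[has_next] <- st[which(has_next) + 1L]
  # death within one year after a person's last grid point
  is_last <- !same_person
  cand <- which(is_last & !has_next & !is.na(ann$death_date))
  if (length(cand)) {
    t_last <- ann$baseline_date[cand] + ann$grid_year[cand] * YEAR_DAYS
    dt <- as.numeric(ann$death_date[cand] - t_last)
    to[cand[dt >= 0 & dt <= YEAR_DAYS]] <- "Death"
  }
  tibble(person_id = ann$person_id, grid_year = ann$grid_year, age = ann$age,
         from_state = factor(st, levels = head(lev, -1L)),
         to_state = factor(to, levels = lev),
         weight = 1)
}
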