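#' @keywords internal
#' @noRd
round_half_up <- function(x, digits = 0) {
  # base round() is banker's rounding; staging and NNT use commercial half-up
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' @keywords internal
#' @noRd
stop_domain <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "admarkov_domain_error")
}

#' @keywords internal
#' @noRd
stop_param <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "admarkov_parameter_error")
}

#' @keywords internal
#' @noRd
check_prob <- function(x, name, open = FALSE) {
  bad <- if (open) any(x <= 0 | x >= 1) else any(x < 0 | x > 1)
  if (any(is.na(x)) || bad) {
    stop_domain("`%s` must be a probability in %s, got %s",
                name, if (open) "(0, 1)" else "[0, 1]",
                paste(format(x), collapse = ", "))
  }
  invisible(x)
}

#' Currency conversion constants (SEK 2016)
#'
#' Fixed exchange rates used when reporting costs in other currencies:
#' 1 US$ = 8.56 SEK and 1 EUR = 9.47 SEK. All internal accounting is in SEK.
#'
#' @format A named numeric vector with elements `SEK_per_USD` and `SEK_per_EUR`.
#' @export
currency_constants <- c(SEK_per_USD = 8.56, SEK_per_EUR = 9.47)

#' Convert SEK amounts to another currency
#'
#' @param sek Numeric vector of amounts in SEK (2016 price level).
#' @param to `"USD"` or `"EUR"`.
#' @return Numeric vector in the target currency.
#' @examples
#' sek_to(252843, "USD")
#' @export
sek_to <- function(sek, to = c("USD", "EUR")) {
  to <- match.arg(to)
  rate <- switch(to, USD = currency_constants[["SEK_per_USD"]],
                 EUR = currency_constants[["SEK_per_EUR"]])
  sek / rate
}
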