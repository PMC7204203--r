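#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero, the
#' convention used in analytical-chemistry reporting (so 0.8125 -> 0.813),
#' unlike [base::round()]'s round-half-to-even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(0.8125, 0.0005), 3)
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# internal argument checks ------------------------------------------------

stop_if_not_positive <- function(..., .allow_zero = FALSE) {
  args <- list(...)
  nms <- names(args)
  for (i in seq_along(args)) {
    v <- args[[i]]
    if (!is.numeric(v) || anyNA(v) ||
        (if (.allow_zero) any(v < 0) else any(v <= 0))) {
      stop(sprintf("`%s` must be %s numeric, got: %s",
                   nms[i], if (.allow_zero) "a non-negative" else "a positive",
                   paste(utils::head(v, 3), collapse = ", ")),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}
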