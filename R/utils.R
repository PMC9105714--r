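#' Round half away from zero
#'
#' Deterministic decimal rounding in which ties (a trailing 5 at the last
#' kept digit) move away from zero, e.g. `-5.55 -> -5.6` at one decimal.
#' Used for all table-style reporting in the package so that printed values
#' are reproducible across platforms (base [round()] uses round-half-even
#' and is sensitive to binary representation).
#'
#' @param x numeric vector.
#' @param digits number of decimal places to keep.
#' @return numeric vector rounded to `digits` decimals.
#' @examples
#' round_half_away(-5.55, 1) # -5.6
#' round_half_away(0.285, 2) # 0.29
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  # small guard absorbs binary representation error just below a tie
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Derive a stage-specific child seed
#'
#' All randomness in a pipeline run flows from one configuration seed.
#' Stage-level generators receive a child seed derived deterministically
#' from the run seed and the stage name, so stages can be re-run in
#' isolation without replaying the whole pipeline.
#'
#' @param seed integer run seed.
#' @param stage character stage name.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) + h * 7919) %% (2^31 - 1))
}

# internal: stop with a classed condition
.gs_abort <- function(msg, class) {
  rlang::abort(msg, class = c(class, "gagstack_error"))
}

# internal: check scalar positivity
.check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0) {
    .gs_abort(sprintf("`%s` must be a single positive number, got %s",
                      name, paste(format(x), collapse = ", ")),
              "gagstack_bad_argument")
  }
  invisible(x)
}
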