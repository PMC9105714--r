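#' Sulfation-dependence statistic D
#'
#' Computes `D = n_MB * t / n_SO3`, the number of dyes bound simultaneously
#' to the chain, weighted by the time fraction spent at that count, per
#' sulfate group. D is the package's measure of how strongly simultaneous
#' dye binding depends on the chain's sulfate inventory; it is undefined
#' for a chain with no sulfates (fully desulfated heparin), which is
#' reported as an undefined flag rather than a number.
#'
#' @param n_mb integer count of simultaneously bound dyes (>= 0).
#' @param t time fraction in `[0, 1]` spent at that count.
#' @param n_so3 integer number of sulfate groups in the chain (>= 0).
#' @return one-row tibble: `n_mb`, `t`, `n_so3`, `D` (unrounded, `NA` when
#'   undefined), `D_rounded` (2 decimals, half away from zero), `defined`.
#' @examples
#' compute_D(10, 0.42, 15) # D = 0.28
#' compute_D(7, 0.5, 0)    # undefined (no sulfates)
#' @export
compute_D <- function(n_mb, t, n_so3) {
  stopifnot(is.numeric(n_mb), n_mb >= 0, is.numeric(n_so3), n_so3 >= 0)
  if (!is.numeric(t) || is.na(t) || t < 0 || t > 1) {
    .gs_abort(sprintf("`t` must be a fraction in [0, 1], got %s", format(t)),
              "gagstack_bad_argument")
  }
  defined <- n_so3 > 0
  D <- if (defined) n_mb * t / n_so3 else NA_real_
  tibble::tibble(
    n_mb = as.integer(n_mb), t = t, n_so3 = as.integer(n_so3),
    D = D,
    D_rounded = if (defined) round_half_away(D, 2) else NA_real_,
    defined = defined)
}

#' Assemble the sulfation-dependence table
#'
#' One row per GAG preset with the simultaneous-binder count, sulfate
#' inventory, time fraction and D statistic — the cross-preset comparison
#' table of the analysis.
#'
#' @param summaries named list (names = preset names) of
#'   [binding_summary()] objects, or a tibble with columns `preset`,
#'   `n_mb`, `t`.
#' @param chains optional named list of [build_gag()] chains supplying
#'   `n_so3`; by default chains are built at dp = 10 from the preset names.
#' @param dp chain length used when building default chains.
#' @return tibble: `preset`, `n_mb`, `n_so3`, `t`, `D`, `D_rounded`,
#'   `defined`. For presets without sulfates `t` is carried through but `D`
#'   is `NA` (undefined).
#' @export
d_table <- function(summaries, chains = NULL, dp = 10) {
  if (inherits(summaries, "data.frame")) {
    base <- tibble::as_tibble(summaries)[, c("preset", "n_mb", "t")]
  } else {
    stopifnot(is.list(summaries), !is.null(names(summaries)))
    base <- purrr::imap_dfr(summaries, function(s, nm) {
      tibble::tibble(preset = nm, n_mb = s$n_mb, t = s$t)
    })
  }
  if (anyDuplicated(base$preset)) {
    .gs_abort("presets in `summaries` must be unique", "gagstack_bad_argument")
  }
  n_so3 <- vapply(base$preset, function(p) {
    if (!is.null(chains) && p %in% names(chains)) n_sulfates(chains[[p]])
    else n_sulfates(build_gag(p, dp))
  }, numeric(1))
  purrr::pmap_dfr(list(base$preset, base$n_mb, base$t, n_so3),
                  function(p, n, t, s) {
                    dplyr::mutate(compute_D(n, t, s), preset = p, .before = 1)
                  })
}
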