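#' Dye-to-site distance time series
#'
#' For every frame, dye and anionic site, the distance between the site's
#' anchor atom (sulfate sulfur or carboxyl carbon) and the nearer of the
#' dye's two terminal dimethylamino nitrogens — the atoms that carry the
#' most positive charge of the cation and anchor the electrostatic contact.
#'
#' @param traj an [mb_trajectory()] containing a GAG chain.
#' @param frames frames to analyze (default all).
#' @return tibble with columns `frame`, `mb_id`, `site_id`, `site_type`,
#'   `residue_index`, `distance` (Angstrom).
#' @export
mb_site_distances <- function(traj, frames = NULL) {
  stopifnot(inherits(traj, "mb_trajectory"))
  rows <- .traj_rows(traj)
  if (!length(rows$sites)) {
    .gs_abort("trajectory has no anionic sites (no GAG chain present)",
              "gagstack_no_gag")
  }
  frames <- frames %||% seq_len(traj$n_frames)
  ids <- mb_ids(traj)
  topo <- traj$topology
  site_info <- topo[rows$sites, c("atom_label", "site_type", "residue_index")]
  site_info$site_id <- as.integer(sub("^A", "", site_info$atom_label))
  M <- as.matrix(traj$coords[, c("x", "y", "z")])
  n_atoms <- traj$n_atoms
  n_rows_flat <- unlist(rows$mb_n, use.names = FALSE)

  purrr::map_dfr(frames, function(f) {
    base <- (f - 1) * n_atoms
    anchors <- M[base + rows$sites, , drop = FALSE]
    npos <- M[base + n_rows_flat, , drop = FALSE]
    dmat <- .cross_dist(npos, anchors)           # (2 * n_mb) x n_sites
    odd <- seq(1, nrow(dmat), by = 2)
    dmin <- pmin(dmat[odd, , drop = FALSE], dmat[odd + 1, , drop = FALSE])
    tibble::tibble(
      frame = f,
      mb_id = rep(ids, times = ncol(dmin)),
      site_id = rep(site_info$site_id, each = length(ids)),
      site_type = rep(site_info$site_type, each = length(ids)),
      residue_index = rep(site_info$residue_index, each = length(ids)),
      distance = as.vector(dmin))
  })
}

#' Per-site-type contact fractions
#'
#' The fraction of simulation time (percent of frames) during which at
#' least one dye has a terminal nitrogen strictly below `cutoff` of an
#' anchor of each site type. A secondary per-pair occupancy — the mean,
#' over all (dye, site) pairs of the type, of each pair's own sub-cutoff
#' time fraction — is reported alongside, since summary conventions differ
#' between studies. Site types absent from the chain get `NA` (rendered as
#' dashes in table output).
#'
#' @param traj an [mb_trajectory()] containing a GAG chain.
#' @param cutoff contact distance cutoff in Angstrom (default 8).
#' @return a tibble of class `contact_table`: `site_type` (five canonical
#'   types), `n_sites`, `fraction_pct`, `pair_occupancy_pct`; attribute
#'   `cutoff`.
#' @export
contact_fractions <- function(traj, cutoff = 8) {
  .check_positive(cutoff, "cutoff")
  d <- mb_site_distances(traj)
  per_type <- purrr::map_dfr(site_type_levels(), function(ty) {
    dt <- d[d$site_type == ty, ]
    n_sites <- length(unique(dt$site_id))
    if (!nrow(dt)) {
      return(tibble::tibble(site_type = ty, n_sites = 0L,
                            fraction_pct = NA_real_,
                            pair_occupancy_pct = NA_real_))
    }
    frame_hit <- tapply(dt$distance < cutoff, dt$frame, any)
    pair_occ <- tapply(dt$distance < cutoff,
                       paste(dt$mb_id, dt$site_id), mean)
    tibble::tibble(site_type = ty, n_sites = n_sites,
                   fraction_pct = 100 * mean(frame_hit),
                   pair_occupancy_pct = 100 * mean(pair_occ))
  })
  structure(per_type, cutoff = cutoff,
            class = c("contact_table", class(per_type)))
}

#' Per-dye bound flags and per-frame simultaneous bound counts
#'
#' A dye is bound in a frame when any anionic site of any type lies
#' strictly within `cutoff` of one of its terminal nitrogens.
#'
#' @inheritParams contact_fractions
#' @return `bound_flags()`: tibble `frame`, `mb_id`, `bound`;
#'   `bound_counts()`: tibble `frame`, `n_bound`.
#' @export
bound_flags <- function(traj, cutoff = 8) {
  .check_positive(cutoff, "cutoff")
  d <- mb_site_distances(traj)
  d |>
    dplyr::summarise(bound = any(.data$distance < cutoff),
                     .by = c("frame", "mb_id"))
}

#' @rdname bound_flags
#' @export
bound_counts <- function(traj, cutoff = 8) {
  bound_flags(traj, cutoff) |>
    dplyr::summarise(n_bound = sum(.data$bound), .by = "frame")
}

#' Simultaneous-binding summary
#'
#' Summarizes how many dyes interact with the GAG at the same time:
#' `n_mb` is the maximum simultaneous bound count observed over the
#' trajectory and `t` the fraction of frames at that count. Because the
#' convention (frames at exactly the count, at least the count, or episode
#' lengths) is not unique, the full distribution of bound counts over
#' frames is always carried along so alternative summaries can be read off.
#'
#' @inheritParams contact_fractions
#' @return an object of class `binding_summary`: list with `n_mb`, `t`,
#'   `no_binding` flag, `distribution` (tibble: n_bound, n_frames,
#'   fraction, fraction_at_least), `mb_count`, `n_frames`, `cutoff`.
#' @export
binding_summary <- function(traj, cutoff = 8) {
  counts <- bound_counts(traj, cutoff)
  total_frames <- nrow(counts)
  dist <- counts |>
    dplyr::count(.data$n_bound, name = "n_frames") |>
    dplyr::arrange(.data$n_bound) |>
    dplyr::mutate(fraction = .data$n_frames / total_frames,
                  fraction_at_least = rev(cumsum(rev(.data$fraction))))
  n_mb <- max(counts$n_bound)
  structure(
    list(n_mb = as.integer(n_mb),
         t = dist$fraction[dist$n_bound == n_mb],
         no_binding = n_mb == 0,
         distribution = dist,
         mb_count = length(mb_ids(traj)),
         n_frames = total_frames, cutoff = cutoff),
    class = "binding_summary")
}

#' @export
print.binding_summary <- function(x, ...) {
  cat(sprintf("<binding_summary> n_MB = %d, t = %.3f over %d frames%s\n",
              x$n_mb, x$t, x$n_frames,
              if (x$no_binding) " (no binding observed)" else ""))
  invisible(x)
}

#' @rdname binding_summary
#' @param x a `binding_summary` object.
#' @param ... unused.
#' @export
tidy.binding_summary <- function(x, ...) x$distribution

#' @rdname binding_summary
#' @export
glance.binding_summary <- function(x, ...) {
  tibble::tibble(n_mb = x$n_mb, t = x$t, no_binding = x$no_binding,
                 mb_count = x$mb_count, n_frames = x$n_frames,
                 cutoff = x$cutoff)
}

#' Chain bending ratio
#'
#' Per-frame end-to-end to contour-length ratio of the GAG backbone (the
#' contour is the polyline through consecutive backbone beads). The ratio
#' is 1 for a fully extended chain and decreases as the chain bends; a
#' semicircular arc approaches 2/pi.
#'
#' @param traj an [mb_trajectory()] containing a GAG chain.
#' @return tibble with columns `frame` and `ratio`.
#' @export
chain_bending <- function(traj) {
  stopifnot(inherits(traj, "mb_trajectory"))
  rows <- .traj_rows(traj)
  if (length(rows$backbone) < 2) {
    .gs_abort("chain bending needs at least 2 backbone beads", "gagstack_no_gag")
  }
  M <- as.matrix(traj$coords[, c("x", "y", "z")])
  n_atoms <- traj$n_atoms
  purrr::map_dfr(seq_len(traj$n_frames), function(f) {
    bb <- M[(f - 1) * n_atoms + rows$backbone, , drop = FALSE]
    seg <- sqrt(rowSums(diff(bb)^2))
    ee <- sqrt(sum((bb[nrow(bb), ] - bb[1, ])^2))
    tibble::tibble(frame = f, ratio = ee / sum(seg))
  })
}
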