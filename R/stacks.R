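#' Detect pi-pi stacks of dye molecules
#'
#' Builds, for each frame, the stacking graph over the dye molecules: an
#' edge joins two dyes when their mean inter-plane distance is at most
#' `d_max`, the angle between their ring normals (taken modulo 180 degrees)
#' is at most `angle_max`, and the in-plane centroid offset is at most
#' `lateral_max`. Stacks are the connected components of size >= 2; within
#' a stack the members are ordered along the mean stack normal (ties broken
#' by molecule id) and the mutual orientation of each consecutive pair is
#' classified from the long axes.
#'
#' The defaults accept face-to-face stacks at the canonical ~3.7 Angstrom
#' spacing with thermal wobble while excluding T-shaped and edge-on
#' contacts; all three thresholds are exposed.
#'
#' @param traj an [mb_trajectory()].
#' @param d_max maximum mean inter-plane distance (Angstrom).
#' @param angle_max maximum angle between ring normals (degrees).
#' @param lateral_max maximum in-plane centroid offset (Angstrom).
#' @param frames frames to analyze (default all).
#' @return tibble with one row per detected stack: `frame`, `stack_id`
#'   (1-based within frame), `size`, `members` (list of molecule ids,
#'   ordered along the stack), `mean_spacing` (Angstrom, mean inter-plane
#'   distance of consecutive members) and `orientations` (list of
#'   `"parallel"`/`"antiparallel"` flags, length `size - 1`). Frames with
#'   no stacks contribute no rows.
#' @export
detect_stacks <- function(traj, d_max = 4.5, angle_max = 30,
                          lateral_max = 3.0, frames = NULL) {
  stopifnot(inherits(traj, "mb_trajectory"))
  .check_positive(d_max, "d_max")
  .check_positive(angle_max, "angle_max")
  .check_positive(lateral_max, "lateral_max")
  frames <- frames %||% seq_len(traj$n_frames)
  rows <- .traj_rows(traj)
  ids <- mb_ids(traj)
  if (length(ids) < 1) .gs_abort("trajectory contains no dyes", "gagstack_bad_trajectory")
  M <- as.matrix(traj$coords[, c("x", "y", "z")])
  n_atoms <- traj$n_atoms

  out <- purrr::map_dfr(frames, function(f) {
    base <- (f - 1) * n_atoms
    geo <- .frame_mb_geometry(M, base, rows, ids)
    comp <- .stack_components(geo, d_max, angle_max, lateral_max)
    if (!length(comp)) return(NULL)
    purrr::imap_dfr(comp, function(members, k) {
      ordm <- .order_stack(members, geo)
      sp <- vapply(seq_len(length(ordm) - 1), function(i)
        .pair_interplane(geo, ordm[i], ordm[i + 1]), numeric(1))
      ori <- vapply(seq_len(length(ordm) - 1), function(i)
        classify_orientation(geo$npos[[ordm[i]]], geo$npos[[ordm[i + 1]]]),
        character(1))
      tibble::tibble(frame = f, stack_id = as.integer(k),
                     size = length(ordm),
                     members = list(ids[ordm]),
                     mean_spacing = mean(sp),
                     orientations = list(ori))
    })
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(frame = integer(0), stack_id = integer(0),
                          size = integer(0), members = list(),
                          mean_spacing = numeric(0), orientations = list())
  }
  attr(out, "mb_count") <- length(ids)
  attr(out, "n_frames") <- traj$n_frames
  out
}

# per-frame dye geometry: ring plane fits and terminal-N coordinates
.frame_mb_geometry <- function(M, base, rows, ids) {
  planes <- lapply(ids, function(id) {
    fit_ring_plane(M[base + rows$mb_ring[[id]], , drop = FALSE])
  })
  list(
    ctr = t(vapply(planes, `[[`, numeric(3), "centroid")),
    nrm = t(vapply(planes, `[[`, numeric(3), "normal")),
    npos = lapply(ids, function(id) M[base + rows$mb_n[[id]], , drop = FALSE])
  )
}

# stacking criterion for one pair; returns the three geometric measures
.pair_geometry <- function(geo, i, j) {
  d <- geo$ctr[j, ] - geo$ctr[i, ]
  rc2 <- sum(d^2)
  ipl <- (abs(sum(d * geo$nrm[i, ])) + abs(sum(d * geo$nrm[j, ]))) / 2
  cosang <- min(abs(sum(geo$nrm[i, ] * geo$nrm[j, ])), 1)
  list(interplane = ipl,
       angle = acos(cosang) * 180 / pi,
       lateral = sqrt(max(rc2 - ipl^2, 0)))
}

.pair_interplane <- function(geo, i, j) .pair_geometry(geo, i, j)$interplane

# connected components of the stacking graph (components of size >= 2)
.stack_components <- function(geo, d_max, angle_max, lateral_max) {
  n <- nrow(geo$ctr)
  if (n < 2) return(list())
  edges <- integer(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      g <- .pair_geometry(geo, i, j)
      if (g$interplane <= d_max && g$angle <= angle_max &&
          g$lateral <= lateral_max) {
        edges <- c(edges, i, j)
      }
    }
  }
  if (!length(edges)) return(list())
  gr <- igraph::graph_from_edgelist(matrix(edges, ncol = 2, byrow = TRUE),
                                    directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0, n - igraph::vcount(gr)))
  mem <- igraph::components(gr)$membership
  comp <- split(seq_len(n), mem)
  comp <- comp[vapply(comp, length, integer(1)) >= 2]
  # deterministic order: by smallest member id
  comp[order(vapply(comp, min, integer(1)))]
}

# order members along the mean stack normal; ties broken by molecule index
.order_stack <- function(members, geo) {
  ref <- geo$nrm[members[1], ]
  aligned <- t(vapply(members, function(m) {
    v <- geo$nrm[m, ]
    if (sum(v * ref) < 0) -v else v
  }, numeric(3)))
  axis <- colMeans(aligned)
  axis <- axis / sqrt(sum(axis^2))
  proj <- geo$ctr[members, , drop = FALSE] %*% axis
  members[order(proj, members)]
}

#' Stack statistics over a trajectory
#'
#' Summarizes [detect_stacks()] output over all frames: the per-frame stack
#' size histogram (singletons included, so a fully dispersed system has all
#' its mass at size 1), the mean inter-plane spacing between adjacent
#' stacked molecules — reported both over all adjacent pairs and over
#' dimers only, since the two averages can differ in mixed populations —
#' and parallel/antiparallel orientation counts.
#'
#' @inheritParams detect_stacks
#' @return an object of class `stack_stats` with elements `records` (the
#'   [detect_stacks()] tibble), `size_histogram` (tibble: size, n_per_frame,
#'   fraction of molecules), `mean_spacing` (all adjacent pairs),
#'   `mean_spacing_dimers`, `orientation_counts` and `n_frames`.
#' @export
stack_statistics <- function(traj, d_max = 4.5, angle_max = 30,
                             lateral_max = 3.0) {
  stopifnot(inherits(traj, "mb_trajectory"))
  if (traj$n_frames < 1) {
    .gs_abort("trajectory has no frames", "gagstack_bad_trajectory")
  }
  rec <- detect_stacks(traj, d_max, angle_max, lateral_max)
  mb_count <- length(mb_ids(traj))
  n_frames <- traj$n_frames

  stacked_sizes <- if (nrow(rec)) rec$size else integer(0)
  n_singletons <- n_frames * mb_count - sum(stacked_sizes)
  sizes <- c(rep(1L, n_singletons), stacked_sizes)
  # histogram over component sizes, averaged per frame
  hist <- tibble::tibble(size = sizes) |>
    dplyr::count(.data$size) |>
    dplyr::mutate(n_per_frame = .data$n / n_frames,
                  molecule_fraction = .data$size * .data$n /
                    (n_frames * mb_count)) |>
    dplyr::select("size", "n_per_frame", "molecule_fraction")

  all_sp <- if (nrow(rec)) {
    rep(rec$mean_spacing, rec$size - 1)  # weight by number of adjacent pairs
  } else numeric(0)
  dim_sp <- if (nrow(rec)) rec$mean_spacing[rec$size == 2] else numeric(0)
  ori <- unlist(if (nrow(rec)) rec$orientations else character(0))

  structure(
    list(records = rec,
         size_histogram = hist,
         mean_spacing = if (length(all_sp)) mean(all_sp) else NA_real_,
         mean_spacing_dimers = if (length(dim_sp)) mean(dim_sp) else NA_real_,
         orientation_counts = tibble::tibble(
           orientation = c("parallel", "antiparallel", "indeterminate"),
           n = c(sum(ori == "parallel"), sum(ori == "antiparallel"),
                 sum(ori == "indeterminate"))),
         n_frames = n_frames, mb_count = mb_count),
    class = "stack_stats")
}

#' @export
print.stack_stats <- function(x, ...) {
  cat(sprintf("<stack_stats> %d frames, %d dyes\n", x$n_frames, x$mb_count))
  cat(sprintf("  mean adjacent spacing: %s A (dimers only: %s A)\n",
              format(x$mean_spacing, digits = 4),
              format(x$mean_spacing_dimers, digits = 4)))
  modal <- x$size_histogram$size[which.max(x$size_histogram$n_per_frame)]
  cat(sprintf("  modal component size: %d\n", modal))
  invisible(x)
}

#' @rdname stack_statistics
#' @param x a `stack_stats` object.
#' @param ... unused.
#' @export
tidy.stack_stats <- function(x, ...) {
  if (!nrow(x$records)) return(x$records)
  x$records |>
    dplyr::mutate(members = vapply(.data$members, paste, character(1),
                                   collapse = ","),
                  orientations = vapply(.data$orientations, function(o)
                    paste(substr(o, 1, 1), collapse = ""), character(1)))
}

#' @rdname stack_statistics
#' @export
glance.stack_stats <- function(x, ...) {
  tibble::tibble(
    n_frames = x$n_frames, mb_count = x$mb_count,
    mean_spacing = x$mean_spacing,
    mean_spacing_dimers = x$mean_spacing_dimers,
    modal_size = x$size_histogram$size[which.max(x$size_histogram$n_per_frame)],
    parallel = x$orientation_counts$n[1],
    antiparallel = x$orientation_counts$n[2])
}
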