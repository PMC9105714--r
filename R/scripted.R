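#' Scripted synthetic trajectories
#'
#' Scripted mode generates trajectories whose analysis-level properties are
#' known exactly by construction: which dyes are bound to the GAG in which
#' frames, how they are partitioned into stacks, the inter-plane spacing and
#' the parallel/antiparallel pattern within each stack. These trajectories
#' stand in for all-atom MD production runs so that every analysis stage can
#' be verified against ground truth.
#'
#' A script is a tibble with one row per (frame, dye): columns `frame`,
#' `mb_id` (integer), `bound` (logical), `stack_id` (integer or `NA` for
#' singletons), `stack_pos` (1-based position along the stack axis),
#' `orientation` (`"parallel"`/`"antiparallel"` of each member relative to
#' the previous one; `NA` for the first member and for singletons).
#' All members of one stack must share the same `bound` flag.
#'
#' @param n_frames number of frames.
#' @param mb_count number of dye molecules.
#' @param gag_preset GAG preset name, or `NULL` for a GAG-free box.
#' @param script script tibble as described above (see [script_stacks()],
#'   [script_bound_fraction()], [script_singletons()]).
#' @param spacing target inter-plane spacing within stacks (Angstrom).
#' @param bound_distance distance from the inner terminal nitrogen of a
#'   bound singleton to its assigned anionic-site anchor (Angstrom).
#' @param site_type preferred site type for bound placements (`NULL`: any).
#' @param dp chain length passed to [build_gag()].
#' @param seed integer seed recorded with the trajectory (scripted
#'   placement is deterministic; the seed matters only for provenance).
#' @return an object of class `mb_scenario`.
#' @export
scripted_scenario <- function(n_frames, mb_count = 10, gag_preset = NULL,
                              script, spacing = 3.7, bound_distance = 4.0,
                              site_type = NULL, dp = 10, seed = 1L) {
  .check_positive(spacing, "spacing")
  .check_positive(bound_distance, "bound_distance")
  script <- tibble::as_tibble(script)
  .validate_script(script, n_frames, mb_count, is.null(gag_preset))
  structure(
    list(n_frames = as.integer(n_frames), mb_count = as.integer(mb_count),
         gag_preset = gag_preset, script = script, spacing = spacing,
         bound_distance = bound_distance, site_type = site_type,
         dp = dp, seed = as.integer(seed)),
    class = "mb_scenario")
}

.validate_script <- function(script, n_frames, mb_count, gag_free) {
  need <- c("frame", "mb_id", "bound", "stack_id", "stack_pos", "orientation")
  if (!all(need %in% names(script))) {
    .gs_abort(paste("script must have columns", paste(need, collapse = ", ")),
              "gagstack_bad_script")
  }
  key <- paste(script$frame, script$mb_id)
  if (anyDuplicated(key) ||
      nrow(script) != n_frames * mb_count ||
      !setequal(unique(script$frame), seq_len(n_frames)) ||
      !setequal(unique(script$mb_id), seq_len(mb_count))) {
    .gs_abort("script must contain every (frame, mb_id) pair exactly once",
              "gagstack_bad_script")
  }
  if (gag_free && any(script$bound)) {
    .gs_abort("script marks dyes bound but no GAG preset is set",
              "gagstack_bad_script")
  }
  for (f in unique(script$frame[!is.na(script$stack_id)])) {
    fr <- script[script$frame == f & !is.na(script$stack_id), ]
    for (s in unique(fr$stack_id)) {
      g <- fr[fr$stack_id == s, ]
      if (nrow(g) < 2 || !setequal(g$stack_pos, seq_len(nrow(g)))) {
        .gs_abort(sprintf(
          "frame %d stack %d: stack_pos must be 1..size with size >= 2", f, s),
          "gagstack_bad_script")
      }
      if (length(unique(g$bound)) != 1) {
        .gs_abort(sprintf(
          "frame %d stack %d: members of one stack must share the bound flag",
          f, s), "gagstack_bad_script")
      }
      if (any(is.na(g$orientation[g$stack_pos > 1])) ||
          !is.na(g$orientation[g$stack_pos == 1])) {
        .gs_abort(sprintf(
          "frame %d stack %d: orientation must be NA for position 1 and set otherwise",
          f, s), "gagstack_bad_script")
      }
    }
  }
  invisible(script)
}

#' All-singleton script (no stacks, nothing bound)
#' @inheritParams scripted_scenario
#' @return script tibble.
#' @export
script_singletons <- function(n_frames, mb_count) {
  tidyr::expand_grid(frame = seq_len(n_frames), mb_id = seq_len(mb_count)) |>
    dplyr::mutate(bound = FALSE, stack_id = NA_integer_,
                  stack_pos = NA_integer_, orientation = NA_character_)
}

#' Persistent-stack script
#'
#' Assigns the first `sum(sizes)` dyes to stacks of the given sizes, held
#' for every frame; remaining dyes are free singletons.
#'
#' @inheritParams scripted_scenario
#' @param sizes integer vector of stack sizes (each >= 2).
#' @param orientations either a single string (`"parallel"` or
#'   `"antiparallel"`) applied to every consecutive pair, or a list of
#'   character vectors, one per stack, of length `size - 1`.
#' @param bound logical: are the stacks in contact with the GAG?
#' @return script tibble.
#' @export
script_stacks <- function(n_frames, sizes, mb_count = sum(sizes),
                          orientations = "antiparallel", bound = FALSE) {
  stopifnot(all(sizes >= 2), sum(sizes) <= mb_count)
  if (!is.list(orientations)) {
    orientations <- lapply(sizes, function(s) rep(orientations, s - 1))
  }
  stopifnot(length(orientations) == length(sizes))
  rows <- list()
  mb <- 1L
  for (k in seq_along(sizes)) {
    s <- sizes[k]
    rows[[k]] <- tibble::tibble(
      mb_id = mb:(mb + s - 1L), bound = bound, stack_id = k,
      stack_pos = seq_len(s),
      orientation = c(NA_character_, orientations[[k]]))
    mb <- mb + s
  }
  fixed <- dplyr::bind_rows(
    dplyr::bind_rows(rows),
    if (mb <= mb_count) tibble::tibble(
      mb_id = mb:mb_count, bound = FALSE, stack_id = NA_integer_,
      stack_pos = NA_integer_, orientation = NA_character_))
  tidyr::expand_grid(frame = seq_len(n_frames), fixed)
}

#' Bound-fraction script
#'
#' Realizes a known simultaneous-binding time fraction: in the first
#' `round(fraction * n_frames)` frames, dyes `1..n_bound` are bound (as
#' singletons, each at its own anionic site); in the remaining frames only
#' `baseline_bound` dyes stay bound. With `baseline_bound < n_bound` the
#' maximum simultaneous count is `n_bound` and its time fraction is exactly
#' `fraction` (up to frame rounding).
#'
#' @inheritParams scripted_scenario
#' @param fraction target fraction of frames at the full bound count.
#' @param n_bound number of dyes bound in the high-count frames.
#' @param baseline_bound number bound in the remaining frames.
#' @return script tibble.
#' @export
script_bound_fraction <- function(n_frames, mb_count, fraction,
                                  n_bound = mb_count,
                                  baseline_bound = max(0L, n_bound - 1L)) {
  stopifnot(fraction >= 0, fraction <= 1, n_bound <= mb_count,
            baseline_bound <= n_bound)
  k <- as.integer(round(fraction * n_frames))
  tidyr::expand_grid(frame = seq_len(n_frames), mb_id = seq_len(mb_count)) |>
    dplyr::mutate(
      bound = ifelse(.data$frame <= k, .data$mb_id <= n_bound,
                     .data$mb_id <= baseline_bound),
      stack_id = NA_integer_, stack_pos = NA_integer_,
      orientation = NA_character_)
}

#' Realize a scripted scenario as coordinates
#'
#' Places every dye so that the script is realized exactly: stacked
#' neighbours sit `spacing` apart along a shared plane normal with the
#' scripted orientation pattern; bound dyes (or bound stacks) sit alongside
#' the GAG chain so that each bound dye has a terminal nitrogen within the
#' contact range of an anionic site (singletons at exactly
#' `bound_distance`); unbound dyes are parked at least 20 Angstrom away
#' from all sites and from each other. Placement is deterministic.
#'
#' @param scenario an [scripted_scenario()] object.
#' @param check_overlap verify that no two molecules come closer than 1.5
#'   Angstrom atom-to-atom (rejected as geometric infeasibility).
#' @return list with elements `trajectory` (an [mb_trajectory()]) and
#'   `truth` (tibble: frame, mb_id, bound, stack_id, stack_pos,
#'   orientation, site_id).
#' @export
generate_scripted <- function(scenario, check_overlap = TRUE) {
  stopifnot(inherits(scenario, "mb_scenario"))
  tpl <- .mb_template_mat()
  chain <- if (!is.null(scenario$gag_preset)) {
    build_gag(scenario$gag_preset, scenario$dp)
  }
  topo <- .make_topology(scenario$mb_count, chain)
  gag_block <- if (!is.null(chain)) .gag_coord_block(chain)

  script <- dplyr::arrange(scenario$script, .data$frame, .data$mb_id)
  frames <- split(script, script$frame)

  # identical layouts are realized once and reused
  layout_key <- vapply(frames, function(fr) {
    paste(fr$mb_id, fr$bound, fr$stack_id, fr$stack_pos, fr$orientation,
          collapse = ";")
  }, character(1))
  layouts <- new.env(parent = emptyenv())

  coord_blocks <- vector("list", length(frames))
  truth_blocks <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    key <- layout_key[[f]]
    if (is.null(layouts[[key]])) {
      layouts[[key]] <- .realize_layout(frames[[f]], scenario, chain, tpl,
                                        frame_index = f,
                                        check_overlap = check_overlap)
    }
    lay <- layouts[[key]]
    coord_blocks[[f]] <- lay$mb_xyz
    truth_blocks[[f]] <- dplyr::mutate(lay$truth, frame = f, .before = 1)
  }

  n_mb_atoms <- nrow(tpl$xyz)
  mb_labels <- rep(tpl$labels, scenario$mb_count)
  mb_mols <- rep(paste0("MB", seq_len(scenario$mb_count)), each = n_mb_atoms)

  coords <- purrr::map_dfr(seq_along(frames), function(f) {
    xyz <- coord_blocks[[f]]
    block <- if (is.null(gag_block)) xyz else rbind(gag_block, xyz)
    tibble::tibble(
      frame = f,
      molecule_id = c(if (!is.null(chain)) rep("GAG", nrow(gag_block)), mb_mols),
      atom_label = c(if (!is.null(chain))
        c(paste0("BB", chain$backbone$residue_index),
          paste0("A", chain$sites$site_id)), mb_labels),
      x = block[, 1], y = block[, 2], z = block[, 3])
  })

  traj <- mb_trajectory(coords, topo,
                        gag_preset = scenario$gag_preset %||% NA_character_,
                        seed = scenario$seed)
  list(trajectory = traj, truth = dplyr::bind_rows(truth_blocks))
}

# place all dyes for one frame layout; returns mb coordinate block and truth
.realize_layout <- function(fr, scenario, chain, tpl, frame_index,
                            check_overlap) {
  L <- tpl$half_length
  d0 <- scenario$bound_distance
  sp <- scenario$spacing
  zhat <- c(0, 0, 1)
  mb_count <- scenario$mb_count
  poses <- vector("list", mb_count)      # per-mb list(R, t)
  site_of <- rep(NA_integer_, mb_count)

  sites <- if (!is.null(chain)) chain$sites
  cand_sites <- if (!is.null(sites)) {
    s <- if (!is.null(scenario$site_type)) {
      sites[sites$site_type %in% scenario$site_type, ]
    } else sites
    if (nrow(s) == 0) {
      .gs_abort(sprintf("frame %d: no sites of type %s in preset %s",
                        frame_index, paste(scenario$site_type, collapse = "/"),
                        scenario$gag_preset), "gagstack_infeasible")
    }
    dplyr::arrange(s, .data$z, .data$site_id)
  }
  z_max <- if (!is.null(chain)) max(chain$backbone$z) else 45

  groups <- .layout_groups(fr)
  used_sites <- integer(0)
  used_azimuth <- numeric(0)
  slot_i <- 0L
  n_unbound_groups <- sum(!vapply(groups, function(g) g$bound[1], logical(1)))

  for (g in groups) {
    size <- nrow(g)
    if (g$bound[1]) {
      if (is.null(cand_sites)) {
        .gs_abort(sprintf("frame %d: bound dye without a GAG", frame_index),
                  "gagstack_infeasible")
      }
      if (size == 1) {
        avail <- cand_sites[!cand_sites$site_id %in% used_sites, ]
        if (nrow(avail) == 0) {
          .gs_abort(sprintf(
            "frame %d: more bound dyes than available anionic sites",
            frame_index), "gagstack_infeasible")
        }
        s <- avail[1, ]
        used_sites <- c(used_sites, s$site_id)
        u <- c(cos(s$azimuth), sin(s$azimuth), 0)
        ctr <- c(s$x, s$y, s$z) + (d0 + L) * u
        poses[[g$mb_id[1]]] <- list(R = .frame_from(u, zhat), t = ctr)
        site_of[g$mb_id[1]] <- s$site_id
      } else {
        span <- (size - 1) * sp
        ok <- cand_sites[!cand_sites$site_id %in% used_sites &
                           cand_sites$z + span <= z_max + .BB_SPACING, ]
        if (length(used_azimuth)) {
          dAz <- outer(ok$azimuth, used_azimuth,
                       function(a, b) abs(((a - b + pi) %% (2 * pi)) - pi))
          ok <- ok[apply(dAz, 1, min) >= pi / 3, , drop = FALSE]
        }
        if (nrow(ok) == 0) {
          .gs_abort(sprintf(
            "frame %d: cannot place a bound stack of %d without overlap",
            frame_index, size), "gagstack_infeasible")
        }
        s <- ok[1, ]
        used_sites <- c(used_sites, s$site_id)
        used_azimuth <- c(used_azimuth, s$azimuth)
        u0 <- c(cos(s$azimuth), sin(s$azimuth), 0)
        rc <- .SITE_RADIUS + d0 + L
        g <- g[order(g$stack_pos), ]
        flip <- cumsum(c(FALSE, g$orientation[-1] == "antiparallel")) %% 2 == 1
        for (m in seq_len(size)) {
          u <- if (flip[m]) -u0 else u0
          ctr <- c(rc * u0[1], rc * u0[2], s$z + (m - 1) * sp)
          poses[[g$mb_id[m]]] <- list(R = .frame_from(u, zhat), t = ctr)
          site_of[g$mb_id[m]] <- s$site_id
        }
      }
    } else {
      slot_i <- slot_i + 1L
      slot <- .far_slot(slot_i, n_unbound_groups, z_center = z_max / 2)
      u0 <- c(cos(slot$az), sin(slot$az), 0)
      g <- g[order(g$stack_pos %||% 1L), ]
      flip <- if (size > 1) {
        cumsum(c(FALSE, g$orientation[-1] == "antiparallel")) %% 2 == 1
      } else FALSE
      z0 <- slot$z - (size - 1) / 2 * sp
      for (m in seq_len(size)) {
        u <- if (flip[m]) -u0 else u0
        ctr <- c(slot$r * u0[1], slot$r * u0[2], z0 + (m - 1) * sp)
        poses[[g$mb_id[m]]] <- list(R = .frame_from(u, zhat), t = ctr)
      }
    }
  }

  blocks <- lapply(poses, function(p) .apply_pose(tpl$xyz, p$R, p$t))
  if (check_overlap) .check_no_overlap(blocks, frame_index)

  truth <- fr[, c("mb_id", "bound", "stack_id", "stack_pos", "orientation")]
  truth$mb_id <- paste0("MB", truth$mb_id)
  truth$site_id <- site_of[fr$mb_id]
  list(mb_xyz = do.call(rbind, blocks), truth = tibble::as_tibble(truth))
}

# split one frame's script rows into placement groups (stacks + singletons)
.layout_groups <- function(fr) {
  singles <- fr[is.na(fr$stack_id), ]
  stacks <- fr[!is.na(fr$stack_id), ]
  c(
    if (nrow(stacks)) unname(split(stacks, stacks$stack_id)),
    if (nrow(singles)) unname(split(singles, seq_len(nrow(singles))))
  )
}

# parking slot far from the chain and from other parked groups
.far_slot <- function(i, n_groups, z_center, r0 = 45, per_ring = 12) {
  ring <- (i - 1) %/% per_ring
  k <- (i - 1) %% per_ring
  n_on_ring <- min(n_groups - ring * per_ring, per_ring)
  list(r = r0 + 30 * ring,
       az = 2 * pi * k / max(n_on_ring, 1) + pi / 7,
       z = z_center)
}

.check_no_overlap <- function(blocks, frame_index, min_dist = 1.5) {
  n <- length(blocks)
  ctrs <- t(vapply(blocks, colMeans, numeric(3)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sqrt(sum((ctrs[i, ] - ctrs[j, ])^2)) > 15) next
      dmin <- min(.cross_dist(blocks[[i]], blocks[[j]]))
      if (dmin < min_dist) {
        .gs_abort(sprintf(
          "frame %d: molecules %d and %d overlap (min atom distance %.2f A)",
          frame_index, i, j, dmin), "gagstack_infeasible")
      }
    }
  }
  invisible(TRUE)
}

# all pairwise distances between two coordinate matrices
.cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
  sqrt(pmax(d2, 0))
}
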