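# shared fixtures, built in code at test time

# place the dye template at a given pose; returns list(ring, npair, all)
place_mb <- function(centroid = c(0, 0, 0), long_axis = c(1, 0, 0),
                     normal = c(0, 0, 1)) {
  tpl <- mb_template()
  R <- gagstack:::.frame_from(long_axis, normal)
  xyz <- as.matrix(tpl[, c("x", "y", "z")]) %*% t(R)
  xyz <- sweep(xyz, 2, centroid, "+")
  colnames(xyz) <- c("x", "y", "z")
  list(ring = xyz[tpl$role == "ring", , drop = FALSE],
       npair = xyz[tpl$role == "terminal_N", , drop = FALSE],
       all = xyz, tpl = tpl)
}

# hand-built one-frame trajectory from a list of dye placements and a chain
toy_trajectory <- function(placements, chain = NULL, n_frames = 1) {
  tpl <- mb_template()
  coords <- purrr::map_dfr(seq_len(n_frames), function(f) {
    mb <- purrr::imap_dfr(placements, function(pl, j) {
      tibble::tibble(frame = f, molecule_id = paste0("MB", j),
                     atom_label = tpl$atom_label,
                     x = pl$all[, "x"], y = pl$all[, "y"], z = pl$all[, "z"])
    })
    if (is.null(chain)) return(mb)
    gag <- tibble::tibble(
      frame = f, molecule_id = "GAG",
      atom_label = c(paste0("BB", chain$backbone$residue_index),
                     paste0("A", chain$sites$site_id)),
      x = c(chain$backbone$x, chain$sites$x),
      y = c(chain$backbone$y, chain$sites$y),
      z = c(chain$backbone$z, chain$sites$z))
    dplyr::bind_rows(gag, mb)
  })
  topo <- gagstack:::.make_topology(length(placements), chain)
  mb_trajectory(coords, topo)
}

# independent union-find over an explicit pairwise edge check (oracle for
# stack component detection)
brute_components <- function(geo_pairs, n) {
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (e in geo_pairs) {
    ri <- find(e[1]); rj <- find(e[2])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(seq_len(n), roots)
}

# explicit O(n^2) stacking edge list from raw coordinates (independent of
# detect_stacks internals; recomputes planes with its own tiny fitter)
brute_stack_edges <- function(rings, d_max = 4.5, angle_max = 30,
                              lateral_max = 3) {
  fitp <- function(m) {
    ctr <- colMeans(m)
    s <- svd(sweep(m, 2, ctr))
    list(c = ctr, n = s$v[, 3])
  }
  pl <- lapply(rings, fitp)
  edges <- list()
  n <- length(rings)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- pl[[j]]$c - pl[[i]]$c
      ipl <- (abs(sum(d * pl[[i]]$n)) + abs(sum(d * pl[[j]]$n))) / 2
      ang <- acos(min(abs(sum(pl[[i]]$n * pl[[j]]$n)), 1)) * 180 / pi
      lat <- sqrt(max(sum(d^2) - ipl^2, 0))
      if (ipl <= d_max && ang <= angle_max && lat <= lateral_max) {
        edges[[length(edges) + 1]] <- c(i, j)
      }
    }
  }
  edges
}

# ring coordinates of every dye in one frame of a trajectory
frame_rings <- function(traj, f) {
  rows <- gagstack:::.traj_rows(traj)
  M <- as.matrix(traj$coords[, c("x", "y", "z")])
  base <- (f - 1) * traj$n_atoms
  lapply(mb_ids(traj), function(id) M[base + rows$mb_ring[[id]], , drop = FALSE])
}
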