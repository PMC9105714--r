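#' Multi-frame coordinate trajectory container
#'
#' An `mb_trajectory` bundles the per-frame coordinates of all dye (MB)
#' molecules and, optionally, one GAG chain, together with a topology table
#' assigning each atom a role. Coordinates are kept in a tidy tibble
#' (frame, molecule_id, atom_label, x, y, z) in a canonical atom order
#' (GAG atoms first, then MB molecules in id order, template atom order
#' within each molecule), identical in every frame.
#'
#' Roles follow the topology-sidecar vocabulary:
#' `ring`, `terminal_N` (MB), `backbone`, `sulfate_S`, `carboxylate_C` (GAG).
#'
#' @param coords tibble with columns frame, molecule_id, atom_label, x, y, z.
#' @param topology tibble with columns molecule_id, atom_label, role,
#'   site_type, residue_index (`NA` where not applicable).
#' @param frame_interval nominal time per frame (arbitrary units).
#' @param gag_preset preset name of the embedded chain, or `NA`.
#' @param seed seed the trajectory was generated from, or `NA`.
#' @return an object of class `mb_trajectory`.
#' @export
mb_trajectory <- function(coords, topology, frame_interval = 1,
                          gag_preset = NA_character_, seed = NA_integer_) {
  coords <- tibble::as_tibble(coords)
  topology <- tibble::as_tibble(topology)
  need_c <- c("frame", "molecule_id", "atom_label", "x", "y", "z")
  need_t <- c("molecule_id", "atom_label", "role")
  if (!all(need_c %in% names(coords))) {
    .gs_abort("coords must have columns frame, molecule_id, atom_label, x, y, z",
              "gagstack_bad_trajectory")
  }
  if (!all(need_t %in% names(topology))) {
    .gs_abort("topology must have columns molecule_id, atom_label, role",
              "gagstack_bad_trajectory")
  }
  if (!"site_type" %in% names(topology)) topology$site_type <- NA_character_
  if (!"residue_index" %in% names(topology)) topology$residue_index <- NA_integer_
  ok_roles <- c("ring", "terminal_N", "backbone", "sulfate_S", "carboxylate_C")
  bad <- setdiff(unique(topology$role), ok_roles)
  if (length(bad)) {
    .gs_abort(sprintf("unknown atom role(s): %s (valid: %s)",
                      paste(bad, collapse = ", "), paste(ok_roles, collapse = ", ")),
              "gagstack_bad_role")
  }

  topology <- .canonical_topology(topology)
  atom_key <- paste(topology$molecule_id, topology$atom_label)
  n_atoms <- nrow(topology)

  frames <- sort(unique(coords$frame))
  # enforce identical atom sets in every frame
  per_frame <- table(coords$frame)
  if (length(unique(per_frame)) != 1 || per_frame[[1]] != n_atoms) {
    off <- names(per_frame)[per_frame != n_atoms][1] %||% frames[1]
    .gs_abort(sprintf("atom count mismatch at frame %s: expected %d atoms",
                      off, n_atoms), "gagstack_bad_trajectory")
  }
  ord <- order(match(coords$frame, frames),
               match(paste(coords$molecule_id, coords$atom_label), atom_key))
  coords <- coords[ord, need_c]
  coords$frame <- match(coords$frame, frames)  # renumber 1..n_frames

  structure(
    list(coords = coords, topology = topology,
         n_frames = length(frames), n_atoms = n_atoms,
         frame_interval = frame_interval,
         gag_preset = gag_preset, seed = seed),
    class = "mb_trajectory")
}

# canonical atom order: GAG first (backbone then sites by label), then MB
# molecules by numeric id, template atom order within each
.canonical_topology <- function(topology) {
  mol <- unique(topology$molecule_id)
  mb <- mol[grepl("^MB", mol)]
  mb <- mb[order(as.integer(sub("^MB", "", mb)))]
  mol_order <- c(setdiff(mol, mb), mb)
  ord <- order(match(topology$molecule_id, mol_order), seq_len(nrow(topology)))
  topology[ord, , drop = FALSE]
}

#' @export
print.mb_trajectory <- function(x, ...) {
  cat(sprintf("<mb_trajectory> %d frames, %d atoms (%d MB molecules%s)\n",
              x$n_frames, x$n_atoms, length(mb_ids(x)),
              if (is.na(x$gag_preset)) "" else paste0(", GAG ", x$gag_preset)))
  invisible(x)
}

#' Dye molecule ids in a trajectory
#' @param traj an `mb_trajectory`.
#' @return character vector `MB1`, `MB2`, ... in numeric order.
#' @export
mb_ids <- function(traj) {
  stopifnot(inherits(traj, "mb_trajectory"))
  ids <- unique(traj$topology$molecule_id)
  ids <- ids[grepl("^MB", ids)]
  ids[order(as.integer(sub("^MB", "", ids)))]
}

# ---- fast internal indexing -------------------------------------------------

# coordinate matrix of one frame, rows in canonical topology order
.frame_xyz <- function(traj, f) {
  n <- traj$n_atoms
  rows <- ((f - 1) * n + 1):(f * n)
  m <- as.matrix(traj$coords[rows, c("x", "y", "z")])
  rownames(m) <- NULL
  m
}

# row indices (within a frame) of the pieces the analyses need
.traj_rows <- function(traj) {
  topo <- traj$topology
  ids <- mb_ids(traj)
  list(
    mb_ring = lapply(setNames(ids, ids), function(id)
      which(topo$molecule_id == id & topo$role == "ring")),
    mb_n = lapply(setNames(ids, ids), function(id)
      which(topo$molecule_id == id & topo$role == "terminal_N")),
    mb_all = lapply(setNames(ids, ids), function(id)
      which(topo$molecule_id == id)),
    sites = which(topo$role %in% c("sulfate_S", "carboxylate_C")),
    backbone = which(topo$role == "backbone")
  )
}

#' Keep a subset of frames
#'
#' @param traj an `mb_trajectory`.
#' @param frames integer vector of frame indices to keep (in order).
#' @return a new `mb_trajectory` with frames renumbered `1..length(frames)`;
#'   the original indices are kept in attribute `source_frames`.
#' @export
subset_frames <- function(traj, frames) {
  stopifnot(inherits(traj, "mb_trajectory"))
  frames <- as.integer(frames)
  if (any(frames < 1 | frames > traj$n_frames)) {
    .gs_abort("frame indices out of range", "gagstack_bad_argument")
  }
  n <- traj$n_atoms
  rows <- unlist(lapply(frames, function(f) ((f - 1) * n + 1):(f * n)))
  coords <- traj$coords[rows, ]
  coords$frame <- rep(seq_along(frames), each = n)
  out <- traj
  out$coords <- coords
  out$n_frames <- length(frames)
  attr(out, "source_frames") <- frames
  out
}

#' Apply a global rigid transform to every frame
#'
#' Rotates and translates all coordinates of all frames; useful for
#' verifying that the analyses are invariant under global rigid motion.
#'
#' @param traj an `mb_trajectory`.
#' @param R 3 x 3 rotation matrix.
#' @param shift length-3 translation.
#' @return transformed `mb_trajectory`.
#' @export
transform_trajectory <- function(traj, R = diag(3), shift = c(0, 0, 0)) {
  stopifnot(inherits(traj, "mb_trajectory"))
  m <- as.matrix(traj$coords[, c("x", "y", "z")])
  m <- m %*% t(R)
  m <- sweep(m, 2, shift, "+")
  traj$coords$x <- m[, 1]; traj$coords$y <- m[, 2]; traj$coords$z <- m[, 3]
  traj
}

# build the topology tibble for mb_count dyes and an optional chain
.make_topology <- function(mb_count, chain = NULL) {
  tpl <- mb_template()
  mb_topo <- purrr::map_dfr(seq_len(mb_count), function(j) {
    tibble::tibble(molecule_id = paste0("MB", j),
                   atom_label = tpl$atom_label, role = tpl$role,
                   site_type = NA_character_, residue_index = NA_integer_)
  })
  if (is.null(chain)) return(mb_topo)
  gag_topo <- dplyr::bind_rows(
    tibble::tibble(molecule_id = "GAG",
                   atom_label = paste0("BB", chain$backbone$residue_index),
                   role = "backbone", site_type = NA_character_,
                   residue_index = chain$backbone$residue_index),
    tibble::tibble(molecule_id = "GAG",
                   atom_label = paste0("A", chain$sites$site_id),
                   role = ifelse(chain$sites$site_type == "carboxylate",
                                 "carboxylate_C", "sulfate_S"),
                   site_type = chain$sites$site_type,
                   residue_index = chain$sites$residue_index)
  )
  dplyr::bind_rows(gag_topo, mb_topo)
}

# static GAG coordinate block matching .make_topology order
.gag_coord_block <- function(chain) {
  rbind(as.matrix(chain$backbone[, c("x", "y", "z")]),
        as.matrix(chain$sites[, c("x", "y", "z")]))
}
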