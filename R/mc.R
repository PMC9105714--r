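#' Parameters for the rigid-body Monte Carlo generator
#'
#' Settings of the Metropolis Monte Carlo mode of the synthetic trajectory
#' generator. The pair potential is deliberately minimal: a flat-bottom
#' stacking well between dye molecules (active when a pair satisfies the
#' geometric stacking criterion at the target spacing, with
#' orientation-independent depth), a screened-Coulomb attraction between
#' the positively charged terminal nitrogens and the anionic-site anchors,
#' and hard-core repulsion. The chain is held rigid; dyes move by
#' single-molecule rigid-body translations (up to 1 Angstrom) and rotations
#' (up to 15 degrees), one attempt per dye per sweep, inside a reflecting
#' spherical cell centred on the chain.
#'
#' @param mb_count number of dye molecules.
#' @param gag_preset GAG preset name or `NULL` for a GAG-free cell.
#' @param stacking_well_depth well depth (energy units, >= 0).
#' @param site_attraction_strength prefactor of the screened-Coulomb
#'   nitrogen-site attraction (>= 0).
#' @param screening_length Debye-like screening length (Angstrom).
#' @param temperature_factor Metropolis temperature kT (> 0).
#' @param n_sweeps number of sweeps; one frame is recorded per sweep.
#' @param spacing stacking well minimum (Angstrom).
#' @param well_width half-width of the flat-bottom well (Angstrom).
#' @param cell_radius radius of the reflecting spherical cell (Angstrom).
#' @param dp chain length for [build_gag()].
#' @param seed integer seed; the trajectory is reproducible from it.
#' @return a list of class `mc_params`.
#' @export
mc_params <- function(mb_count = 10, gag_preset = NULL,
                      stacking_well_depth = 2, site_attraction_strength = 2,
                      screening_length = 8, temperature_factor = 1,
                      n_sweeps = 1000, spacing = 3.7, well_width = 0.8,
                      cell_radius = 60, dp = 10, seed = 1L) {
  if (!is.numeric(temperature_factor) || temperature_factor <= 0) {
    .gs_abort("temperature_factor must be positive", "gagstack_bad_argument")
  }
  stopifnot(stacking_well_depth >= 0, site_attraction_strength >= 0,
            screening_length > 0, mb_count >= 1, n_sweeps >= 1)
  structure(as.list(environment()), class = "mc_params")
}

#' Generate a trajectory by rigid-body Metropolis Monte Carlo
#'
#' @param params an [mc_params()] object.
#' @return an [mb_trajectory()] with one frame per sweep.
#' @export
generate_mc <- function(params) {
  stopifnot(inherits(params, "mc_params"))
  set.seed(params$seed)
  tpl <- .mb_template_mat()
  chain <- if (!is.null(params$gag_preset)) build_gag(params$gag_preset, params$dp)
  anchors <- if (!is.null(chain)) as.matrix(chain$sites[, c("x", "y", "z")])
  backbone <- if (!is.null(chain)) as.matrix(chain$backbone[, c("x", "y", "z")])
  z_max <- if (!is.null(chain)) max(chain$backbone$z) else 0
  center <- c(0, 0, z_max / 2)
  n <- params$mb_count

  poses <- .mc_init(n, params, backbone, center)
  e_site <- vapply(poses, function(p)
    .mc_site_energy(p, tpl, anchors, backbone, params), numeric(1))

  frames <- vector("list", params$n_sweeps)
  max_tr <- 1.0
  max_rot <- 15 * pi / 180
  for (sw in seq_len(params$n_sweeps)) {
    for (i in seq_len(n)) {
      old <- poses[[i]]
      prop <- list(
        R = rotation_about(stats::rnorm(3), stats::runif(1, -max_rot, max_rot)) %*% old$R,
        t = old$t + .runif_ball(max_tr))
      if (sqrt(sum((prop$t - center)^2)) > params$cell_radius) next  # wall
      e_old <- e_site[i] + .mc_pair_sum(i, old, poses, params)
      new_site <- .mc_site_energy(prop, tpl, anchors, backbone, params)
      e_new <- new_site + {
        tmp <- poses; tmp[[i]] <- prop
        .mc_pair_sum(i, prop, tmp, params)
      }
      if (e_new - e_old <= 0 ||
          stats::runif(1) < exp(-(e_new - e_old) / params$temperature_factor)) {
        poses[[i]] <- prop
        e_site[i] <- new_site
      }
    }
    frames[[sw]] <- poses
  }
  .poses_to_trajectory(frames, tpl, chain, params)
}

# uniform point in a ball of given radius
.runif_ball <- function(r) {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2)) * r * stats::runif(1)^(1 / 3)
}

# dispersed random initial poses (no hard-core violations)
.mc_init <- function(n, params, backbone, center) {
  poses <- vector("list", n)
  placed <- matrix(numeric(0), 0, 3)
  for (i in seq_len(n)) {
    repeat {
      # init from the uniform distribution over the cell, which is the
      # stationary distribution of the zero-interaction chain
      t0 <- center + .runif_ball(params$cell_radius)
      ok <- (nrow(placed) == 0 ||
               min(sqrt(rowSums(sweep(placed, 2, t0)^2))) > 6) &&
        (is.null(backbone) ||
           min(sqrt(rowSums(sweep(backbone, 2, t0)^2))) > 6)
      if (ok) break
    }
    M <- matrix(stats::rnorm(9), 3)
    Q <- qr.Q(qr(M))
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    poses[[i]] <- list(R = Q, t = t0)
    placed <- rbind(placed, t0)
  }
  poses
}

# stacking-well + hard-core energy of dye i against all other dyes
.mc_pair_sum <- function(i, pose_i, poses, params) {
  e <- 0
  for (j in seq_along(poses)) {
    if (j == i) next
    e <- e + .mc_pair_energy(pose_i, poses[[j]], params)
    if (e >= 1e6) return(e)
  }
  e
}

.mc_pair_energy <- function(a, b, params) {
  d <- b$t - a$t
  rc <- sqrt(sum(d^2))
  if (rc < 3.0) return(1e6)                     # hard core
  if (rc > params$spacing + params$well_width + 6) return(0)
  na <- a$R[, 3]; nb <- b$R[, 3]
  ipl <- (abs(sum(d * na)) + abs(sum(d * nb))) / 2
  if (abs(ipl - params$spacing) > params$well_width) return(0)
  cosang <- abs(sum(na * nb))
  if (cosang < cos(30 * pi / 180)) return(0)
  lat <- sqrt(max(rc^2 - ((abs(sum(d * na)) + abs(sum(d * nb))) / 2)^2, 0))
  if (lat > 3.0) return(0)
  -params$stacking_well_depth
}

# screened-Coulomb attraction of the two terminal N to all anionic anchors,
# plus hard-core against the chain
.mc_site_energy <- function(pose, tpl, anchors, backbone, params) {
  if (is.null(anchors) || params$site_attraction_strength == 0) {
    if (is.null(backbone)) return(0)
    if (min(sqrt(rowSums(sweep(backbone, 2, pose$t)^2))) < 3.0) return(1e6)
    return(0)
  }
  if (min(sqrt(rowSums(sweep(backbone, 2, pose$t)^2))) < 3.0) return(1e6)
  npos <- .apply_pose(tpl$xyz[tpl$n_rows, , drop = FALSE], pose$R, pose$t)
  r <- .cross_dist(npos, anchors)
  lam <- params$screening_length
  -params$site_attraction_strength * lam * sum(exp(-r / lam) / r)
}

# assemble recorded pose frames into an mb_trajectory
.poses_to_trajectory <- function(frames, tpl, chain, params) {
  topo <- .make_topology(params$mb_count, chain)
  gag_block <- if (!is.null(chain)) .gag_coord_block(chain)
  n_mb_atoms <- nrow(tpl$xyz)
  mb_labels <- rep(tpl$labels, params$mb_count)
  mb_mols <- rep(paste0("MB", seq_len(params$mb_count)), each = n_mb_atoms)
  gag_labels <- if (!is.null(chain)) {
    c(paste0("BB", chain$backbone$residue_index), paste0("A", chain$sites$site_id))
  }
  coords <- purrr::map_dfr(seq_along(frames), function(f) {
    xyz <- do.call(rbind, lapply(frames[[f]], function(p)
      .apply_pose(tpl$xyz, p$R, p$t)))
    block <- if (is.null(gag_block)) xyz else rbind(gag_block, xyz)
    tibble::tibble(
      frame = f,
      molecule_id = c(if (!is.null(chain)) rep("GAG", nrow(gag_block)), mb_mols),
      atom_label = c(gag_labels, mb_labels),
      x = block[, 1], y = block[, 2], z = block[, 3])
  })
  mb_trajectory(coords, topo,
                gag_preset = params$gag_preset %||% NA_character_,
                seed = params$seed)
}
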