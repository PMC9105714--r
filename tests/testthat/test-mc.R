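# Mechanistic contrasts of the Monte Carlo generator. Runs are kept small
# (few dyes, small cells, short chains of sweeps) and repeated over seeds.

mc_bound_fraction <- function(traj) {
  mean(bound_flags(traj)$bound)
}

# fraction of dyes that sit in a stack of size >= 2, averaged over frames
mc_stacked_fraction <- function(traj, frames = NULL) {
  rec <- detect_stacks(traj, frames = frames)
  n_frames <- length(frames %||% seq_len(traj$n_frames))
  sum(rec$size) / (n_frames * length(mb_ids(traj)))
}

test_that("with all interactions off, binding matches the random-placement baseline", {
  n_seeds <- 20
  cell <- 25
  fracs <- vapply(seq_len(n_seeds), function(s) {
    traj <- generate_mc(mc_params(
      mb_count = 5, gag_preset = "HS1", stacking_well_depth = 0,
      site_attraction_strength = 0, n_sweeps = 150, cell_radius = cell,
      seed = 100 + s))
    mc_bound_fraction(traj)
  }, numeric(1))

  # oracle: bound probability of a uniformly placed, uniformly rotated dye
  set.seed(999)
  chain <- build_gag("HS1", 10)
  anchors <- as.matrix(chain$sites[, c("x", "y", "z")])
  center <- c(0, 0, max(chain$backbone$z) / 2)
  tpl <- mb_template()
  nmat <- as.matrix(tpl[tpl$role == "terminal_N", c("x", "y", "z")])
  n_draw <- 4000
  hit <- vapply(seq_len(n_draw), function(i) {
    v <- rnorm(3); t0 <- center + v / sqrt(sum(v^2)) * cell * runif(1)^(1 / 3)
    Q <- qr.Q(qr(matrix(rnorm(9), 3)))
    np <- sweep(nmat %*% t(Q), 2, t0, "+")
    any(sqrt(outer(rowSums(np^2), rowSums(anchors^2), "+") -
               2 * np %*% t(anchors)) < 8)
  }, logical(1))
  p0 <- mean(hit)
  se <- sqrt(var(fracs) / n_seeds + p0 * (1 - p0) / n_draw)
  expect_lt(abs(mean(fracs) - p0), 3 * se)
})

test_that("a deep stacking well enriches stacking relative to the null model", {
  n_seeds <- 20
  res <- t(vapply(seq_len(n_seeds), function(s) {
    base <- list(mb_count = 5, n_sweeps = 150, cell_radius = 12,
                 seed = 200 + s)
    on <- do.call(mc_params, c(base, list(stacking_well_depth = 8)))
    off <- do.call(mc_params, c(base, list(stacking_well_depth = 0)))
    c(on = mc_stacked_fraction(generate_mc(on)),
      off = mc_stacked_fraction(generate_mc(off)))
  }, numeric(2)))
  expect_gt(mean(res[, "on"]), mean(res[, "off"]))
  # the enrichment should be substantial, not a tie broken by noise
  expect_gt(mean(res[, "on"] - res[, "off"]), 0.05)
})

test_that("chain attraction drives dye binding relative to the neutral model", {
  n_seeds <- 20
  res <- t(vapply(seq_len(n_seeds), function(s) {
    base <- list(mb_count = 4, gag_preset = "HP", stacking_well_depth = 0,
                 n_sweeps = 150, cell_radius = 25, screening_length = 8,
                 seed = 300 + s)
    on <- do.call(mc_params, c(base, list(site_attraction_strength = 6)))
    off <- do.call(mc_params, c(base, list(site_attraction_strength = 0)))
    c(on = mc_bound_fraction(generate_mc(on)),
      off = mc_bound_fraction(generate_mc(off)))
  }, numeric(2)))
  expect_gt(mean(res[, "on"]), mean(res[, "off"]))
  expect_gt(mean(res[, "on"] - res[, "off"]), 0.05)
})

test_that("the null model's modal stack size is 1", {
  sizes <- vapply(seq_len(20), function(s) {
    traj <- generate_mc(mc_params(
      mb_count = 5, stacking_well_depth = 0, site_attraction_strength = 0,
      n_sweeps = 60, cell_radius = 25, seed = 400 + s))
    st <- stack_statistics(traj)
    st$size_histogram$size[which.max(st$size_histogram$n_per_frame)]
  }, integer(1))
  expect_true(all(sizes == 1L))
})
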