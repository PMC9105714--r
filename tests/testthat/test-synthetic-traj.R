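test_that("scripted placement preserves rigid-body geometry across frames", {
  scen <- scripted_scenario(4, 6, "HS1",
                            script_stacks(4, c(3), mb_count = 6, bound = TRUE))
  traj <- generate_scripted(scen)$trajectory
  rows <- gagstack:::.traj_rows(traj)
  M <- as.matrix(traj$coords[, c("x", "y", "z")])
  for (id in mb_ids(traj)) {
    ref <- NULL
    for (f in seq_len(traj$n_frames)) {
      xyz <- M[(f - 1) * traj$n_atoms + rows$mb_all[[id]], ]
      d <- as.vector(dist(xyz))
      if (is.null(ref)) ref <- d else expect_lt(max(abs(d - ref)), 1e-6)
    }
  }
})

test_that("script validation rejects malformed partitions", {
  ok <- script_stacks(2, c(2), mb_count = 3)
  # duplicate (frame, mb) pair
  expect_error(
    scripted_scenario(2, 3, "HP", dplyr::bind_rows(ok, ok[1, ])),
    "exactly once", class = "gagstack_bad_script")
  # missing molecule
  expect_error(
    scripted_scenario(2, 4, "HP", ok), class = "gagstack_bad_script")
  # stack positions must enumerate 1..size
  bad <- ok
  bad$stack_pos[bad$stack_pos == 2] <- 3L
  expect_error(scripted_scenario(2, 3, "HP", bad),
               class = "gagstack_bad_script")
  # bound dyes need a chain to bind
  bound <- script_bound_fraction(2, 3, 1)
  expect_error(scripted_scenario(2, 3, NULL, bound),
               "no GAG", class = "gagstack_bad_script")
  # mixed bound flags within one stack
  mixed <- script_stacks(1, c(2), mb_count = 2, bound = TRUE)
  mixed$bound[1] <- FALSE
  expect_error(scripted_scenario(1, 2, "HP", mixed),
               class = "gagstack_bad_script")
})

test_that("infeasible bound placements are rejected with the frame index", {
  # more bound singletons than anionic sites: deHP dp2 has a single site
  scen <- scripted_scenario(1, 3, "deHP", script_bound_fraction(1, 3, 1),
                            dp = 2)
  expect_error(generate_scripted(scen), "frame 1",
               class = "gagstack_infeasible")
})

test_that("bound singletons sit at the requested anchor distance", {
  scen <- scripted_scenario(2, 2, "CS6", script_bound_fraction(2, 2, 1),
                            bound_distance = 4.0)
  run <- generate_scripted(scen)
  d <- mb_site_distances(run$trajectory)
  truth <- run$truth
  for (i in seq_len(nrow(truth))) {
    di <- d[d$frame == truth$frame[i] & d$mb_id == truth$mb_id[i] &
              d$site_id == truth$site_id[i], ]
    expect_equal(di$distance, 4.0, tolerance = 1e-9)
  }
  # and nothing is parked closer than 20 A when unbound
  scen0 <- scripted_scenario(1, 3, "CS6", script_singletons(1, 3))
  d0 <- mb_site_distances(generate_scripted(scen0)$trajectory)
  expect_gt(min(d0$distance), 20)
})

test_that("Monte Carlo trajectories are reproducible from the seed", {
  p <- mc_params(mb_count = 4, gag_preset = "CS4", n_sweeps = 25,
                 cell_radius = 25, seed = 11L)
  t1 <- generate_mc(p)
  t2 <- generate_mc(p)
  expect_identical(t1$coords, t2$coords)
  t3 <- generate_mc(mc_params(mb_count = 4, gag_preset = "CS4",
                              n_sweeps = 25, cell_radius = 25, seed = 12L))
  expect_false(identical(t1$coords, t3$coords))
})

test_that("Monte Carlo moves keep molecules rigid", {
  traj <- generate_mc(mc_params(mb_count = 3, n_sweeps = 30,
                                cell_radius = 20, seed = 5L))
  rows <- gagstack:::.traj_rows(traj)
  M <- as.matrix(traj$coords[, c("x", "y", "z")])
  for (id in mb_ids(traj)) {
    ref <- as.vector(dist(M[rows$mb_all[[id]], ]))
    last <- (traj$n_frames - 1) * traj$n_atoms
    expect_lt(max(abs(as.vector(dist(M[last + rows$mb_all[[id]], ])) - ref)),
              1e-6)
  }
})

test_that("non-positive temperature is rejected", {
  expect_error(mc_params(temperature_factor = 0), "positive")
  expect_error(mc_params(temperature_factor = -1), "positive")
})
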