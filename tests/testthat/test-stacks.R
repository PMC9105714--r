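test_that("scripted tetramer + hexamer are recovered exactly", {
  scen <- scripted_scenario(3, 10, "HP",
                            script_stacks(3, c(4, 6), bound = TRUE))
  run <- generate_scripted(scen)
  rec <- detect_stacks(run$trajectory)
  for (f in 1:3) {
    sizes <- sort(rec$size[rec$frame == f])
    expect_equal(sizes, c(4L, 6L))
  }
  expect_equal(rec$mean_spacing, rep(3.7, nrow(rec)), tolerance = 1e-9)
  # membership matches the script exactly
  truth <- run$truth[run$truth$frame == 1 & !is.na(run$truth$stack_id), ]
  detected <- lapply(rec$members[rec$frame == 1], sort)
  scripted <- lapply(split(truth$mb_id, truth$stack_id), sort)
  expect_setequal(lapply(detected, paste, collapse = ","),
                  lapply(scripted, paste, collapse = ","))
})

test_that("dispersed dyes yield no stacks", {
  scen <- scripted_scenario(2, 10, NULL, script_singletons(2, 10))
  rec <- detect_stacks(generate_scripted(scen)$trajectory)
  expect_identical(nrow(rec), 0L)
})

test_that("a scripted trimer reports its alternating orientation pattern", {
  script <- script_stacks(2, c(3), orientations = "antiparallel")
  scen <- scripted_scenario(2, 3, NULL, script)
  rec <- detect_stacks(generate_scripted(scen)$trajectory)
  expect_equal(rec$size, c(3L, 3L))
  for (ori in rec$orientations) {
    expect_equal(ori, c("antiparallel", "antiparallel"))
  }
  # parallel variant for contrast
  scen2 <- scripted_scenario(1, 3, NULL,
                             script_stacks(1, c(3), orientations = "parallel"))
  rec2 <- detect_stacks(generate_scripted(scen2)$trajectory)
  expect_equal(rec2$orientations[[1]], c("parallel", "parallel"))
})

test_that("every dye appears in exactly one component per frame", {
  traj <- generate_mc(mc_params(mb_count = 6, stacking_well_depth = 8,
                                n_sweeps = 200, cell_radius = 10, seed = 7L))
  rec <- detect_stacks(traj)
  expect_gt(nrow(rec), 0)
  for (f in unique(rec$frame)) {
    members <- unlist(rec$members[rec$frame == f])
    expect_identical(anyDuplicated(members), 0L)
    expect_true(all(members %in% mb_ids(traj)))
  }
})

test_that("detection is invariant under global rigid motion", {
  scen <- scripted_scenario(2, 7, "HS2",
                            script_stacks(2, c(2, 3), mb_count = 7, bound = TRUE))
  traj <- generate_scripted(scen)$trajectory
  R <- rotation_about(c(1, -1, 2), 1.1)
  moved <- transform_trajectory(traj, R, c(12, -30, 5))
  a <- detect_stacks(traj)
  b <- detect_stacks(moved)
  expect_equal(a$size, b$size)
  expect_equal(a$members, b$members)
  expect_equal(a$mean_spacing, b$mean_spacing, tolerance = 1e-6)
  expect_equal(a$orientations, b$orientations)
})

test_that("components agree with an exhaustive pairwise oracle", {
  # small Monte-Carlo systems with strong stacking produce mixed frames
  checked_nontrivial <- 0
  for (seed in c(2, 7, 21)) {
    traj <- generate_mc(mc_params(mb_count = 6, stacking_well_depth = 8,
                                  n_sweeps = 200, cell_radius = 10,
                                  seed = seed))
    rec <- detect_stacks(traj)
    stack_frames <- unique(rec$frame)
    checked_nontrivial <- checked_nontrivial + length(stack_frames)
    frames <- unique(c(1, utils::head(stack_frames, 1),
                       utils::tail(stack_frames, 1)))
    for (f in frames) {
      rings <- frame_rings(traj, f)
      comp <- brute_components(brute_stack_edges(rings), length(rings))
      oracle <- Filter(function(g) length(g) >= 2, comp)
      oracle_sets <- sort(unname(vapply(oracle, function(g)
        paste(sort(mb_ids(traj)[g]), collapse = ","), character(1))))
      got <- rec[rec$frame == f, ]
      got_sets <- sort(unname(vapply(got$members, function(m)
        paste(sort(m), collapse = ","), character(1))))
      expect_identical(got_sets, oracle_sets,
                       info = sprintf("seed %d frame %d", seed, f))
    }
  }
  expect_gt(checked_nontrivial, 0)  # the comparison was not vacuous
})

test_that("stack statistics summarize spacing and size mass correctly", {
  # persistent dimer: spacing equals the scripted 3.7 A on both summaries
  dimer <- generate_scripted(
    scripted_scenario(5, 2, NULL, script_stacks(5, c(2))))$trajectory
  st <- stack_statistics(dimer)
  expect_equal(st$mean_spacing, 3.7, tolerance = 1e-6)
  expect_equal(st$mean_spacing_dimers, 3.7, tolerance = 1e-6)

  # full 10-mer: all molecule mass at size 10
  tenmer <- generate_scripted(
    scripted_scenario(3, 10, NULL, script_stacks(3, c(10))))$trajectory
  st10 <- stack_statistics(tenmer)
  expect_equal(
    st10$size_histogram$molecule_fraction[st10$size_histogram$size == 10], 1.0)
  expect_identical(nrow(st10$size_histogram), 1L)

  # empty trajectory is rejected
  empty <- dimer
  empty$n_frames <- 0L
  expect_error(stack_statistics(empty), class = "gagstack_bad_trajectory")
})

test_that("tidy and glance expose the stack summary", {
  traj <- generate_scripted(
    scripted_scenario(2, 6, NULL,
                      script_stacks(2, c(2, 4),
                                    orientations = list("parallel",
                                                        rep("antiparallel", 3)))))$trajectory
  st <- stack_statistics(traj)
  td <- tidy(st)
  expect_true(all(c("frame", "stack_id", "size", "members", "mean_spacing",
                    "orientations") %in% names(td)))
  expect_type(td$members, "character")
  gl <- glance(st)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$parallel, 2L)      # one parallel pair per frame
  expect_equal(gl$antiparallel, 6L)  # three antiparallel pairs per frame
})
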