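test_that("frame filter keeps exactly the frames with enough bound dyes", {
  # three blocks with simultaneous counts 2, 3, 5
  n <- 9
  script <- dplyr::bind_rows(
    script_bound_fraction(3, 6, 1, n_bound = 2, baseline_bound = 2),
    script_bound_fraction(3, 6, 1, n_bound = 3, baseline_bound = 3) |>
      dplyr::mutate(frame = frame + 3),
    script_bound_fraction(3, 6, 1, n_bound = 5, baseline_bound = 5) |>
      dplyr::mutate(frame = frame + 6))
  traj <- generate_scripted(
    scripted_scenario(n, 6, "HP", script))$trajectory
  kept <- filter_frames(traj, min_bound = 3)
  expect_identical(attr(kept, "source_frames"), 4:9)
  all_kept <- filter_frames(traj, min_bound = 0)
  expect_identical(attr(all_kept, "source_frames"), 1:9)
  # brute-force agreement with the per-frame counts
  counts <- bound_counts(traj)
  expect_identical(attr(kept, "source_frames"),
                   counts$frame[counts$n_bound >= 3])
  # empty selection warns but does not fail
  expect_warning(none <- filter_frames(traj, min_bound = 6), "no frames")
  expect_identical(none$n_frames, 0L)
})

test_that("per-drug normalization reproduces the reference table rounding", {
  expect_equal(per_drug_normalize(
    data.frame(dG = -13.0, vdw = -15.1, eel = 44.6, esurf = -1.0,
               eel_egb = 3.1), n_drugs = 2)$dG_per, -6.5)
  ref <- mmgbsa_reference()
  out <- per_drug_normalize(ref)
  # the half-away-from-zero tie: -55.5 / 10 -> -5.6
  expect_equal(out$dG_per[out$system == "HS2/MB"], -5.6)
  expect_equal(out$eel_per[out$system == "HP/MB"], -326.3)
  expect_equal(out$dG_per[out$system == "HS3/MB"], -2.0)
  expect_equal(out$eel_per[out$system == "MB-MB"], 22.3)
  expect_error(per_drug_normalize(ref[, -2]), class = "gagstack_bad_argument")
  expect_error(per_drug_normalize(ref, n_drugs = 0),
               class = "gagstack_bad_argument")
})

test_that("printed per-drug cells are flagged only where arithmetic cannot explain them", {
  # every printed per-drug entry should be within half a printed decimal of
  # total / drug count, except the desulfated-heparin cells that were
  # normalized by the full dye count instead of the row's own drug count
  chk <- normalization_consistency()
  bad <- chk[!chk$consistent, ]
  expect_identical(unique(bad$system), "deHP/MB")
  expect_setequal(bad$component, c("dG", "eel", "eel_egb"))
  expect_equal(bad$raw_per[bad$component == "dG"], -0.4)        # arithmetic
  expect_equal(bad$printed_per[bad$component == "dG"], -0.3)    # printed
  expect_equal(bad$printed_per[bad$component == "eel"], -17.4)
  expect_equal(bad$raw_per[bad$component == "eel"], -174.1 / 7, tolerance = 1e-9)
})

test_that("component additivity holds except on the inconsistent reference row", {
  chk <- additivity_check(mmgbsa_reference())
  # the desulfated-heparin row's printed components do not close the
  # identity (residual -0.7 kcal/mol); every other row does within 0.15
  expect_identical(chk$system[!chk$additive], "deHP/MB")
  expect_equal(chk$residual[chk$system == "deHP/MB"], -0.7, tolerance = 1e-9)
  ok <- chk[chk$system != "deHP/MB", ]
  expect_true(all(ok$additive))
  expect_true(all(abs(ok$residual) <= 0.15))
  broken <- data.frame(dG = -10, vdw = -5, esurf = -2, eel_egb = -2)
  expect_false(additivity_check(broken)$additive)
  expect_equal(additivity_check(broken)$residual, -1)
})

test_that("surrogate components vanish at large separation", {
  far <- toy_trajectory(list(place_mb(c(0, 0, 0)),
                             place_mb(c(500, 0, 0))))
  e <- surrogate_energy(far)
  expect_lt(max(abs(unlist(e[, c("vdw", "eel", "esurf", "eel_egb", "dG")]))),
            1e-6)
})

test_that("surrogate electrostatics grow with the site inventory", {
  placements <- list(place_mb(c(10, 0, 10)), place_mb(c(-10, 0, 20)))
  e_hp <- surrogate_energy(toy_trajectory(placements, build_gag("HP", 10)))
  e_dehp <- surrogate_energy(toy_trajectory(placements, build_gag("deHP", 10)))
  expect_gt(abs(e_hp$eel), abs(e_dehp$eel))
  expect_lt(e_hp$eel, 0)
})

test_that("surrogate energy is invariant under dye relabeling and additive by construction", {
  a <- place_mb(c(8, 0, 5)); b <- place_mb(c(-6, 2, 12), long_axis = c(0, 1, 0))
  chain <- build_gag("HS1", 10)
  e1 <- surrogate_energy(toy_trajectory(list(a, b), chain))
  e2 <- surrogate_energy(toy_trajectory(list(b, a), chain))
  expect_equal(e1[, -1], e2[, -1], tolerance = 1e-9)
  expect_equal(e1$dG, e1$vdw + e1$esurf + e1$eel_egb, tolerance = 1e-12)
  expect_true(all(additivity_check(e1)$additive))
})
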