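test_that("dye-site distance is the minimum over the two terminal nitrogens", {
  chain <- build_gag("CS4", 2)
  s <- chain$sites[chain$sites$site_type == "4-O-sulfate", ]
  anchor <- c(s$x, s$y, s$z)
  u <- c(cos(s$azimuth), sin(s$azimuth), 0)
  L <- max(abs(mb_template()$x))
  # N1 exactly 8.0 A from the sulfate sulfur, N2 much farther
  pl <- place_mb(centroid = anchor + (8 + L) * u, long_axis = u)
  traj <- toy_trajectory(list(pl), chain)
  d <- mb_site_distances(traj)
  expect_equal(d$distance[d$site_id == s$site_id], 8.0, tolerance = 1e-9)

  # both nitrogens equidistant: place the long axis perpendicular to the
  # anchor direction so the two N are symmetric about the centroid
  perp <- c(-u[2], u[1], 0)
  pl2 <- place_mb(centroid = anchor + 6 * u, long_axis = perp)
  d2 <- mb_site_distances(toy_trajectory(list(pl2), chain))
  expect_equal(d2$distance[d2$site_id == s$site_id],
               sqrt(36 + L^2), tolerance = 1e-9)
})

test_that("scripted per-type contact fraction is exact (30.2% scenario)", {
  scen <- scripted_scenario(1000, 1, "CS4",
                            script_bound_fraction(1000, 1, 0.302,
                                                  baseline_bound = 0),
                            site_type = "4-O-sulfate")
  traj <- generate_scripted(scen)$trajectory
  cf <- contact_fractions(traj)
  expect_equal(cf$fraction_pct[cf$site_type == "4-O-sulfate"], 30.2)
  expect_equal(cf$fraction_pct[cf$site_type == "carboxylate"], 0)
  expect_true(is.na(cf$fraction_pct[cf$site_type == "N-sulfate"]))
})

test_that("contact fractions match exhaustive enumeration on a toy run", {
  scen <- scripted_scenario(5, 3, "HS1",
                            script_bound_fraction(5, 3, 0.6, n_bound = 2,
                                                  baseline_bound = 1))
  traj <- generate_scripted(scen)$trajectory
  cutoff <- 8
  # oracle: triple loop over frames, dyes and sites on raw coordinates
  chain_sites <- traj$topology[traj$topology$role %in%
                                 c("sulfate_S", "carboxylate_C"), ]
  M <- as.matrix(traj$coords[, c("x", "y", "z")])
  rows <- gagstack:::.traj_rows(traj)
  hits <- list()
  for (f in 1:5) {
    base <- (f - 1) * traj$n_atoms
    for (ty in unique(chain_sites$site_type)) {
      any_hit <- FALSE
      for (id in mb_ids(traj)) {
        np <- M[base + rows$mb_n[[id]], , drop = FALSE]
        for (srow in which(traj$topology$site_type %in% ty)) {
          a <- M[base + srow, ]
          dmin <- min(sqrt(rowSums(sweep(np, 2, a)^2)))
          if (dmin < cutoff) any_hit <- TRUE
        }
      }
      hits[[ty]] <- c(hits[[ty]], any_hit)
    }
  }
  cf <- contact_fractions(traj, cutoff)
  for (ty in names(hits)) {
    expect_equal(cf$fraction_pct[cf$site_type == ty], 100 * mean(hits[[ty]]),
                 info = ty)
  }
})

test_that("contact fractions are monotone in the cutoff", {
  scen <- scripted_scenario(4, 4, "HP",
                            script_bound_fraction(4, 4, 0.5, n_bound = 3,
                                                  baseline_bound = 1))
  traj <- generate_scripted(scen)$trajectory
  prev <- NULL
  for (cut in c(3, 5, 8, 12, 30)) {
    cf <- contact_fractions(traj, cut)
    vals <- cf$fraction_pct[!is.na(cf$fraction_pct)]
    if (!is.null(prev)) expect_true(all(vals >= prev - 1e-12))
    prev <- vals
  }
  expect_error(contact_fractions(traj, 0), class = "gagstack_bad_argument")
})

test_that("desulfated heparin reports no sulfate columns at all", {
  scen <- scripted_scenario(3, 2, "deHP",
                            script_bound_fraction(3, 2, 1, n_bound = 1,
                                                  baseline_bound = 1))
  cf <- contact_fractions(generate_scripted(scen)$trajectory)
  sulf <- cf[cf$site_type != "carboxylate", ]
  expect_true(all(is.na(sulf$fraction_pct)))
  expect_true(all(sulf$n_sites == 0))
  expect_false(is.na(cf$fraction_pct[cf$site_type == "carboxylate"]))
})

test_that("binding summary reports the max simultaneous count and its fraction", {
  # 10 dyes bound in 42% of frames, 9 otherwise
  scen <- scripted_scenario(100, 10, "HP", script_bound_fraction(100, 10, 0.42))
  bs <- binding_summary(generate_scripted(scen)$trajectory)
  expect_identical(bs$n_mb, 10L)
  expect_equal(bs$t, 0.42)
  expect_false(bs$no_binding)
  expect_equal(sum(bs$distribution$fraction), 1)
  expect_equal(bs$distribution$fraction_at_least[bs$distribution$n_bound == 10],
               0.42)

  # never bound
  scen0 <- scripted_scenario(5, 3, "HP", script_singletons(5, 3))
  bs0 <- binding_summary(generate_scripted(scen0)$trajectory)
  expect_identical(bs0$n_mb, 0L)
  expect_true(bs0$no_binding)
  expect_equal(bs0$t, 1.0)

  # always exactly 7 of 10
  scen7 <- scripted_scenario(6, 10, "HS2",
                             script_bound_fraction(6, 10, 1, n_bound = 7,
                                                   baseline_bound = 7))
  bs7 <- binding_summary(generate_scripted(scen7)$trajectory)
  expect_identical(bs7$n_mb, 7L)
  expect_equal(bs7$t, 1.0)
  expect_identical(nrow(tidy(bs7)), 1L)
  expect_identical(glance(bs7)$n_mb, 7L)
})

test_that("chain bending ratio is 1 when straight and matches the arc closed form", {
  straight <- generate_scripted(
    scripted_scenario(2, 1, "HP", script_singletons(2, 1)))$trajectory
  cb <- chain_bending(straight)
  expect_equal(cb$ratio, rep(1.0, 2), tolerance = 1e-12)

  # semicircular arc: dp beads of arc spacing 5 on radius 45/pi
  R <- 45 / pi
  chain_bent <- build_gag("HP", 10, bend_radius = R)
  traj_bent <- toy_trajectory(list(place_mb(c(200, 0, 0))), chain_bent)
  ratio <- chain_bending(traj_bent)$ratio[1]
  step <- 5 / R
  closed_form <- (2 * R) / (9 * 2 * R * sin(step / 2))
  expect_equal(ratio, closed_form, tolerance = 1e-9)
  expect_equal(ratio, 2 / pi, tolerance = 0.02)  # discretization limit
  expect_lt(ratio, 1)
})
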