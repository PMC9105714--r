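#' Reference scripted scenario for a GAG preset
#'
#' Builds the scripted scenario that realizes, with exact ground truth, the
#' reference binding behaviour of a preset: the dyes form persistent
#' stacks (two stacks of four and six for heparin, a single stack of the
#' reference simultaneous-binder count otherwise) which are in contact
#' with the chain for exactly the reference time fraction `t` of frames
#' and parked away from it otherwise. Feeding the generated trajectory
#' through the contact analysis and [compute_D()] therefore reproduces the
#' reference `(n_MB, t, D)` row by construction.
#'
#' @param preset GAG preset name.
#' @param n_frames number of frames (a multiple of 50 keeps the reference
#'   fractions exactly representable).
#' @param dp chain length.
#' @param seed recorded seed.
#' @return an [scripted_scenario()] object.
#' @export
reference_scenario <- function(preset, n_frames = 100, dp = 10, seed = 1L) {
  ref <- binding_reference()
  ref <- ref[ref$preset == preset, ]
  if (!nrow(ref)) {
    .gs_abort(sprintf("no reference row for preset %s", preset),
              "gagstack_bad_argument")
  }
  t_ref <- if (is.na(ref$t)) 0.5 else ref$t  # desulfated chain: no reference t
  mb_count <- 10L
  sizes <- if (preset == "HP") c(4L, 6L) else ref$n_mb
  k <- as.integer(round(t_ref * n_frames))
  bound_part <- script_stacks(k, sizes, mb_count = mb_count, bound = TRUE)
  free_part <- script_stacks(n_frames - k, sizes, mb_count = mb_count,
                             bound = FALSE)
  free_part$frame <- free_part$frame + k
  scripted_scenario(n_frames, mb_count = mb_count, gag_preset = preset,
                    script = dplyr::bind_rows(bound_part, free_part),
                    dp = dp, seed = seed)
}

#' Run configuration
#'
#' Flat key-value configuration of a full pipeline run. All thresholds are
#' in Angstrom (angles in degrees); every output table carries the
#' configuration hash and seed in its header.
#'
#' @param gag_preset GAG preset name.
#' @param mode `"scripted"` (reference scenario) or `"mc"` (Monte Carlo).
#' @param mb_count number of dyes (MC mode; scripted reference uses 10).
#' @param frames number of frames.
#' @param seed run seed; stage generators use [stage_seed()] children.
#' @param cutoff contact cutoff.
#' @param d_max,angle_max,lateral_max stack-detection thresholds.
#' @param min_bound frame filter threshold for energy scoring.
#' @param scenario optional [scripted_scenario()] overriding the reference
#'   scenario in scripted mode.
#' @return list of class `run_config`.
#' @export
run_config <- function(gag_preset = "HP", mode = c("scripted", "mc"),
                       mb_count = 10, frames = 100, seed = 1L, cutoff = 8,
                       d_max = 4.5, angle_max = 30, lateral_max = 3.0,
                       min_bound = 3, scenario = NULL) {
  mode <- match.arg(mode)
  for (v in c("cutoff", "d_max", "angle_max", "lateral_max")) {
    .check_positive(get(v), v)
  }
  structure(list(gag_preset = gag_preset, mode = mode, mb_count = mb_count,
                 frames = frames, seed = as.integer(seed), cutoff = cutoff,
                 d_max = d_max, angle_max = angle_max,
                 lateral_max = lateral_max, min_bound = min_bound,
                 scenario = scenario),
            class = "run_config")
}

# deterministic short hash of the configuration (provenance headers)
.config_hash <- function(config) {
  s <- paste(deparse(config[setdiff(names(config), "scenario")]), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) a trajectory, runs stack detection, contact
#' analysis, the D statistic, surrogate energy scoring on the frames that
#' pass the bound-count filter, and chain bending, and writes one TSV per
#' stage plus a JSON run manifest. Deterministic given the configuration
#' seed.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @param prefix file name prefix.
#' @param traj optional pre-built [mb_trajectory()]; skips generation.
#' @return invisibly, a list with the result tables and output paths.
#' @export
run_pipeline <- function(config, out_dir = ".", prefix = "run", traj = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- .config_hash(config)
  hdr <- c(sprintf("seed=%d", config$seed), sprintf("config=%s", hash))
  p <- function(name) file.path(out_dir, paste0(prefix, "_", name))

  if (is.null(traj)) {
    if (config$mode == "scripted") {
      scen <- config$scenario %||%
        reference_scenario(config$gag_preset, n_frames = config$frames,
                           seed = stage_seed(config$seed, "simulate"))
      traj <- generate_scripted(scen)$trajectory
    } else {
      traj <- generate_mc(mc_params(
        mb_count = config$mb_count, gag_preset = config$gag_preset,
        n_sweeps = config$frames,
        seed = stage_seed(config$seed, "simulate")))
    }
  }
  message(sprintf("pipeline: %d frames, %d dyes entering analysis",
                  traj$n_frames, length(mb_ids(traj))))

  stats <- stack_statistics(traj, config$d_max, config$angle_max,
                            config$lateral_max)
  .write_tsv(tidy(stats), p("stacks.tsv"), header = hdr)

  contacts <- contact_fractions(traj, config$cutoff)
  .write_tsv(contacts, p("contacts.tsv"), header = hdr)

  summ <- binding_summary(traj, config$cutoff)
  dtab <- d_table(setNames(list(summ), config$gag_preset))
  .write_tsv(dtab, p("d_table.tsv"), header = hdr)

  kept <- filter_frames(traj, config$min_bound, config$cutoff)
  message(sprintf("pipeline: %d of %d frames pass the bound-count filter (>= %d)",
                  kept$n_frames, traj$n_frames, config$min_bound))
  energy <- if (kept$n_frames > 0) {
    surrogate_energy(kept) |>
      dplyr::mutate(frame = attr(kept, "source_frames")[.data$frame])
  } else {
    tibble::tibble(frame = integer(0), vdw = numeric(0), eel = numeric(0),
                   esurf = numeric(0), eel_egb = numeric(0), dG = numeric(0))
  }
  .write_tsv(energy, p("energy.tsv"), header = hdr)

  bending <- chain_bending(traj)
  .write_tsv(bending, p("bending.tsv"), header = hdr)

  manifest <- list(
    config = config[setdiff(names(config), "scenario")],
    config_hash = hash,
    seed = config$seed,
    n_frames = traj$n_frames,
    frames_after_filter = kept$n_frames,
    package_version = as.character(utils::packageVersion("gagstack")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(trajectory = traj, stacks = stats, contacts = contacts,
                 binding = summ, d_table = dtab, energy = energy,
                 bending = bending,
                 paths = vapply(c("stacks.tsv", "contacts.tsv", "d_table.tsv",
                                  "energy.tsv", "bending.tsv", "manifest.json"),
                                p, character(1))))
}
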