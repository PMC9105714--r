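#' @title Glycosaminoglycan decasaccharide presets
#' @description
#' Seven sulfation presets of linear GAG chains built from repeating
#' disaccharide units (hexosamine + uronic acid). Per disaccharide:
#'
#' * `HP`   heparin: N-sulfate + 6-O-sulfate on the hexosamine,
#'   2-O-sulfate + carboxylate on the uronic acid (3 sulfates).
#' * `deHP` fully desulfated heparin: carboxylate only.
#' * `CS4`  chondroitin 4-sulfate: one 4-O-sulfate + carboxylate.
#' * `CS6`  chondroitin 6-sulfate: one 6-O-sulfate + carboxylate.
#' * `HS1`  heparan sulfate (GlcNS-IdoA(2S)): N-sulfate + 2-O-sulfate.
#' * `HS2`  heparan sulfate (GlcNS(6S)-IdoA): N-sulfate + 6-O-sulfate.
#' * `HS3`  heparan sulfate (GlcNAc(6S)-IdoA(2S)): 6-O-sulfate + 2-O-sulfate.
#'
#' Every uronic residue carries exactly one carboxylate, so the three HS
#' presets all have net charge -3 per disaccharide (2 sulfates + 1
#' carboxylate) while differing in sulfation pattern.
#' @name gag_presets
NULL

# per-disaccharide site plan: list(hexosamine = types, uronic = types)
.gag_repeat <- list(
  HP   = list(hexosamine = c("N-sulfate", "6-O-sulfate"),
              uronic     = c("2-O-sulfate", "carboxylate")),
  deHP = list(hexosamine = character(0),
              uronic     = "carboxylate"),
  CS4  = list(hexosamine = "4-O-sulfate",
              uronic     = "carboxylate"),
  CS6  = list(hexosamine = "6-O-sulfate",
              uronic     = "carboxylate"),
  HS1  = list(hexosamine = "N-sulfate",
              uronic     = c("2-O-sulfate", "carboxylate")),
  HS2  = list(hexosamine = c("N-sulfate", "6-O-sulfate"),
              uronic     = "carboxylate"),
  HS3  = list(hexosamine = "6-O-sulfate",
              uronic     = c("2-O-sulfate", "carboxylate"))
)

#' Names of the available GAG presets
#' @return character vector of the seven preset names.
#' @export
gag_preset_names <- function() names(.gag_repeat)

#' Site types recognized by the contact analysis
#' @return character vector of the five anionic site types.
#' @export
site_type_levels <- function() {
  c("N-sulfate", "4-O-sulfate", "6-O-sulfate", "2-O-sulfate", "carboxylate")
}

# geometry constants of the coarse chain scaffold (Angstrom)
.BB_SPACING   <- 5.0   # backbone bead spacing along the helical axis
.SITE_RADIUS  <- 4.0   # radial offset of anionic sites from the axis
.SITE_SPREAD  <- 40 * pi / 180  # azimuthal fan between sites on one residue

#' Build a coarse GAG chain model
#'
#' Constructs a rigid, coarse-grained model of a GAG oligosaccharide: one
#' backbone bead per monosaccharide every 5.0 Angstrom along a straight
#' (or uniformly bent) axis, with the anionic sites of each residue offset
#' 4.0 Angstrom radially, residues alternating sides of the axis. Odd
#' residues are hexosamines, even residues uronic acids; each uronic acid
#' carries one carboxylate whose anchor atom is the carboxyl carbon, each
#' sulfate's anchor is its sulfur. Only the labeled site and backbone
#' positions matter to the downstream analyses; sugar-ring internal
#' geometry is intentionally not modeled.
#'
#' @param preset one of [gag_preset_names()].
#' @param dp even degree of polymerization counted in monosaccharides
#'   (dp = 10 is five disaccharides, the default).
#' @param bend_radius radius (Angstrom) of a circular arc onto which the
#'   chain axis is bent, preserving the 5.0 Angstrom bead spacing as arc
#'   length; `Inf` (default) gives a straight chain.
#' @return an object of class `gag_chain`: a list with `preset`, `dp`,
#'   `backbone` (tibble: residue_index, residue_class, x, y, z) and
#'   `sites` (tibble: site_id, site_type, residue_index, anchor_label,
#'   x, y, z).
#' @examples
#' hp <- build_gag("HP", 10)
#' count_anionic_sites(hp)
#' @export
build_gag <- function(preset, dp = 10, bend_radius = Inf) {
  preset <- as.character(preset)
  if (length(preset) != 1 || !preset %in% names(.gag_repeat)) {
    .gs_abort(sprintf(
      "unknown GAG preset %s; valid presets are: %s",
      deparse(preset), paste(names(.gag_repeat), collapse = ", ")),
      "gagstack_unknown_preset")
  }
  if (!is.numeric(dp) || length(dp) != 1 || dp < 2 || dp %% 2 != 0) {
    .gs_abort(sprintf("`dp` must be an even integer >= 2, got %s", format(dp)),
              "gagstack_bad_dp")
  }
  .check_positive(bend_radius, "bend_radius")

  rep_plan <- .gag_repeat[[preset]]
  res_class <- rep(c("hexosamine", "uronic"), dp / 2)
  arc <- (seq_len(dp) - 1) * .BB_SPACING  # arc-length position of each bead

  axis_pos <- .bend_points(arc, bend_radius)      # bead centers
  frames   <- .bend_frames(arc, bend_radius)      # local (radial1, radial2) dirs

  backbone <- tibble::tibble(
    residue_index = seq_len(dp),
    residue_class = res_class,
    x = axis_pos[, 1], y = axis_pos[, 2], z = axis_pos[, 3]
  )

  sites <- purrr::map_dfr(seq_len(dp), function(i) {
    types <- rep_plan[[res_class[i]]]
    if (length(types) == 0) return(NULL)
    k <- length(types)
    offsets <- if (k == 1) 0 else seq(-.SITE_SPREAD, .SITE_SPREAD, length.out = k)
    phi <- (i - 1) * pi + offsets  # residues alternate sides of the axis
    dir <- outer(cos(phi), frames$r1[i, ]) + outer(sin(phi), frames$r2[i, ])
    pos <- sweep(dir * .SITE_RADIUS, 2, axis_pos[i, ], "+")
    tibble::tibble(
      site_type = types,
      residue_index = i,
      anchor_label = ifelse(types == "carboxylate", "carboxylate_C", "sulfate_S"),
      azimuth = phi,
      x = pos[, 1], y = pos[, 2], z = pos[, 3]
    )
  })
  sites <- dplyr::arrange(sites, .data$residue_index,
                          match(.data$site_type, site_type_levels()))
  sites <- dplyr::mutate(sites, site_id = dplyr::row_number(), .before = 1)

  structure(
    list(preset = preset, dp = dp, bend_radius = bend_radius,
         backbone = backbone, sites = sites,
         net_charge_per_disaccharide = -(length(rep_plan$hexosamine) +
                                           length(rep_plan$uronic))),
    class = "gag_chain")
}

# map arc-length positions onto a straight line (z axis) or a circular arc
# of radius R in the x-z plane; returns n x 3 bead positions
.bend_points <- function(arc, R) {
  if (is.infinite(R)) {
    cbind(0, 0, arc)
  } else {
    th <- arc / R
    cbind(R * (1 - cos(th)), 0, R * sin(th))
  }
}

# local radial directions perpendicular to the chain axis at each bead
.bend_frames <- function(arc, R) {
  n <- length(arc)
  if (is.infinite(R)) {
    list(r1 = matrix(rep(c(1, 0, 0), each = n), n),
         r2 = matrix(rep(c(0, 1, 0), each = n), n))
  } else {
    th <- arc / R
    list(r1 = cbind(cos(th), 0, -sin(th)),
         r2 = matrix(rep(c(0, 1, 0), each = n), n))
  }
}

#' Count anionic sites per type
#'
#' @param chain a [build_gag()] chain.
#' @return tibble with columns `site_type` (all five recognized types, in
#'   canonical order) and `n` (0 for types absent from the preset), plus a
#'   `n_so3` attribute giving the total sulfate count.
#' @export
count_anionic_sites <- function(chain) {
  stopifnot(inherits(chain, "gag_chain"))
  counts <- chain$sites |>
    dplyr::count(site_type = factor(.data$site_type, site_type_levels()),
                 .drop = FALSE) |>
    dplyr::mutate(site_type = as.character(.data$site_type))
  out <- tibble::as_tibble(counts)
  attr(out, "n_so3") <- sum(out$n[out$site_type != "carboxylate"])
  out
}

#' Number of sulfate groups in a chain
#' @param chain a [build_gag()] chain.
#' @return integer sulfate count (n_SO3).
#' @export
n_sulfates <- function(chain) {
  stopifnot(inherits(chain, "gag_chain"))
  sum(chain$sites$site_type != "carboxylate")
}

#' @export
print.gag_chain <- function(x, ...) {
  cat(sprintf("<gag_chain> %s dp%d: %d anionic sites (%d sulfates, %d carboxylates)\n",
              x$preset, x$dp, nrow(x$sites), n_sulfates(x),
              sum(x$sites$site_type == "carboxylate")))
  invisible(x)
}

# ---- methylene blue template ------------------------------------------------

.MB_CC <- 1.39       # aromatic C-C bond length
.MB_N_EXT <- 1.35    # terminal N beyond the outermost ring vertex

#' Rigid planar template of the methylene blue cation
#'
#' A coarse template of the tricyclic phenothiazine ring system: three
#' linearly fused benzene-like hexagons (C-C 1.39 Angstrom) lying exactly in
#' a plane, with the two terminal dimethylamino nitrogens placed 1.35
#' Angstrom beyond the outermost ring vertices on the long axis. The long
#' axis runs along template x, the ring normal along template z, and the two
#' nitrogens are symmetric about the template center. The formal +1 charge
#' is carried as an attribute; downstream analyses use only the plane, the
#' long axis and the nitrogen positions.
#'
#' @return tibble with columns `atom_label`, `role` (`"ring"` or
#'   `"terminal_N"`), `x`, `y`, `z`, carrying attribute `charge = 1`.
#' @export
mb_template <- function() {
  a <- .MB_CC
  h <- a * sqrt(3) / 2
  # three fused hexagons (flat-top orientation), ring centers at x = 0, +-2h
  verts <- list()
  for (cx in c(-2 * h, 0, 2 * h)) {
    verts[[length(verts) + 1]] <-
      cbind(x = cx + c(h, 0, -h, -h, 0, h),
            y = c(a / 2, a, a / 2, -a / 2, -a, -a / 2))
  }
  v <- unique(round(do.call(rbind, verts), 9))
  ring <- tibble::tibble(
    atom_label = paste0("C", seq_len(nrow(v))),
    role = "ring", x = v[, "x"], y = v[, "y"], z = 0
  )
  xn <- 3 * h + .MB_N_EXT
  nitro <- tibble::tibble(
    atom_label = c("N1", "N2"), role = "terminal_N",
    x = c(-xn, xn), y = 0, z = 0
  )
  out <- dplyr::bind_rows(ring, nitro)
  attr(out, "charge") <- 1L
  out
}

# internal: template coordinates as a matrix + row roles (computed once)
.mb_template_mat <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tpl <- mb_template()
      cache <<- list(
        xyz = as.matrix(tpl[, c("x", "y", "z")]),
        labels = tpl$atom_label,
        roles = tpl$role,
        ring_rows = which(tpl$role == "ring"),
        n_rows = which(tpl$role == "terminal_N"),
        half_length = max(abs(tpl$x))
      )
    }
    cache
  }
})
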