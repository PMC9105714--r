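#' Write and read trajectories
#'
#' Two plain-text encodings are supported. The PDB dialect writes one
#' `MODEL`/`ENDMDL` block per frame of `HETATM` records with chain `A` for
#' the GAG and chains `B`, `C`, ... for the dye molecules, coordinates at
#' the format's 3-decimal precision. The extended XYZ dialect writes an
#' atom count line, a comment line `frame=<i>`, and `molecule_id:atom_label
#' x y z` rows. Atom identity is carried by the topology sidecar (see
#' [write_topology()]); atoms are written in canonical topology order and
#' the reader validates label agreement and per-frame atom counts.
#'
#' @param traj an [mb_trajectory()].
#' @param path output file.
#' @param format `"pdb"` or `"xyz"` (default guessed from the extension).
#' @param header optional character vector of provenance lines (written as
#'   `REMARK` records in PDB, `#` lines before the first frame in XYZ).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = NULL, header = NULL) {
  stopifnot(inherits(traj, "mb_trajectory"))
  format <- format %||% (if (grepl("\\.xyz$", path)) "xyz" else "pdb")
  format <- match.arg(format, c("pdb", "xyz"))
  topo <- traj$topology
  n <- traj$n_atoms
  M <- as.matrix(traj$coords[, c("x", "y", "z")])
  lines <- character(0)
  if (format == "pdb") {
    mols <- unique(topo$molecule_id)
    mb <- mols[grepl("^MB", mols)]
    if (length(mb) > 25) {
      .gs_abort("PDB dialect supports at most 25 dye chains", "gagstack_bad_argument")
    }
    chain_of <- setNames(c(rep("A", length(mols) - length(mb)),
                           LETTERS[1 + seq_along(mb)]),
                         c(setdiff(mols, mb), mb))
    resseq <- ifelse(is.na(topo$residue_index), 1L, topo$residue_index)
    resname <- ifelse(topo$molecule_id == "GAG", "GAG", "MBD")
    elem <- dplyr::case_when(
      topo$role == "sulfate_S" ~ "S",
      topo$role == "terminal_N" ~ "N",
      TRUE ~ "C")
    atom_fmt <- "HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s"
    hdr <- if (length(header)) paste("REMARK   1", header)
    blocks <- vapply(seq_len(traj$n_frames), function(f) {
      base <- (f - 1) * n
      rows <- sprintf(atom_fmt, seq_len(n), substr(topo$atom_label, 1, 4),
                      resname, chain_of[topo$molecule_id], resseq,
                      M[base + seq_len(n), 1], M[base + seq_len(n), 2],
                      M[base + seq_len(n), 3], elem)
      paste(c(sprintf("MODEL     %4d", f), rows, "ENDMDL"), collapse = "\n")
    }, character(1))
    lines <- c(hdr, blocks, "END")
  } else {
    hdr <- if (length(header)) paste("#", header)
    blocks <- vapply(seq_len(traj$n_frames), function(f) {
      base <- (f - 1) * n
      rows <- sprintf("%s:%s %.3f %.3f %.3f",
                      topo$molecule_id, topo$atom_label,
                      M[base + seq_len(n), 1], M[base + seq_len(n), 2],
                      M[base + seq_len(n), 3])
      paste(c(as.character(n), sprintf("frame=%d", f), rows), collapse = "\n")
    }, character(1))
    lines <- c(hdr, blocks)
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_trajectory
#' @param topology_path path of the topology sidecar TSV.
#' @export
read_trajectory <- function(path, topology_path, format = NULL) {
  topo <- read_topology(topology_path)
  format <- format %||% (if (grepl("\\.xyz$", path)) "xyz" else "pdb")
  format <- match.arg(format, c("pdb", "xyz"))
  txt <- readLines(path)
  n <- nrow(topo)
  key <- paste0(topo$molecule_id, ":", topo$atom_label)

  if (format == "pdb") {
    starts <- grep("^MODEL", txt)
    ends <- grep("^ENDMDL", txt)
    if (!length(starts)) {
      .gs_abort("no MODEL records found", "gagstack_bad_file")
    }
    if (length(ends) < length(starts)) {
      .gs_abort(sprintf("truncated trajectory: frame %d has no ENDMDL",
                        length(starts)), "gagstack_bad_file")
    }
    frames <- purrr::map(seq_along(starts), function(f) {
      block <- txt[(starts[f] + 1):(ends[f] - 1)]
      block <- block[grepl("^(HETATM|ATOM )", block)]
      if (length(block) != n) {
        .gs_abort(sprintf(
          "atom count mismatch at frame %d: %d atoms, topology has %d",
          f, length(block), n), "gagstack_bad_file")
      }
      lab <- trimws(substr(block, 13, 16))
      if (!all(lab == topo$atom_label)) {
        .gs_abort(sprintf("atom labels at frame %d do not match the topology", f),
                  "gagstack_bad_file")
      }
      cbind(as.numeric(substr(block, 31, 38)),
            as.numeric(substr(block, 39, 46)),
            as.numeric(substr(block, 47, 54)))
    })
  } else {
    txt <- txt[!grepl("^#", txt)]
    frames <- list()
    i <- 1; f <- 0
    while (i <= length(txt)) {
      if (!grepl("^\\s*\\d+\\s*$", txt[i])) { i <- i + 1; next }
      nat <- as.integer(txt[i]); f <- f + 1
      if (nat != n) {
        .gs_abort(sprintf(
          "atom count mismatch at frame %d: %d atoms, topology has %d",
          f, nat, n), "gagstack_bad_file")
      }
      if (i + 1 + nat > length(txt)) {
        .gs_abort(sprintf("truncated trajectory at frame %d", f),
                  "gagstack_bad_file")
      }
      body <- txt[(i + 2):(i + 1 + nat)]
      parts <- strsplit(body, "\\s+")
      lab <- vapply(parts, `[[`, character(1), 1)
      if (!all(lab == key)) {
        .gs_abort(sprintf("atom labels at frame %d do not match the topology", f),
                  "gagstack_bad_file")
      }
      frames[[f]] <- cbind(as.numeric(vapply(parts, `[[`, character(1), 2)),
                           as.numeric(vapply(parts, `[[`, character(1), 3)),
                           as.numeric(vapply(parts, `[[`, character(1), 4)))
      i <- i + 2 + nat
    }
    if (!length(frames)) .gs_abort("no frames found", "gagstack_bad_file")
  }

  coords <- purrr::map_dfr(seq_along(frames), function(f) {
    tibble::tibble(frame = f, molecule_id = topo$molecule_id,
                   atom_label = topo$atom_label,
                   x = frames[[f]][, 1], y = frames[[f]][, 2],
                   z = frames[[f]][, 3])
  })
  mb_trajectory(coords, topo)
}

#' Write and read the topology sidecar
#'
#' TSV with columns `molecule_id`, `atom_label`, `role`, `site_type`,
#' `residue_index` (`-` for absent cells).
#'
#' @param traj an [mb_trajectory()] (or a topology tibble).
#' @param path file path.
#' @return `path` / topology tibble.
#' @export
write_topology <- function(traj, path) {
  topo <- if (inherits(traj, "mb_trajectory")) traj$topology else traj
  .write_tsv(topo, path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                        na = "-",
                        col_types = readr::cols(
                          molecule_id = readr::col_character(),
                          atom_label = readr::col_character(),
                          role = readr::col_character(),
                          site_type = readr::col_character(),
                          residue_index = readr::col_integer()))
  need <- c("molecule_id", "atom_label", "role")
  if (!all(need %in% names(df))) {
    .gs_abort("topology sidecar must have molecule_id, atom_label, role columns",
              "gagstack_bad_file")
  }
  tibble::as_tibble(df)
}

# TSV writer used for every table output: "." decimal, "-" for absent
# cells, optional "# " provenance header lines
.write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste("#", header), con)
  df <- as.data.frame(df)
  for (cc in names(df)) {
    if (is.list(df[[cc]])) {
      df[[cc]] <- vapply(df[[cc]], paste, character(1), collapse = ",")
    }
  }
  df[] <- lapply(df, function(x) {
    out <- if (is.numeric(x)) format(x, trim = TRUE, digits = 10) else as.character(x)
    out[is.na(x)] <- "-"
    out
  })
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    writeLines(do.call(paste, c(unname(df), sep = "\t")), con)
  }
  invisible(path)
}
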