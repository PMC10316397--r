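# Multi-frame extended-XYZ I/O for trajectories, plus fixed-width PDB
# export of single structures. Extended XYZ is self-describing: each frame
# is a particle count, a key=value comment line (lattice, time, metadata),
# then one row per particle with species, position and particle id.

#' Write a trajectory as multi-frame extended XYZ
#'
#' Each frame is written as
#' `natoms` / comment / `species x y z id` rows. The comment line carries
#' `Lattice`, `Properties=species:S:1:pos:R:3:id:I:1`, `Time`, and the
#' trajectory metadata (`replicate_id`, `seed`, `fingerprint`). Coordinates
#' are written with 6 decimals, so a write/read round trip is exact to
#' 1e-6 Angstrom.
#'
#' @param traj A `pore_trajectory` (or any tibble with columns `frame`,
#'   `time`, `particle_id`, `species`, `x`, `y`, `z`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_trajectory()]
#' @export
write_trajectory <- function(traj, path) {
  frames <- unique(traj$frame)
  if (length(frames) == 0L) rlang::abort("no frames: trajectory is empty.")
  box <- attr(traj, "box", exact = TRUE) %||% c(0, 0, 0)
  rep_id <- attr(traj, "replicate_id", exact = TRUE) %||% NA_integer_
  seed <- attr(traj, "seed", exact = TRUE) %||% NA_integer_
  fp <- attr(traj, "fingerprint", exact = TRUE) %||% "none"

  ord <- order(traj$frame, traj$particle_id)
  tr <- traj[ord, , drop = FALSE]
  sp <- split(seq_len(nrow(tr)), tr$frame)

  blocks <- purrr::map(sp, function(ix) {
    n <- length(ix)
    tm <- tr$time[ix[1]]
    header <- sprintf(
      paste0('Lattice="%g 0.0 0.0 0.0 %g 0.0 0.0 0.0 %g" ',
             "Properties=species:S:1:pos:R:3:id:I:1 Time=%.6f ",
             "replicate_id=%s seed=%s fingerprint=%s"),
      box[1], box[2], box[3], tm, rep_id, seed, fp)
    rows <- sprintf("%s %.6f %.6f %.6f %d",
                    tr$species[ix], tr$x[ix], tr$y[ix], tr$z[ix],
                    tr$particle_id[ix])
    c(as.character(n), header, rows)
  })
  writeLines(unlist(blocks, use.names = FALSE), path)
  invisible(path)
}

#' Read a multi-frame extended-XYZ trajectory
#'
#' Parses files written by [write_trajectory()] (and plain extended XYZ
#' with a trailing integer id column). The particle set must be identical
#' across frames and frame times strictly increasing.
#'
#' @param path File path.
#' @return A `pore_trajectory` tibble.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) rlang::abort(sprintf("no frames in '%s'.", path))
  parse_fail <- function(frame, line_no, why) {
    rlang::abort(sprintf("Malformed trajectory '%s' at frame %d, line %d: %s",
                         path, frame, line_no, why))
  }
  out <- list()
  pos <- 1L
  frame <- 0L
  box <- c(NA_real_, NA_real_, NA_real_)
  rep_id <- NA_integer_; seed <- NA_integer_; fp <- NA_character_
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    frame <- frame + 1L
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n) || n < 0) parse_fail(frame, pos, "expected particle count")
    if (pos + 1L + n > length(lines) + 0L) {
      parse_fail(frame, pos, sprintf("frame truncated (needs %d particle rows)", n))
    }
    header <- lines[pos + 1L]
    lat <- regmatches(header, regexec('Lattice="([^"]*)"', header))[[1]]
    if (length(lat) == 2L) {
      lv <- as.numeric(strsplit(trimws(lat[2]), "\\s+")[[1]])
      if (length(lv) == 9L) box <- lv[c(1, 5, 9)]
    }
    tm <- frame - 1
    tmm <- regmatches(header, regexec("Time=([-0-9.eE+]+)", header))[[1]]
    if (length(tmm) == 2L) tm <- as.numeric(tmm[2])
    grab <- function(key, cast) {
      m <- regmatches(header, regexec(paste0(key, "=([^ ]+)"), header))[[1]]
      if (length(m) == 2L) cast(m[2]) else NULL
    }
    rep_id <- grab("replicate_id", function(x) suppressWarnings(as.integer(x))) %||% rep_id
    seed <- grab("seed", function(x) suppressWarnings(as.integer(x))) %||% seed
    fp <- grab("fingerprint", as.character) %||% fp
    rows <- lines[pos + 1L + seq_len(n)]
    toks <- strsplit(trimws(rows), "\\s+")
    nt <- lengths(toks)
    if (any(nt < 5L)) {
      bad <- which(nt < 5L)[1]
      parse_fail(frame, pos + 1L + bad, "expected 'species x y z id'")
    }
    m <- matrix(unlist(purrr::map(toks, function(t) t[2:5])), ncol = 4, byrow = TRUE)
    co <- suppressWarnings(apply(m, 2, as.numeric))
    if (any(!is.finite(co))) {
      bad <- which(rowSums(!is.finite(co)) > 0)[1]
      parse_fail(frame, pos + 1L + bad, "non-numeric coordinate or id")
    }
    out[[frame]] <- tibble::tibble(
      frame = frame,
      time = tm,
      particle_id = as.integer(co[, 4]),
      species = purrr::map_chr(toks, 1L),
      x = co[, 1], y = co[, 2], z = co[, 3]
    )
    pos <- pos + 2L + n
  }
  if (frame == 0L) rlang::abort(sprintf("no frames in '%s'.", path))
  df <- dplyr::bind_rows(out)
  ids <- split(df$particle_id, df$frame)
  if (length(unique(purrr::map_chr(ids, function(i) paste(sort(i), collapse = ",")))) != 1L) {
    rlang::abort("particle_id set differs across frames.")
  }
  tms <- purrr::map_dbl(split(df$time, df$frame), 1)
  if (any(diff(tms[order(as.integer(names(tms)))]) <= 0)) {
    rlang::abort("frame times are not strictly increasing.")
  }
  spec <- NULL
  structure(
    df,
    box = box,
    replicate_id = rep_id,
    seed = seed,
    fingerprint = fp,
    spec = spec,
    class = c("pore_trajectory", class(tibble::tibble()))
  )
}

#' Export a structure as a PDB file
#'
#' Writes standard fixed-width ATOM/HETATM records. Accepts either a
#' backbone model (see [build_ideal_helix()]) — written as ATOM records with
#' N/CA/C/O atoms — or a single trajectory frame, written as HETATM records
#' (NA+ for ions, O of water for waters).
#'
#' @param x A `backbone_model` tibble or a one-frame particle tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  fmt <- function(serial, name, resn, chain, resno, xx, yy, zz, el, rec = "ATOM  ") {
    # standard columns: serial 7-11, name 13-16, altLoc 17, resName 18-20,
    # chain 22, resSeq 23-26, coords 31-54
    sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            rec, serial, name, resn, substr(chain, 1, 1), resno,
            xx, yy, zz, 1.0, 0.0, el)
  }
  lines <- character()
  if (inherits(x, "backbone_model") || all(c("resno", "atom", "x", "y", "z") %in% names(x))) {
    aa3 <- aa_three_letter(x$aa %||% rep("A", nrow(x)))
    chain <- substr(x$subunit %||% rep("A", nrow(x)), 2, 2)
    chain[!nzchar(chain)] <- "A"
    el <- substr(x$atom, 1, 1)
    nm <- ifelse(nchar(x$atom) < 4, paste0(" ", x$atom), x$atom)
    lines <- fmt(seq_len(nrow(x)), nm, aa3, chain, x$resno, x$x, x$y, x$z, el)
  } else if (all(c("species", "x", "y", "z") %in% names(x))) {
    if ("frame" %in% names(x) && length(unique(x$frame)) > 1L) {
      rlang::abort("write_pdb exports a single frame; filter the trajectory first.")
    }
    resn <- ifelse(x$species == "ion", " NA", "HOH")
    name <- ifelse(x$species == "ion", " NA ", " O  ")
    el <- ifelse(x$species == "ion", "NA", "O")
    lines <- fmt(seq_len(nrow(x)), name, resn, "A", seq_len(nrow(x)),
                 x$x, x$y, x$z, el, rec = "HETATM")
  } else {
    rlang::abort("Don't know how to write this object as PDB.")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

aa_three_letter <- function(one) {
  map <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
  out <- unname(map[toupper(one)])
  out[is.na(out)] <- "UNK"
  out
}
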