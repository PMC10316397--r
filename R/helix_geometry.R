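# Secondary-structure assignment from backbone geometry, pi-stretch
# localization, pore-facing prediction and the register-shift map by which
# a pi-bulge rotates downstream pore-facing residues.

# distance and C=O...N angle test for a backbone H-bond between the
# carbonyl of residue i and the amide N of residue i+k.
hbond_ok <- function(O, C, N2, dist_max = 3.5, angle_min = 120) {
  d <- sqrt(sum((O - N2)^2))
  if (!is.finite(d) || d > dist_max) return(FALSE)
  v1 <- C - O
  v2 <- N2 - O
  ang <- acos(sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))) * 180 / pi
  ang >= angle_min
}

backbone_atom_matrix <- function(backbone, atom) {
  b <- backbone[backbone$atom == atom, ]
  b <- b[order(b$resno), ]
  m <- as.matrix(b[, c("x", "y", "z")])
  rownames(m) <- b$resno
  m
}

#' Assign alpha/pi secondary structure from backbone geometry
#'
#' Uses a geometric hydrogen-bond criterion: residue `i` donates an alpha
#' H-bond if O(i)...N(i+4) <= 3.5 Angstrom with a C=O...N angle >= 120
#' degrees, and a pi H-bond under the same criterion for O(i)...N(i+5).
#' Each alpha bond marks residues `i+1..i+3` and each pi bond residues
#' `i+1..i+4` as helical; pi takes precedence over alpha where patterns
#' overlap (pi detection is the purpose). Unmatched interior residues are
#' coil; terminal coil runs are labeled by extension of the adjacent
#' interior label. This is a distance/angle criterion, not DSSP's
#' electrostatic energy — simpler, and adequate for ideal and near-ideal
#' helices.
#'
#' @param backbone A `backbone_model` with N, CA, C, O atoms per residue.
#' @return An `ss_assignment`: tibble `resno`, `aa`, `subunit`, `label`
#'   (`"alpha"`, `"pi"`, `"coil"`), with attribute `pi_intervals` (tibble
#'   `start`, `end`).
#' @export
assign_secondary_structure <- function(backbone) {
  need <- c("N", "CA", "C", "O")
  by_res <- split(backbone$atom, backbone$resno)
  missing <- names(by_res)[!purrr::map_lgl(by_res, function(a) all(need %in% a))]
  if (length(missing) > 0) {
    rlang::abort(sprintf("residue %s is missing backbone atoms.", missing[1]))
  }
  resno <- sort(unique(backbone$resno))
  n <- length(resno)
  if (n < 6L) rlang::abort("need >= 6 residues to assign secondary structure.")
  O <- backbone_atom_matrix(backbone, "O")
  C <- backbone_atom_matrix(backbone, "C")
  N <- backbone_atom_matrix(backbone, "N")

  lab <- rep("coil", n)
  # alpha pass
  for (i in seq_len(n - 4L)) {
    if (hbond_ok(O[i, ], C[i, ], N[i + 4L, ])) {
      lab[(i + 1L):(i + 3L)] <- "alpha"
    }
  }
  # pi pass takes precedence
  for (i in seq_len(n - 5L)) {
    if (hbond_ok(O[i, ], C[i, ], N[i + 5L, ])) {
      lab[(i + 1L):(i + 4L)] <- "pi"
    }
  }
  # extend terminal coil runs from the adjacent interior label
  interior <- which(lab != "coil")
  if (length(interior) > 0) {
    if (interior[1] > 1L) lab[seq_len(interior[1] - 1L)] <- lab[interior[1]]
    last <- interior[length(interior)]
    if (last < n) lab[(last + 1L):n] <- lab[last]
  }

  res_tbl <- backbone[backbone$atom == "CA", c("resno", "aa", "subunit")]
  res_tbl <- res_tbl[order(res_tbl$resno), ]
  out <- tibble::tibble(resno = resno,
                        aa = res_tbl$aa[match(resno, res_tbl$resno)],
                        subunit = res_tbl$subunit[match(resno, res_tbl$resno)],
                        label = lab)
  structure(out,
            pi_intervals = label_intervals(resno, lab, "pi"),
            class = c("ss_assignment", class(tibble::tibble())))
}

label_intervals <- function(resno, lab, which_label) {
  is_l <- lab == which_label
  if (!any(is_l)) return(tibble::tibble(start = integer(), end = integer()))
  r <- rle(is_l)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  tibble::tibble(start = resno[starts[keep]], end = resno[ends[keep]])
}

#' Locate pi-helix stretches and their anchor residues
#'
#' Returns the pi intervals of an assignment together with the anchor
#' residue at which each bulge begins (the interval start). Use
#' [pi_stretch_shift()] to compare the localization of two assignments.
#'
#' @param ss An `ss_assignment` from [assign_secondary_structure()], or a
#'   tibble with `resno` and `label`.
#' @param subunit Optional subunit filter.
#' @return Tibble `subunit`, `start`, `end`, `anchor`.
#' @export
locate_pi_stretch <- function(ss, subunit = NULL) {
  d <- ss
  if (!is.null(subunit)) d <- d[d$subunit == subunit, ]
  iv <- label_intervals(d$resno, d$label, "pi")
  tibble::tibble(subunit = if (nrow(iv)) (d$subunit[1] %||% NA_character_) else character(),
                 start = iv$start, end = iv$end, anchor = iv$start)
}

#' Register shift between two pi-helix localizations
#'
#' Reports, in residues, how far the pi stretch of assignment `b` is
#' shifted relative to assignment `a` (anchor difference). A pi-helix
#' placed one helical turn further down the helix — as in the Nav1.7
#' structures where the bulge sits at N1767 instead of F1762 — is reported
#' as a shift of +5 residues.
#'
#' @param ss_a,ss_b Two assignments (or their [locate_pi_stretch()]
#'   outputs).
#' @return Integer shift in residues (NA if either has no pi stretch;
#'   0 for identical localization).
#' @export
pi_stretch_shift <- function(ss_a, ss_b) {
  a <- if ("anchor" %in% names(ss_a)) ss_a else locate_pi_stretch(ss_a)
  b <- if ("anchor" %in% names(ss_b)) ss_b else locate_pi_stretch(ss_b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(NA_integer_)
  as.integer(b$anchor[1] - a$anchor[1])
}

# Ideal C-beta reconstructed from backbone N, CA, C by tetrahedral
# geometry (1.53 A bond, ~110.5 deg to both N and C). Works for Gly too
# (placeholder C-beta), so PDB files lacking side chains still work.
reconstruct_cbeta <- function(N, CA, C) {
  n1 <- N - CA; n1 <- n1 / sqrt(sum(n1^2))
  n2 <- C - CA; n2 <- n2 / sqrt(sum(n2^2))
  bis <- n1 + n2; bis <- bis / sqrt(sum(bis^2))
  perp <- c(n1[2] * n2[3] - n1[3] * n2[2],
            n1[3] * n2[1] - n1[1] * n2[3],
            n1[1] * n2[2] - n1[2] * n2[1])
  perp <- perp / sqrt(sum(perp^2))
  half <- acos(sum(n1 * n2)) / 2
  ct <- -cos(110.5 * pi / 180) / cos(half)
  ct <- max(min(ct, 1), -1)
  st <- sqrt(1 - ct^2)
  CA + 1.53 * (-bis * ct + perp * st)
}

#' Predict pore-facing residues
#'
#' A residue faces the pore if its CA -> C-beta direction (C-beta
#' reconstructed from the backbone, so side chains are not required) is
#' within `cutoff_deg` of the inward radial direction toward the pore
#' axis. The default 60-degree cutoff encodes the categorical
#' "faces the pore" judgment of structural descriptions.
#'
#' @param backbone A `backbone_model`, positioned relative to the pore.
#' @param pore_axis List with `point` (length-3) and `dir` (length-3,
#'   non-zero); default is the z axis through the origin.
#' @param cutoff_deg Facing cutoff in degrees.
#' @return A `pore_facing` tibble: `subunit`, `resno`, `aa`, `angle_deg`,
#'   `facing` (logical).
#' @export
predict_pore_facing <- function(backbone,
                                pore_axis = list(point = c(0, 0, 0),
                                                 dir = c(0, 0, 1)),
                                cutoff_deg = 60) {
  dir <- pore_axis$dir
  if (sqrt(sum(dir^2)) < 1e-12) rlang::abort("pore axis direction is degenerate.")
  dir <- dir / sqrt(sum(dir^2))
  p0 <- pore_axis$point
  N <- backbone_atom_matrix(backbone, "N")
  CA <- backbone_atom_matrix(backbone, "CA")
  C <- backbone_atom_matrix(backbone, "C")
  resno <- as.integer(rownames(CA))
  ang <- vapply(seq_len(nrow(CA)), function(i) {
    cb <- reconstruct_cbeta(N[i, ], CA[i, ], C[i, ])
    v <- cb - CA[i, ]
    # inward radial direction: from CA toward its projection on the axis
    w <- p0 + sum((CA[i, ] - p0) * dir) * dir - CA[i, ]
    wn <- sqrt(sum(w^2))
    if (wn < 1e-9) return(NA_real_) # CA on the axis: radial undefined
    acos(max(min(sum(v * w) / (sqrt(sum(v^2)) * wn), 1), -1)) * 180 / pi
  }, 0)
  res_tbl <- backbone[backbone$atom == "CA", c("resno", "aa", "subunit")]
  res_tbl <- res_tbl[order(res_tbl$resno), ]
  structure(
    tibble::tibble(subunit = res_tbl$subunit, resno = resno, aa = res_tbl$aa,
                   angle_deg = ang, facing = !is.na(ang) & ang <= cutoff_deg),
    class = c("pore_facing", class(tibble::tibble()))
  )
}

#' Map pore-facing residues through a pi-bulge register shift
#'
#' A pi-helix inserted at `bulge_start` adds one residue to a helical turn
#' and thereby rotates everything downstream: residues numbered below
#' `bulge_start` keep their orientation, while for residues at or beyond
#' it the pore-facing register advances by one residue (409 -> 410,
#' 413 -> 414, ...). Applying the map with `shift = -1` restores the
#' alpha-helical facing set. This reproduces the rotation of the conserved
#' DIV asparagine toward the pore when DIV-S6 is pi-helical.
#'
#' @param facing A pore-facing set: tibble with `resno` (and optionally
#'   `subunit`), or a bare numeric vector of residue numbers.
#' @param bulge_start Residue number at which the pi bulge begins.
#' @param helix_range Optional length-2 residue-number range of the helix;
#'   if supplied, `bulge_start` must fall inside it.
#' @param sequence Optional named character vector mapping residue numbers
#'   to one-letter amino acids, used to annotate the shifted set.
#' @param shift Register advance for residues at/beyond the bulge
#'   (default +1; use -1 to invert).
#' @return Tibble `resno`, `aa` (NA when no sequence is given).
#' @export
#' @examples
#' register_shift_map(c(409, 413), bulge_start = 405)$resno # 410, 414
register_shift_map <- function(facing, bulge_start, helix_range = NULL,
                               sequence = NULL, shift = 1L) {
  resno <- if (is.numeric(facing)) as.integer(facing) else as.integer(facing$resno)
  if (!is.null(helix_range)) {
    if (bulge_start < helix_range[1] || bulge_start > helix_range[2]) {
      rlang::abort("`bulge_start` lies outside the helix.")
    }
  }
  new_resno <- ifelse(resno >= bulge_start, resno + as.integer(shift), resno)
  aa <- if (!is.null(sequence)) {
    unname(sequence[as.character(new_resno)])
  } else {
    NA_character_
  }
  tibble::tibble(resno = new_resno, aa = aa)
}

#' Activation-gate residues of human Nav1.5 S6 helices
#'
#' The hydrophobic residues lining the activation gate in the human
#' cardiac channel Nav1.5 (human numbering), per subunit: the upper tetrad
#' I409/F937/I1468/V1766 and, one helical turn below, V413/I941/I1472/I1770,
#' together with the residues rotated into the pore when the respective S6
#' is pi-helical (L410/A414, I938/I942, N1767/A1771 — including the
#' conserved DIV asparagine N1767).
#'
#' @return Tibble `subunit`, `resno`, `aa`, `faces_pore_when` (`"alpha"` or
#'   `"pi"`).
#' @export
nav15_gate_residues <- function() {
  tibble::tribble(
    ~subunit, ~resno, ~aa, ~faces_pore_when,
    "DI",   409L, "I", "alpha",
    "DI",   413L, "V", "alpha",
    "DI",   410L, "L", "pi",
    "DI",   414L, "A", "pi",
    "DII",  937L, "F", "alpha",
    "DII",  941L, "I", "alpha",
    "DII",  938L, "I", "pi",
    "DII",  942L, "I", "pi",
    "DIII", 1468L, "I", "alpha",
    "DIII", 1472L, "I", "alpha",
    "DIV",  1766L, "V", "alpha",
    "DIV",  1770L, "I", "alpha",
    "DIV",  1767L, "N", "pi",
    "DIV",  1771L, "A", "pi"
  )
}

#' Read a backbone model from a PDB file
#'
#' Parses standard ATOM records (first model of multi-model files) with
#' bio3d and keeps the N, CA, C, O backbone atoms. Author residue
#' numbering is trusted as-is.
#'
#' @param path PDB file path.
#' @param chain Optional chain identifier filter.
#' @param subunit_label Label attached to the residues (default the chain).
#' @return A `backbone_model` tibble with `source = "PDB"`.
#' @export
read_backbone_pdb <- function(path, chain = NULL, subunit_label = NULL) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    rlang::abort("reading PDB files requires the bio3d package.")
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$elety %in% c("N", "CA", "C", "O"), ]
  if (!is.null(chain)) at <- at[at$chain %in% chain, ]
  if (nrow(at) == 0L) rlang::abort("no backbone ATOM records found.")
  at <- at[!duplicated(at[, c("chain", "resno", "elety")]), ]
  one <- tryCatch(bio3d::aa321(at$resid), error = function(e) rep("X", nrow(at)))
  new_backbone_model(
    tibble::tibble(resno = as.integer(at$resno),
                   aa = one,
                   subunit = subunit_label %||% at$chain,
                   atom = at$elety,
                   x = at$x, y = at$y, z = at$z),
    source = "PDB"
  )
}
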