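# Helix building, secondary-structure assignment, pore-facing prediction
# and the register-shift map.

test_that("ideal all-alpha helices are assigned alpha throughout", {
  bb <- build_ideal_helix(helix_spec(strrep("A", 30), strrep("A", 30)))
  ss <- assign_secondary_structure(bb)
  expect_true(all(ss$label == "alpha"))
  expect_equal(nrow(locate_pi_stretch(ss)), 0L)
})

test_that("pi stretches round-trip exactly through build and assignment", {
  for (iv in list(c(10, 15), c(8, 13), c(12, 19), c(10, 14))) {
    ssv <- rep("A", 30); ssv[iv[1]:iv[2]] <- "P"
    bb <- build_ideal_helix(helix_spec(strrep("A", 30),
                                       paste(ssv, collapse = "")))
    ss <- assign_secondary_structure(bb)
    expect_identical(ss$resno[ss$label == "pi"], iv[1]:iv[2])
    got <- locate_pi_stretch(ss)
    expect_equal(c(got$start, got$end), iv)
  }
})

test_that("axial rise is ~1.5 A for alpha and ~1.15 A for pi helices", {
  rise_of <- function(ss_string) {
    bb <- align_helix_axis(build_ideal_helix(helix_spec(
      strrep("A", nchar(ss_string)), ss_string)))
    ca <- bb[bb$atom == "CA", ]
    z <- ca$z[order(ca$resno)]
    mean(abs(diff(z[5:(length(z) - 4)])))
  }
  expect_equal(rise_of(strrep("A", 30)), 1.5, tolerance = 0.1)
  expect_equal(rise_of(strrep("P", 30)), 1.15, tolerance = 0.1)
})

test_that("missing backbone atoms are reported by residue", {
  bb <- build_ideal_helix(helix_spec(strrep("A", 10), strrep("A", 10)))
  broken <- bb[!(bb$resno == 4 & bb$atom == "O"), ]
  expect_error(assign_secondary_structure(broken), "residue 4")
  expect_error(assign_secondary_structure(bb[bb$resno <= 5, ]), ">= 6")
})

test_that("pi localization shifted by one helical turn reports +5", {
  mk_ss <- function(from, to) {
    lab <- rep("alpha", 30)
    lab[seq(from, to) - 1745] <- "pi" # residues numbered 1746..1775
    tibble::tibble(resno = 1746:1775, label = lab, subunit = "DIV")
  }
  a <- mk_ss(1762, 1766)
  b <- mk_ss(1767, 1771)
  expect_equal(pi_stretch_shift(a, b), 5L)
  expect_equal(pi_stretch_shift(a, a), 0L)
  no_pi <- tibble::tibble(resno = 1746:1775, label = "alpha", subunit = "DIV")
  expect_equal(nrow(locate_pi_stretch(no_pi)), 0L)
  expect_true(is.na(pi_stretch_shift(a, no_pi)))
})

test_that("pore-facing prediction matches a brute-force angle scan", {
  bb <- align_helix_axis(build_ideal_helix(helix_spec(strrep("A", 18),
                                                      strrep("A", 18))))
  bb$x <- bb$x + 10 # helix axis parallel to pore axis, 10 A away
  pf <- predict_pore_facing(bb)
  # independent brute-force check over all residues
  for (i in unique(bb$resno)) {
    at <- function(a) unlist(bb[bb$resno == i & bb$atom == a, c("x", "y", "z")])
    n1 <- at("N") - at("CA"); n1 <- n1 / sqrt(sum(n1^2))
    n2 <- at("C") - at("CA"); n2 <- n2 / sqrt(sum(n2^2))
    bis <- (n1 + n2) / sqrt(sum((n1 + n2)^2))
    perp <- c(n1[2] * n2[3] - n1[3] * n2[2], n1[3] * n2[1] - n1[1] * n2[3],
              n1[1] * n2[2] - n1[2] * n2[1])
    perp <- perp / sqrt(sum(perp^2))
    ct <- -cos(110.5 * pi / 180) / cos(acos(sum(n1 * n2)) / 2)
    cb <- at("CA") + 1.53 * (-bis * ct + perp * sqrt(1 - ct^2))
    v <- cb - at("CA")
    inward <- c(-at("CA")[1], -at("CA")[2], 0)
    ang <- acos(sum(v * inward) / sqrt(sum(v^2) * sum(inward^2))) * 180 / pi
    expect_equal(pf$facing[pf$resno == i], ang <= 60)
  }
  # the facing set forms the i, i+3/i+4 lattice of a helix face
  f <- pf$resno[pf$facing]
  expect_gt(length(f), 3)
  expect_true(all(diff(f) %in% c(1L, 3L, 4L)))
})

test_that("rotating the helix about its own axis complements the facing set", {
  bb <- align_helix_axis(build_ideal_helix(helix_spec(strrep("A", 18),
                                                      strrep("A", 18))))
  rot <- bb
  rot$x <- -bb$x; rot$y <- -bb$y # 180 degrees about the helix (z) axis
  bb$x <- bb$x + 10
  rot$x <- rot$x + 10
  f1 <- predict_pore_facing(bb)
  f2 <- predict_pore_facing(rot)
  expect_false(any(f1$facing & f2$facing))
})

test_that("glycine gets an ideal C-beta placeholder without crashing", {
  bb <- align_helix_axis(build_ideal_helix(helix_spec("GGGGGGGGGGGG",
                                                      strrep("A", 12))))
  bb$x <- bb$x + 10
  pf <- predict_pore_facing(bb)
  expect_equal(nrow(pf), 12L)
  expect_true(any(pf$facing))
})

test_that("degenerate pore axes are rejected", {
  bb <- build_ideal_helix(helix_spec(strrep("A", 10), strrep("A", 10)))
  expect_error(predict_pore_facing(bb, pore_axis = list(point = c(0, 0, 0),
                                                        dir = c(0, 0, 0))),
               "degenerate")
})

test_that("the register-shift map advances facing residues past the bulge", {
  seq_di <- c("409" = "I", "410" = "L", "413" = "V", "414" = "A")
  shifted <- register_shift_map(c(409, 413), bulge_start = 405,
                                sequence = seq_di)
  expect_equal(shifted$resno, c(410, 414))
  expect_equal(shifted$aa, c("L", "A"))
  # residues before the bulge are untouched
  mixed <- register_shift_map(c(402, 409), bulge_start = 405)
  expect_equal(mixed$resno, c(402, 410))
  expect_error(register_shift_map(c(409, 413), bulge_start = 300,
                                  helix_range = c(400, 420)),
               "outside the helix")
})

test_that("shifting back by one residue inverts the register map", {
  fwd <- register_shift_map(c(1766, 1770), bulge_start = 1760)
  back <- register_shift_map(fwd$resno, bulge_start = 1760, shift = -1L)
  expect_equal(back$resno, c(1766, 1770))
})

test_that("PDB round trip preserves an ideal helix backbone", {
  skip_if_not_installed("bio3d")
  bb <- build_ideal_helix(helix_spec("ALAVIKLFNS", strrep("A", 10)))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(bb, path)
  back <- read_backbone_pdb(path)
  expect_equal(nrow(back), nrow(bb))
  expect_equal(sort(unique(back$atom)), c("C", "CA", "N", "O"))
  merged <- dplyr::left_join(tibble::as_tibble(bb),
                             tibble::as_tibble(back),
                             by = c("resno", "atom"))
  expect_equal(merged$x.y, merged$x.x, tolerance = 1e-3)
  ss <- assign_secondary_structure(back)
  expect_true(all(ss$label == "alpha"))
})
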