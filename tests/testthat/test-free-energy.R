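# Metadynamics machinery: reconstruction arithmetic, tempering behaviour
# and the Boltzmann-inversion oracle. The heavier recovery runs live in
# the acceptance suite.

test_that("a single hill reconstructs to gamma/(gamma-1) times its height", {
  h <- tibble::tibble(center = 0, height = 1, width = 2)
  fe <- reconstruct_free_energy(h, seq(-30, 30, 0.5), gamma = 10)
  # the bias digs a free-energy well of depth 10/9 at the hill center:
  # F(0) - F(far) = -10/9 before shifting, so after the min-shift the
  # center sits at 0 and the far field at 10/9
  expect_equal(fe$F[fe$z == 0], 0)
  expect_equal(max(fe$F), 10 / 9, tolerance = 1e-6)
})

test_that("translating all hill centers translates the profile", {
  set.seed(5)
  h <- tibble::tibble(center = runif(20, -5, 5), height = runif(20, 0.1, 0.3),
                      width = 1.5)
  zg <- seq(-30, 30, 0.25)
  f1 <- reconstruct_free_energy(h, zg, gamma = 8)
  h2 <- dplyr::mutate(h, center = center + 4)
  f2 <- reconstruct_free_energy(h2, zg + 4, gamma = 8)
  expect_equal(f2$F, f1$F, tolerance = 1e-9)
})

test_that("reconstruction rejects empty hill tables and bad gamma", {
  expect_error(reconstruct_free_energy(tibble::tibble(), 1:10, gamma = 10),
               "empty")
  h <- tibble::tibble(center = 0, height = 1, width = 2)
  expect_error(reconstruct_free_energy(h, 1:10, gamma = 1), "gamma")
})

test_that("tempered hill heights are non-increasing at a revisited CV value", {
  spec <- pore_spec(pmf_terms = tibble::tibble(height = -2, center = 0,
                                               width = 4),
                    n_ions = 1, n_waters = 0, n_steps = 2e5, seed = 3)
  mtd <- run_wt_metadynamics(spec, metad_params(), seed = 19)
  expect_true(all(mtd$hills$height <= mtd$params$w0 + 1e-12))
  expect_true(all(mtd$hills$height > 0))
  # heights deposited near the well center decay as the bias fills it
  central <- mtd$hills[abs(mtd$hills$center) < 1, ]
  expect_gt(nrow(central), 5)
  first_half <- mean(head(central$height, ceiling(nrow(central) / 2)))
  second_half <- mean(tail(central$height, floor(nrow(central) / 2)))
  expect_lt(second_half, first_half)
})

test_that("huge gamma with small hills approaches standard metadynamics", {
  spec <- pore_spec(n_ions = 1, n_waters = 0, n_steps = 5e4, seed = 3)
  mtd <- run_wt_metadynamics(spec, metad_params(w0 = 0.01, gamma = 1e6),
                             seed = 4)
  expect_true(all(abs(mtd$hills$height - 0.01) < 1e-4))
})

test_that("Boltzmann inversion recovers an analytic harmonic-like well", {
  pmf <- tibble::tibble(height = -2, center = 0, width = 5) # Gaussian well
  spec <- pore_spec(pmf_terms = pmf, n_ions = 50, n_waters = 0,
                    n_steps = 4000, frame_stride = 2, seed = 8)
  tr <- simulate_pore(spec)
  zg <- seq(-35, 35, 1)
  fe <- boltzmann_invert(tr, zg, kT = 0.0019872041 * 300)
  truth <- porepi:::pmf_potential(zg, pmf, 80)
  truth <- truth - min(truth)
  keep <- !is.na(fe$F) & abs(zg) < 15 # well region is well sampled
  expect_lt(sqrt(mean((fe$F[keep] - truth[keep])^2)), 0.35)
})

test_that("Boltzmann inversion masks unvisited bins and warns when thin", {
  tr <- toy_trajectory(list(c(rep(0, 30), rep(5, 20))))
  expect_warning(fe <- boltzmann_invert(tr, seq(-10, 10, 1)), "noisy")
  expect_true(any(is.na(fe$F)))
  expect_equal(min(fe$F, na.rm = TRUE), 0)
})

test_that("barrier height is a shift-invariant gate/reference contrast", {
  zg <- seq(-38, 38, 0.5)
  flat <- porepi:::new_free_energy_profile(zg, rep(0, length(zg)))
  expect_equal(barrier_height(flat, c(-10, 10), c(25, 38)), 0)
  bump <- porepi:::new_free_energy_profile(zg, 4 * exp(-zg^2 / 18))
  expect_equal(barrier_height(bump, c(-10, 10), c(25, 38)), 4, tolerance = 1e-3)
  shifted <- porepi:::new_free_energy_profile(zg, 7 + 4 * exp(-zg^2 / 18))
  expect_equal(barrier_height(shifted, c(-10, 10), c(25, 38)),
               barrier_height(bump, c(-10, 10), c(25, 38)))
  expect_error(barrier_height(flat, c(100, 110), c(25, 38)), "gate region")
})

test_that("hills tables round-trip through the PLUMED-style TSV layout", {
  h <- tibble::tibble(step = c(500L, 1000L), center = c(-1.2, 3.4),
                      height = c(0.3, 0.28), width = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hills(h, path)
  back <- read_hills(path)
  expect_equal(as.data.frame(back), as.data.frame(h), tolerance = 1e-12)
})
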