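# Generator behaviour: determinism, confinement, water statistics and the
# equilibrium/drift physics of the Langevin integrator.

small_spec <- function(...) {
  pore_spec(n_ions = 4, n_waters = 60, n_steps = 2000, frame_stride = 10,
            seed = 101, ...)
}

test_that("identical spec and seed give bitwise-identical trajectories", {
  a <- simulate_pore(small_spec())
  b <- simulate_pore(small_spec())
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  c <- simulate_pore(small_spec(), seed = 999)
  expect_false(identical(a$z, c$z))
})

test_that("ions stay inside the pore cylinder and z stays in the box", {
  tr <- simulate_pore(small_spec())
  ions <- tr[tr$species == "ion", ]
  expect_true(all(ions$x^2 + ions$y^2 <= 5^2 + 1e-9))
  expect_true(all(abs(ions$z) <= 40 + 1e-9))
})

test_that("water count is conserved at every frame", {
  tr <- simulate_pore(small_spec())
  per_frame <- table(tr$frame[tr$species == "water"])
  expect_true(all(per_frame == 60))
})

test_that("frame times strictly increase and particle ids are stable", {
  tr <- simulate_pore(small_spec())
  tms <- unique(tr[, c("frame", "time")])
  expect_true(all(diff(tms$time[order(tms$frame)]) > 0))
  ids <- split(tr$particle_id, tr$frame)
  expect_length(unique(vapply(ids, function(i) paste(sort(i), collapse = ","),
                              "")), 1L)
})

test_that("zero-voltage flat-PMF ions show no net drift", {
  spec <- pore_spec(n_ions = 6, n_waters = 0, n_steps = 2e4,
                    frame_stride = 10, seed = 7)
  tr <- simulate_pore(spec)
  zu <- unwrap_axial(tr)
  disp <- tapply(zu$z, zu$ion_id, function(z) z[length(z)] - z[1])
  sigma <- sqrt(2 * spec$diffusion_coeff * spec$n_steps * spec$dt)
  expect_true(all(abs(disp) < 3.5 * sigma))
})

test_that("voltage produces the analytic drift velocity of biased diffusion", {
  spec <- pore_spec(n_ions = 8, n_waters = 0, n_steps = 5e4,
                    frame_stride = 10, voltage = -0.5, seed = 13)
  tr <- simulate_pore(spec)
  zu <- unwrap_axial(tr)
  disp <- tapply(zu$z, zu$ion_id, function(z) z[length(z)] - z[1])
  kT <- porepi_constants()$kB_kcal_per_mol_K * 300
  v_th <- spec$diffusion_coeff * spec$ion_charge * spec$voltage *
    porepi_constants()$eV_to_kcal_per_mol / (kT * 80)
  T_tot <- spec$n_steps * spec$dt
  sem <- sqrt(2 * spec$diffusion_coeff * T_tot) / sqrt(length(disp))
  expect_lt(abs(mean(disp) - v_th * T_tot), 3 * sem)
})

test_that("equilibrium z histogram matches the Boltzmann weight of the PMF", {
  pmf <- tibble::tibble(height = 1.5, center = 0, width = 4)
  spec <- pore_spec(pmf_terms = pmf, n_ions = 100, n_waters = 0,
                    n_steps = 1e4, frame_stride = 1, seed = 31)
  tr <- simulate_pore(spec)
  z <- tr$z[tr$species == "ion"]
  expect_gte(length(z), 1e6)
  kT <- porepi_constants()$kB_kcal_per_mol_K * 300
  zg <- seq(-40, 40, length.out = 1601)
  w <- exp(-porepi:::pmf_potential(zg, pmf, 80) / kT)
  cdf <- cumsum(w) / sum(w)
  emp <- stats::ecdf(z)
  ks <- max(abs(emp(zg) - cdf))
  expect_lt(ks, 0.05)
})

test_that("gate water occupancy is non-increasing in the dewetting factor", {
  occ <- vapply(c(0, 0.3, 0.7, 1), function(f) {
    tr <- simulate_pore(pore_spec(n_ions = 1, n_waters = 210, n_steps = 500,
                                  frame_stride = 5, dewetting_factor = f,
                                  seed = 55))
    wat <- tr[tr$species == "water", ]
    sum(wat$z > -10 & wat$z < 10) / length(unique(tr$frame))
  }, 0)
  expect_true(all(diff(occ) < 0))
  expect_equal(occ[4], 0)
})

test_that("unstable integrator settings fail loudly", {
  steep <- tibble::tibble(height = 500, center = 0, width = 1)
  expect_error(simulate_pore(pore_spec(pmf_terms = steep, n_steps = 10)),
               "Time step too large")
})
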