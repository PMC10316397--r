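# Water-density profiles, bulk normalization and gate hydration calls.

uniform_water_traj <- function(n_waters = 4000, L = 80, R = 5, frames = 2,
                               seed = 9) {
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(seq_len(frames), function(fr) {
      r <- R * sqrt(runif(n_waters)); th <- runif(n_waters, 0, 2 * pi)
      tibble::tibble(frame = fr, time = fr - 1,
                     particle_id = seq_len(n_waters), species = "water",
                     x = r * cos(th), y = r * sin(th),
                     z = runif(n_waters, -L / 2, L / 2))
    })) |>
      structure(box = c(30, 30, L),
                class = c("pore_trajectory", class(tibble::tibble())))
  })
}

test_that("a uniform water cylinder gives a flat normalized profile", {
  tr <- uniform_water_traj(n_waters = 20000, frames = 5)
  rho0 <- 20000 / (pi * 25 * 80)
  prof <- water_density_profile(tr, cylinder_radius = 5, bin_width = 4,
                                bulk = rho0)
  expect_true(all(abs(prof$normalized - 1) < 0.05))
})

test_that("an emptied slab has exactly zero density", {
  tr <- uniform_water_traj()
  tr <- tr[!(tr$z > -10 & tr$z < 10), ]
  prof <- water_density_profile(tr, cylinder_radius = 5, bin_width = 1)
  expect_true(all(prof$density[prof$z_mid > -10 & prof$z_mid < 10] == 0))
  expect_true(any(prof$density[abs(prof$z_mid) > 12] > 0))
})

test_that("per-bin densities match a hand-enumerated 4-water fixture", {
  # two frames, 4 waters; bins of 10 A over (-20, 20), cylinder r = 5
  tr <- tibble::tibble(
    frame = c(1, 1, 1, 1, 2, 2, 2, 2),
    time = c(0, 0, 0, 0, 1, 1, 1, 1),
    particle_id = rep(1:4, 2),
    species = "water",
    x = c(0, 1, 0, 4.9, 0, 1, 0, 6), # last water of frame 2 is outside r
    y = 0,
    z = c(-15, -5, 5, 15, -15, -5, 5, 15)
  )
  prof <- water_density_profile(tr, cylinder_radius = 5, bin_width = 10,
                                z_range = c(-20, 20))
  vol <- pi * 25 * 10
  expect_equal(prof$density, c(1, 1, 1, 0.5) / vol)
})

test_that("bulk density recovers the construction density", {
  tr <- uniform_water_traj(n_waters = 20000, frames = 5)
  rho0 <- 20000 / (pi * 25 * 80)
  est <- bulk_density(tr, reference_slab = c(20, 38), cylinder_radius = 5)
  expect_equal(est, rho0, tolerance = 0.05)
  expect_error(bulk_density(tr[0, ], c(20, 38)), "zero frames")
})

test_that("binned mass balances the mean in-cylinder water count", {
  tr <- simulate_pore(pore_spec(n_ions = 1, n_waters = 210, n_steps = 500,
                                frame_stride = 5, dewetting_factor = 0.4,
                                seed = 77))
  prof <- water_density_profile(tr, cylinder_radius = 5, bin_width = 1)
  vols <- pi * 25 * diff(attr(prof, "bin_edges"))
  total_from_bins <- sum(prof$density * vols)
  wat <- tr[tr$species == "water" & tr$x^2 + tr$y^2 <= 25, ]
  mean_count <- nrow(wat) / length(unique(tr$frame))
  expect_equal(total_from_bins, mean_count, tolerance = 1e-6)
})

test_that("the profile is invariant under frame reordering", {
  tr <- uniform_water_traj(frames = 3)
  prof1 <- water_density_profile(tr, bulk = 1)
  sh <- tr[order(-tr$frame, tr$particle_id), ]
  attr(sh, "box") <- c(30, 30, 80)
  prof2 <- water_density_profile(sh, bulk = 1)
  expect_equal(prof1$density, prof2$density)
})

test_that("hydration classes follow the min normalized gate density", {
  gate <- gate_definition(-10, 10)
  mk <- function(val) {
    structure(tibble::tibble(z_mid = seq(-39.5, 39.5, 1), density = 1,
                             normalized = ifelse(abs(seq(-39.5, 39.5, 1)) < 5,
                                                 val, 1)),
              class = c("density_profile", class(tibble::tibble())))
  }
  expect_equal(classify_gate_hydration(mk(0), gate)$class, "dehydrated")
  expect_equal(classify_gate_hydration(mk(0.3), gate)$class,
               "partially_dehydrated")
  expect_equal(classify_gate_hydration(mk(1), gate)$class, "hydrated")
})

test_that("generator dewetting drives the hydration call as constructed", {
  gate <- gate_definition(-10, 10)
  call_for <- function(f) {
    tr <- simulate_pore(pore_spec(n_ions = 1, n_waters = 210, n_steps = 2000,
                                  frame_stride = 5, dewetting_factor = f,
                                  seed = 123))
    bulk <- bulk_density(tr, reference_slab = c(25, 38))
    prof <- water_density_profile(tr, bulk = bulk)
    classify_gate_hydration(prof, gate)
  }
  dry <- call_for(1)
  wet <- call_for(0.3)
  expect_equal(dry$class, "dehydrated")
  expect_true(wet$class %in% c("hydrated", "partially_dehydrated"))
  expect_gt(wet$min_normalized_density, dry$min_normalized_density)
})
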