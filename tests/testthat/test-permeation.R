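# Event detection, unwrapping and conductance arithmetic.

test_that("unwrap applies the minimum image across the boundary", {
  tr <- toy_trajectory(list(c(39, -39)))
  zu <- unwrap_axial(tr, box_length = 80)
  expect_equal(zu$z, c(39, 41))
  tr2 <- toy_trajectory(list(c(-39, 39)))
  expect_equal(unwrap_axial(tr2, box_length = 80)$z, c(-39, -41))
})

test_that("already-continuous series are returned unchanged", {
  z <- cumsum(rep(0.5, 50))
  tr <- toy_trajectory(list(z))
  expect_equal(unwrap_axial(tr, box_length = 80)$z, z)
})

test_that("wrapped and never-wrapped random walks unwrap identically", {
  set.seed(42)
  for (i in 1:50) {
    z <- make_random_walk(400, drift = runif(1, -0.5, 0.5), sd = 1.2)
    wrapped <- toy_trajectory(list(wrap_series(z, 80)))
    zu <- unwrap_axial(wrapped, box_length = 80)
    expect_equal(zu$z, z - z[1] + zu$z[1], tolerance = 1e-9)
  }
})

test_that("a single monotone traversal yields exactly one +1 event", {
  gate <- gate_definition(-10, 10)
  ev <- detect_permeation_events(seq(-30, 30, by = 0.5), gate)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$direction, 1L)
  ev_dn <- detect_permeation_events(seq(30, -30, by = -0.5), gate)
  expect_equal(ev_dn$direction, -1L)
})

test_that("oscillation that never clears both gate boundaries counts nothing", {
  gate <- gate_definition(-10, 10)
  below <- -20 + 5 * sin(seq(0, 20, 0.1))
  expect_equal(nrow(detect_permeation_events(below, gate)), 0L)
  inside_dither <- c(-15, 0, -5, 5, -8, 9, -15) # enters and leaves below
  expect_equal(nrow(detect_permeation_events(inside_dither, gate)), 0L)
})

test_that("detector matches the brute-force bookkeeping oracle on seeded walks", {
  gate <- gate_definition(-10, 10)
  set.seed(7)
  for (i in 1:100) {
    z <- make_random_walk(600, drift = runif(1, -0.6, 0.6), sd = 2,
                          z0 = runif(1, -40, 40))
    orc <- oracle_count_events(z, -10, 10, 80)
    ev <- detect_permeation_events(z, gate, box_length = 80)
    expect_equal(sum(ev$direction == 1), orc$up)
    expect_equal(sum(ev$direction == -1), orc$down)
    # wrapped representation gives identical counts after unwrapping
    zu <- unwrap_axial(toy_trajectory(list(wrap_series(z, 80))),
                       box_length = 80)
    ev_w <- detect_permeation_events(zu, gate, box_length = 80)
    expect_equal(sum(ev_w$direction), sum(ev$direction))
  }
})

test_that("conductance follows g = |N| q e / (T |V|)", {
  est <- estimate_conductance(5, duration_ps = 1e5, voltage = -0.5, charge = 1)
  expect_equal(est$conductance_pS, 5 * 1.602176634e-19 / (1e-7 * 0.5) * 1e12)
  expect_equal(est$conductance_pS, 16.02, tolerance = 1e-3)
  expect_equal(estimate_conductance(0, 1e5, -0.5)$conductance_pS, 0)
  expect_error(estimate_conductance(5, 1e5, 0), "voltage")
  # the published 17.5 pS <-> 6.125 events pairing closes at |V| = 0.56 V
  est2 <- estimate_conductance(6.125, duration_ps = 1e5, voltage = -0.56)
  expect_equal(est2$conductance_pS, 17.52, tolerance = 1e-2)
})

test_that("conductance is invariant under joint scaling of N and T", {
  g1 <- estimate_conductance(4, 1e5, -0.5)$conductance_pS
  g2 <- estimate_conductance(8, 2e5, -0.5)$conductance_pS
  expect_equal(g1, g2)
  g3 <- estimate_conductance(8, 1e5, -0.5)$conductance_pS
  expect_equal(g3, 2 * g1)
})

test_that("replicate conductance reports mean and n-1 SEM", {
  est <- replicate_conductance(rep(2, 6), duration_ps = 1e5, voltage = -0.5)
  expect_equal(est$mean_pS, 6.41, tolerance = 1e-2)
  expect_equal(est$sem_pS, 0)
  est2 <- replicate_conductance(c(1, 5), duration_ps = 1e5, voltage = -0.5)
  g1 <- estimate_conductance(1, 1e5, -0.5)$conductance_pS
  g5 <- estimate_conductance(5, 1e5, -0.5)$conductance_pS
  expect_equal(est2$mean_pS, (g1 + g5) / 2)
  set.seed(11)
  counts <- rpois(6, 3)
  est3 <- replicate_conductance(counts, 1e5, -0.5)
  per <- counts * 1.602176634e-19 / (1e-7 * 0.5) * 1e12
  expect_equal(est3$per_replicate_pS, per)
  expect_equal(est3$mean_pS, sum(per) / 6)
  expect_equal(est3$sem_pS,
               sqrt(sum((per - mean(per))^2) / 5) / sqrt(6))
  expect_error(replicate_conductance(3, 1e5, -0.5), "2 replicates")
})

test_that("model comparison is a symmetric two-sided Welch test", {
  a <- c(9.1, 9.9, 8.7, 10.2, 9.5, 9.0)
  b <- c(19.8, 21.0, 20.4, 19.1, 20.9, 20.2)
  ab <- compare_models(a, b)
  ba <- compare_models(b, a)
  expect_equal(ab$p_value, ba$p_value)
  expect_equal(abs(ab$statistic), abs(ba$statistic))
  expect_lt(ab$p_value, 0.001)
  same <- compare_models(a, a)
  expect_equal(same$p_value, 1)
  expect_equal(compare_models(c(1, 1), c(1, 1))$p_value, 1)
  expect_equal(compare_models(c(1, 1), c(2, 2))$p_value, 0)
  nearly <- compare_models(c(0, 0, 0) + 1e-9 * (1:3), c(10, 10, 10) + 1e-9 * (1:3))
  expect_lt(nearly$p_value, 0.001)
})

test_that("tidy and glance summarise conductance estimates", {
  est <- replicate_conductance(c(2, 3, 4), duration_ps = 1e5, voltage = -0.5)
  td <- generics::tidy(est)
  expect_equal(nrow(td), 3L)
  gl <- generics::glance(est)
  expect_equal(gl$mean_g_pS, est$mean_pS)
  expect_equal(gl$n_replicates, 3L)
})
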