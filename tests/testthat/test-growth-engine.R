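test_that("oocyte volume is affine in absorbed VTG mass", {
  p <- test_params
  expect_identical(oocyte_volume(0, p), p$v_oog)
  m <- 0.37
  expect_equal(oocyte_volume(2 * m, p) - p$v_oog,
               2 * (oocyte_volume(m, p) - p$v_oog))
  p1 <- model_parameters(rho_vtg_ooc = 1, r_vtg = 1)
  expect_equal(oocyte_volume(1, p1), p1$v_oog + 0.156)
  expect_error(oocyte_volume(-0.1, p), ">= 0")
})

test_that("maturation time is inversely proportional to VTG concentration", {
  p <- test_params
  expect_equal(maturation_time(0.05, p), 2 * maturation_time(0.1, p))
  expect_identical(maturation_time(0, p), Inf)
  # strictly decreasing in C, rho, and R
  cs <- seq(0.01, 0.3, length.out = 10)
  expect_true(all(diff(maturation_time(cs, p)) < 0))
  t_base <- maturation_time(0.1, p)
  expect_lt(maturation_time(0.1, model_parameters(rho_vtg_ooc = p$rho_vtg_ooc * 2)),
            t_base)
  expect_lt(maturation_time(0.1, model_parameters(rho_vtg_ooc = p$rho_vtg_ooc,
                                                  r_vtg = 2)),
            t_base)
})

test_that("a batch under constant VTG spawns at recruit time plus maturation time", {
  p <- test_params
  proto <- vtg_protocol(-81, 0.1)
  b <- grow_batch(new_batch(-10, 50, p), proto, 30, p)
  expect_identical(b$status, "spawned")
  expect_equal(b$spawn_time, -10 + maturation_time(0.1, p), tolerance = 1e-12)
  expect_equal(b$v_ooc, p$v_threshold)
})

test_that("zero VTG means zero growth and no spawning", {
  p <- test_params
  b <- grow_batch(new_batch(0, 50, p), vtg_protocol(0, 0), 100, p)
  expect_identical(b$status, "unspawned_at_end")
  expect_equal(b$v_ooc, p$v_oog)
  expect_equal(b$m_vtg, 0)
})

test_that("a step up in VTG at exposure start advances the spawn", {
  p <- test_params
  c_lo <- 0.02
  proto_flat <- vtg_protocol(-81, c_lo)
  proto_step <- vtg_protocol(c(-81, 0), c(c_lo, 0.2))
  b0 <- new_batch(-5, 50, p)
  flat <- grow_batch(b0, proto_flat, 60, p)
  step <- grow_batch(b0, proto_step, 60, p)
  expect_gt(flat$spawn_time, 0)  # crossing occurs after the step time
  expect_lt(step$spawn_time, flat$spawn_time)
})

test_that("volume/mass stay consistent with the affine relation during growth", {
  p <- test_params
  proto <- vtg_protocol(c(-81, 0), c(0.1, 0.03))
  for (t_end in c(-3.5, -1, 0.5, 2)) {
    b <- grow_batch(new_batch(-4, 10, p), proto, t_end, p, final = FALSE)
    expect_lt(abs(b$v_ooc - (p$w_vtg * p$r_vtg * b$m_vtg + p$v_oog)), p$ode_atol)
  }
})

test_that("spawn volumes sit on the threshold within event tolerance", {
  p <- test_params
  set.seed(31)
  sim <- simulate_fish(fish_spec("f", 0.08), 21, p)
  expect_gt(nrow(sim$events), 0)
  expect_true(all(sim$events$v_at_spawn >= p$v_threshold - 1e-6))
  expect_true(all(sim$events$v_at_spawn <= p$v_threshold + 1e-6))
})

test_that("numeric ODE path reproduces the closed-form spawn time", {
  p <- tight_ode_params
  proto <- vtg_protocol(-81, 0.1)
  cf <- grow_batch(new_batch(0, 10, p), proto, 30, p, method = "closed_form")
  od <- grow_batch(new_batch(0, 10, p), proto, 30, p, method = "ode")
  expect_identical(od$status, "spawned")
  expect_lt(abs(od$spawn_time - cf$spawn_time) / cf$spawn_time, 1e-6)

  # piecewise protocol: closed form propagated segment-by-segment vs ODE
  proto2 <- vtg_protocol(c(-81, 0), c(0.04, 0.12))
  cf2 <- grow_batch(new_batch(-2, 10, p), proto2, 30, p, method = "closed_form")
  od2 <- grow_batch(new_batch(-2, 10, p), proto2, 30, p, method = "ode")
  expect_lt(abs(od2$spawn_time - cf2$spawn_time) /
              abs(cf2$spawn_time - (-2)), 1e-6)
})

test_that("trajectory dump matches the state grow_batch reports", {
  p <- test_params
  proto <- vtg_protocol(c(-81, 0), c(0.05, 0.15))
  b0 <- new_batch(-3, 10, p)
  traj <- batch_trajectory(b0, proto, times = c(-2, -1, 0.5, 1), p)
  for (i in seq_len(nrow(traj))) {
    b <- grow_batch(b0, proto, traj$time[i], p, final = FALSE)
    expect_equal(traj$v_ooc[i], b$v_ooc, tolerance = 1e-12)
    expect_equal(traj$m_vtg[i], b$m_vtg, tolerance = 1e-12)
  }
})

test_that("protocol validation catches bad inputs", {
  expect_error(vtg_protocol(c(0, 0), c(1, 1)), "strictly increasing")
  expect_error(vtg_protocol(0, -0.1), ">= 0")
  p <- test_params
  expect_error(grow_batch(new_batch(-5, 10, p), vtg_protocol(0, 0.1), 10, p),
               "cover")
})
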