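test_that("a fish with no VTG never spawns", {
  set.seed(1)
  sim <- simulate_fish(fish_spec("f0", 0, c_vtg_pre = 0), 21, test_params)
  expect_identical(nrow(sim$events), 0L)
  expect_true(all(sim$batches$status == "unspawned_at_end"))
  expect_identical(sim$totals$full$eggs, 0L)
})

test_that("under constant VTG every spawn is recruit time plus maturation time", {
  p <- test_params
  C <- 0.07
  set.seed(17)
  sim <- simulate_fish(fish_spec("f", C, c_vtg_pre = C), 21, p)
  t_star <- maturation_time(C, p)
  sp <- sim$batches[sim$batches$status == "spawned", ]
  expect_equal(sp$spawn_time, sp$recruit_time + t_star, tolerance = 1e-10)
  # enumeration oracle: batches whose crossing lands in the window spawn
  expected_spawned <- sim$batches$recruit_time + t_star <= 21
  expect_identical(sim$batches$status == "spawned", expected_spawned)
  n_exposure <- sum(expected_spawned & sim$batches$recruit_time + t_star >= 0)
  expect_identical(sim$totals$exposure$spawns, as.integer(n_exposure))
})

test_that("egg totals are the exact sums of spawned clutch sizes per period", {
  set.seed(23)
  sim <- simulate_fish(fish_spec("f", 0.11), 21, test_params)
  expect_identical(sim$totals$full$eggs, sum(sim$events$clutch_size))
  expect_identical(sim$totals$exposure$eggs,
                   sum(sim$events$clutch_size[sim$events$study_day >= 0]))
  expect_gte(sim$totals$full$eggs, sim$totals$exposure$eggs)
})

test_that("a control female is already spawning during the pre-exposure window", {
  set.seed(5)
  sim <- simulate_fish(fish_spec("f", 0.1), 21, test_params)
  expect_gt(sum(sim$events$study_day < 0), 0)
})

test_that("cohort simulation is deterministic given the master seed", {
  specs <- list(fish_spec("a", 0.1), fish_spec("b", 0.05))
  c1 <- simulate_cohort(specs, 10, 2, test_params, seed = 42)
  c2 <- simulate_cohort(specs, 10, 2, test_params, seed = 42)
  expect_identical(spawn_events(c1), spawn_events(c2))
  c3 <- simulate_cohort(specs, 10, 2, test_params, seed = 43)
  expect_false(identical(spawn_events(c1), spawn_events(c3)))
})

test_that("one replicate of one fish equals simulate_fish on the derived substream", {
  spec <- fish_spec("solo", 0.09)
  cohort <- simulate_cohort(list(spec), 14, 1, test_params, seed = 9)
  set.seed(oocytedyn:::substream_seed(9, "solo", 1))
  direct <- simulate_fish(spec, 14, test_params)
  expect_identical(cohort[[1]][["solo"]]$events, direct$events)
})

test_that("per-fish substreams are unaffected by cohort composition", {
  a_alone <- simulate_cohort(list(fish_spec("a", 0.1)), 10, 2,
                             test_params, seed = 4)
  a_with_b <- simulate_cohort(list(fish_spec("b", 0.08), fish_spec("a", 0.1)),
                              10, 2, test_params, seed = 4)
  expect_identical(a_alone[[1]][["a"]]$events, a_with_b[[1]][["a"]]$events)
  expect_identical(a_alone[[2]][["a"]]$events, a_with_b[[2]][["a"]]$events)
})

test_that("50 replicates of a 12-fish treatment yield 600 simulations", {
  cohort <- simulate_cohort(make_group_specs(0.09), 21, 50, test_params, seed = 2)
  expect_identical(length(cohort), 50L)
  expect_identical(sum(lengths(cohort)), 600L)
  ev <- spawn_events(cohort)
  expect_true(all(ev$study_day >= -81 & ev$study_day < 21))
  expect_true(all(ev$clutch_size >= 1))
})

test_that("duplicate fish ids and bad windows are rejected", {
  expect_error(simulate_cohort(list(fish_spec("x", 0.1), fish_spec("x", 0.2)),
                               10, 1, test_params, seed = 1),
               "duplicate fish_id")
  expect_error(simulate_fish(fish_spec("x", 0.1), 0, test_params), ">= 1")
})
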