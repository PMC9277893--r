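test_that("Weibull viability matches its closed form", {
  d <- screen_design(seed = 3)
  # t = 0 is always fully viable, whatever the archetype noise
  for (arch in control_archetypes()) {
    traj <- simulate_viability(arch, d, plate = 2, replicate = 5)
    expect_identical(traj$viability[1], 1)
  }
  # exponential special case (k = 1), noise-free: v(tau) = exp(-1)
  a1 <- archetype_spec("x", tau = 4, k_shape = 1, plate_sd = 0, rep_sd = 0)
  traj <- simulate_viability(a1, d)
  expect_equal(traj$viability[traj$day == 4], exp(-1), tolerance = 1e-12)
  # k = 2 on the full grid vs direct formula evaluation
  a2 <- archetype_spec("y", tau = 4, k_shape = 2, plate_sd = 0, rep_sd = 0)
  traj2 <- simulate_viability(a2, d)
  expect_equal(traj2$viability, exp(-(d$timepoints / 4)^2), tolerance = 1e-12)
})

test_that("viability trajectories are monotone non-increasing", {
  d <- screen_design(timepoints = c(0, 1, 2, 3, 5, 8, 13), seed = 11)
  for (p in 1:3) for (r in c(1, 7)) {
    for (arch in control_archetypes(rep_sd = 0.3)) {
      v <- simulate_viability(arch, d, plate = p, replicate = r)$viability
      expect_true(all(diff(v) <= 0))
    }
  }
})

test_that("archetype and design invariants are enforced", {
  expect_error(archetype_spec("a", tau = -1), "tau")
  expect_error(archetype_spec("a", tau = 4, k_shape = 0), "k_shape")
  expect_error(archetype_spec("a", tau = 4, rep_sd = -0.1), "rep_sd")
  expect_error(screen_design(timepoints = c(2, 4)), "day 0")
  expect_error(screen_design(timepoints = c(0, 4, 4)), "increasing")
  expect_error(screen_design(events_per_sample = 0), "events_per_sample")
  expect_error(fluor_model(live_mu = 3, dead_mu = 2), "dead_mu")
})

test_that("emit_events splits live/dead by a binomial draw", {
  fl <- fluor_model()
  ev1 <- emit_events(1, fl, 500, seed = 1)
  expect_identical(nrow(ev1), 500L)
  expect_true(all(ev1$component == "live"))
  ev0 <- emit_events(0, fl, 500, seed = 1)
  expect_true(all(ev0$component == "dead"))
  # v = 0.7: dead count inside the central 99.9% binomial interval
  ev <- emit_events(0.7, fl, 10000, seed = 42)
  n_dead <- sum(ev$component == "dead")
  bounds <- qbinom(c(5e-4, 1 - 5e-4), 10000, 0.3)
  expect_gte(n_dead, bounds[1])
  expect_lte(n_dead, bounds[2])
  expect_error(emit_events(1.2, fl, 100), "\\[0, 1\\]")
})

test_that("event counts are conserved for every sample", {
  fl <- fluor_model()
  for (v in c(0, 0.2, 0.5, 0.9, 1)) {
    ev <- emit_events(v, fl, 777, seed = 5)
    expect_identical(nrow(ev), 777L)
    expect_identical(sum(ev$component == "live") + sum(ev$component == "dead"),
                     777L)
  }
})

test_that("a controls-only screen yields one sample per control and timepoint", {
  d <- screen_design(plates = 1, wells_per_plate = 3, events_per_sample = 50,
                     seed = 2)
  sim <- simulate_screen(d)
  samples <- unique(sim$events[, c("strain", "day")])
  expect_identical(nrow(samples), 3L * length(d$timepoints))
  expect_identical(nrow(sim$events), 3L * length(d$timepoints) * 50L)
  expect_setequal(unique(sim$truth$strain), c("666", "sty1d", "pka1d"))
})

test_that("every simulated plate carries exactly one well per control", {
  d <- screen_design(plates = 3, wells_per_plate = 8, events_per_sample = 20,
                     seed = 4)
  sim <- simulate_screen(d, make_mutant_map(5))
  ctrl <- sim$truth[sim$truth$strain %in% c("666", "sty1d", "pka1d"), ]
  tab <- table(ctrl$strain, ctrl$plate)
  expect_true(all(tab == 1))
  expect_identical(dim(tab), c(3L, 3L))
})

test_that("simulation is deterministic and stable under design extension", {
  d <- screen_design(plates = 2, wells_per_plate = 10, events_per_sample = 40,
                     seed = 9)
  map <- make_mutant_map(2)
  s1 <- simulate_screen(d, map)
  s2 <- simulate_screen(d, map)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$truth, s2$truth)
  # filling previously empty wells and adding plates must not perturb the
  # wells already simulated
  d_big <- screen_design(plates = 3, wells_per_plate = 10,
                         events_per_sample = 40, seed = 9)
  map_big <- c(map, setNames(rep(c("average", "short_lived", "long_lived"), 3),
                             sprintf("new%02d", seq_len(9))))
  s3 <- simulate_screen(d_big, map_big)
  old_wells <- unique(s1$events[, c("plate", "well", "strain")])
  for (i in seq_len(nrow(old_wells))) {
    a <- s1$events[s1$events$plate == old_wells$plate[i] &
                     s1$events$well == old_wells$well[i], ]
    b <- s3$events[s3$events$plate == old_wells$plate[i] &
                     s3$events$well == old_wells$well[i], ]
    expect_identical(a$pi_intensity, b$pi_intensity)
  }
})

test_that("layout errors are caught", {
  d <- screen_design(plates = 1, wells_per_plate = 4, events_per_sample = 10)
  map <- c(m1 = "average", m1 = "average")
  expect_error(simulate_screen(d, map), "duplicate strain")
  expect_error(simulate_screen(d, c(`666` = "average")), "collide")
  expect_error(simulate_screen(d, c(m1 = "no_such_label")), "no archetype")
  expect_error(simulate_screen(d, make_mutant_map(2)), "do not fit")
})

test_that("substream seeds are reproducible and key-sensitive", {
  expect_identical(substream_seed(1, 2, 3), substream_seed(1, 2, 3))
  expect_false(substream_seed(1, 2, 3) == substream_seed(1, 3, 2))
  expect_false(substream_seed(1, 2, 3) == substream_seed(2, 2, 3))
  s <- substream_seed(2^30, 999, 999, 999)
  expect_true(s >= 0 && s < 2^31)
})
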