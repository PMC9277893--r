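make_dists <- function(mean_avg = 450, mean_short = 250, mean_long = 650,
                       sd = 40, n = 31) {
  list(average = control_distribution("average", n, mean_avg, sd),
       short_lived = control_distribution("short_lived", n, mean_short, sd),
       long_lived = control_distribution("long_lived", n, mean_long, sd))
}

test_that("control fitting uses sample mean and n-1 standard deviation", {
  d <- fit_controls(c(10, 20, 30, 100, 110, 120, 200, 210, 220),
                    rep(c("short_lived", "average", "long_lived"), each = 3))
  expect_equal(d$short_lived$mean, 20)
  expect_equal(d$short_lived$sd, 10)
  expect_identical(d$short_lived$df, 2L)
  expect_error(fit_controls(c(5, 5, 5, 2, 3, 4), rep(c("average", "short_lived"), each = 3),
                            classes = c("average", "short_lived")), "zero spread")
  expect_error(fit_controls(1, "average", classes = "average"), "fewer than 2")
})

test_that("fitted moments recover a known normal within sampling error", {
  a <- withr::with_seed(8, rnorm(10000, 450, 40))
  d <- fit_controls(a, rep("average", 10000), classes = "average")$average
  se_mean <- 40 / sqrt(10000)
  se_sd <- 40 / sqrt(2 * 10000)
  expect_lt(abs(d$mean - 450), 3 * se_mean)
  expect_lt(abs(d$sd - 40), 3 * se_sd)
})

test_that("t-predictive likelihood matches direct density evaluation", {
  d <- control_distribution("average", 31, 450, 40)
  scale <- 40 * sqrt(1 + 1 / 31)
  # frozen reference computed from the standard t density by hand
  expect_equal(class_likelihood(640, d), dt((640 - 450) / scale, 30) / scale,
               tolerance = 1e-14)
  expect_equal(class_likelihood(640, d), 2.014409e-06, tolerance = 1e-6)
  # mode and symmetry
  expect_equal(class_likelihood(450, d), dt(0, 30) / scale, tolerance = 1e-14)
  expect_equal(class_likelihood(450 + 37, d), class_likelihood(450 - 37, d),
               tolerance = 1e-14)
  expect_true(class_likelihood(1e5, d) > 0)
})

test_that("posteriors normalise and match a brute-force density oracle", {
  dists <- make_dists()
  pc <- posterior_class(640, dists)
  expect_identical(pc$label, "long_lived")
  # independent normalisation of the three raw densities
  raw <- vapply(dists, function(d) {
    s <- d$sd * sqrt(1 + 1 / d$n)
    dt((640 - d$mean) / s, d$df) / s
  }, 0)
  expect_equal(unlist(pc[paste0("p_", names(dists))], use.names = FALSE),
               unname(raw / sum(raw)), tolerance = 1e-12)
  # an area at a well-separated class mean is called with near certainty
  pc2 <- posterior_class(250, dists)
  expect_identical(pc2$label, "short_lived")
  expect_gt(pc2$p_short_lived, 0.99)
  # posterior triples sum to 1 on random inputs
  areas <- withr::with_seed(10, runif(2000, -200, 1200))
  pm <- posterior_class(areas, dists)
  sums <- pm$p_average + pm$p_short_lived + pm$p_long_lived
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("log-space posteriors survive extreme areas", {
  dists <- make_dists()
  pc <- posterior_class(c(-1e5, 1e6), dists)
  expect_false(any(!is.finite(as.matrix(pc[paste0("p_", names(dists))]))))
  expect_identical(pc$label, c("short_lived", "long_lived"))
  # agreement with direct-density computation where it does not underflow
  areas <- seq(0, 900, by = 50)
  pc2 <- posterior_class(areas, dists)
  raw <- vapply(dists, function(d) class_likelihood(areas, d), numeric(length(areas)))
  direct <- raw / rowSums(raw)
  got <- as.matrix(pc2[paste0("p_", names(dists))])
  nz <- direct > 0
  expect_true(all(abs(got[nz] - direct[nz]) / direct[nz] < 1e-10))
})

test_that("equal-sd equal-n classes cross over exactly at the mean midpoint", {
  dists <- make_dists()
  for (pair in list(c("short_lived", "average"), c("average", "long_lived"))) {
    d1 <- dists[[pair[1]]]; d2 <- dists[[pair[2]]]
    f <- function(a) {
      p <- posterior_class(a, dists)
      p[[paste0("p_", pair[1])]] - p[[paste0("p_", pair[2])]]
    }
    cross <- uniroot(f, c(d1$mean, d2$mean), tol = 1e-10)$root
    expect_lt(abs(cross - (d1$mean + d2$mean) / 2), 1e-6)
  }
})

test_that("a zero prior makes its class unreachable", {
  dists <- make_dists()
  pc <- posterior_class(c(250, 251, 260), dists, priors = c(0.5, 0, 0.5))
  expect_true(all(pc$p_short_lived == 0))
  expect_true(all(pc$label != "short_lived"))
})

test_that("near-ties are flagged ambiguous and fall back conservatively", {
  dists <- make_dists()
  boundary <- (250 + 450) / 2
  pc <- posterior_class(boundary, dists, tie_epsilon = 1e-3)
  expect_true(pc$ambiguous)
  expect_identical(pc$label, "average")
})

test_that("classify_screen summarises replicates and counts classes", {
  dists <- make_dists()
  areas <- data.frame(
    strain = rep(c("sA", "sB", "sC"), each = 2),
    replicate = rep(c("1:A1", "2:A1"), 3),
    area = c(449, 451, 249, 251, 649, 651)
  )
  cls <- classify_screen(areas, dists)
  expect_identical(cls$label, c("average", "short_lived", "long_lived"))
  expect_identical(unname(attr(cls, "counts")), c(1L, 1L, 1L))
  expect_equal(cls$area_mean, c(450, 250, 650))
  expect_identical(cls$n_reps, c(2L, 2L, 2L))
  expect_error(classify_screen(areas[0, ], dists), "empty")
  # per-replicate majority vote agrees on clean data
  cls2 <- classify_screen(areas, dists, per_replicate = TRUE)
  expect_identical(cls2$label, cls$label)
})

test_that("well-separated synthetic screens are recovered almost perfectly", {
  d <- screen_design(plates = 8, wells_per_plate = 13,
                     events_per_sample = 800, seed = 17)
  sim <- simulate_screen(d, make_mutant_map(26))
  res <- screen_pipeline(sim$events)
  rec <- label_recovery(res, sim$truth)
  expect_gte(rec$recovery, 0.99)
})
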