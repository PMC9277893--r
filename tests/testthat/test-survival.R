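test_that("survival normalisation anchors the log sample at 100%", {
  nc <- normalize_curve(c(0, 2, 4), c(0.95, 0.76, 0.475))
  expect_equal(nc$survival_pct, c(100, 80, 50), tolerance = 1e-12)
  expect_false(any(nc$flagged))
  expect_error(normalize_curve(c(0, 2), c(0, 0.5)), "no growth")
  expect_error(normalize_curve(c(2, 4), c(0.9, 0.5)), "day-0")
  # above-100% survival is retained and flagged, not clamped
  nc2 <- normalize_curve(c(0, 2), c(0.8, 0.9))
  expect_equal(nc2$survival_pct[2], 112.5)
  expect_true(nc2$flagged[2])
})

test_that("trapezoidal area matches exact and dense-integration oracles", {
  days <- c(0, 2, 4, 6, 8)
  expect_identical(auc(days, rep(100, 5)), 800)
  expect_identical(auc(days, c(100, 0, 0, 0, 0)), 100)
  expect_error(auc(0, 100), "2 points")
  withr::with_seed(14, {
    for (i in 1:200) {
      surv <- c(100, runif(4, 0, 120))
      expect_equal(auc(days, surv), auc_dense_oracle(days, surv),
                   tolerance = 1e-9)
    }
  })
})

test_that("area is linear in survival scale and bounded by a terminal drop", {
  days <- c(0, 2, 4, 6, 8)
  withr::with_seed(5, {
    for (i in 1:50) {
      surv <- c(100, runif(4, 0, 110))
      c_scale <- runif(1, 0.1, 3)
      expect_equal(auc(days, surv * c_scale), c_scale * auc(days, surv),
                   tolerance = 1e-9)
      # appending a terminal 0% adds at most half a trapezoid
      a0 <- auc(days, surv)
      a1 <- auc(c(days, 10), c(surv, 0))
      expect_lte(a1, a0 + 0.5 * 2 * surv[5] + 1e-12)
      expect_gte(a1, a0)
    }
  })
})

test_that("areas integrate the observed span only", {
  curves <- data.frame(
    strain = "s", replicate = rep(c("r1", "r2"), c(5, 4)),
    day = c(0, 2, 4, 6, 8, 0, 2, 4, 6),
    survival_pct = c(100, 80, 60, 40, 20, 100, 80, 60, 40)
  )
  expect_warning(a <- curve_areas(curves), "spans")
  expect_identical(a[a$replicate == "r2", ]$span_end, 6)
  expect_equal(a[a$replicate == "r2", ]$area, auc(c(0, 2, 4, 6), c(100, 80, 60, 40)))
  a_norm <- suppressWarnings(curve_areas(curves, normalize_span = TRUE))
  expect_equal(a_norm$area, a$area / c(8, 6), tolerance = 1e-12)
})

test_that("identical constant replicates give a flat fit with zero band", {
  curves <- data.frame(
    strain = "s", replicate = rep(c("a", "b", "c"), each = 5),
    day = rep(c(0, 2, 4, 6, 8), 3), survival_pct = 70
  )
  av <- average_curve(curves)
  expect_equal(av$fit, rep(70, nrow(av)), tolerance = 1e-9)
  expect_equal(av$upper - av$lower, rep(0, nrow(av)), tolerance = 1e-9)
  expect_identical(attr(av, "n_replicates"), 3L)
  expect_error(average_curve(curves[curves$replicate == "a", ]), "2 replicates")
})

test_that("degree-1 full-span local regression reproduces the OLS line", {
  days <- rep(c(0, 2, 4, 6, 8), 2)
  surv <- 100 - 9 * days
  curves <- data.frame(strain = "s",
                       replicate = rep(c("a", "b"), each = 5),
                       day = days, survival_pct = surv)
  grid <- seq(0, 8, length.out = 41)
  av <- average_curve(curves, span = 1, degree = 1, grid = grid)
  ols <- lm(surv ~ days)
  expect_equal(av$fit, unname(predict(ols, data.frame(days = grid))),
               tolerance = 1e-8)
})

test_that("the 95% band covers a known trajectory at most grid days", {
  days <- c(0, 2, 4, 6, 8)
  truth <- 100 * weibull_survival(days, tau = 4.5, k_shape = 1.6)
  inside <- 0L; total <- 0L
  for (seed in 1:20) {
    curves <- withr::with_seed(seed, {
      do.call(rbind, lapply(1:30, function(r) {
        data.frame(strain = "s", replicate = sprintf("r%02d", r), day = days,
                   survival_pct = truth + rnorm(5, 0, 5))
      }))
    })
    av <- average_curve(curves, grid = days)
    inside <- inside + sum(truth >= av$lower & truth <= av$upper)
    total <- total + length(days)
  }
  expect_gte(inside / total, 0.9)
})

test_that("exclusion rules drop non-growing strains and log reasons", {
  viab <- data.frame(
    strain = rep(c("ok1", "ok2", "ok3", "dead0", "noqc"), each = 3),
    plate = 1, well = "A1",
    day = rep(c(0, 2, 4), 5),
    fraction_viable = c(rep(c(0.9, 0.7, 0.5), 3), 0, 0.0, 0.0, 0.9, 0.5, 0.3),
    n_events = 1000,
    qc_pass = c(rep(TRUE, 12), TRUE, FALSE, FALSE)
  )
  ex <- exclude_strains(viab)
  expect_setequal(ex$retained, c("ok1", "ok2", "ok3"))
  expect_identical(ex$excluded[ex$excluded$strain == "dead0", ]$reason,
                   "no growth")
  expect_identical(ex$excluded[ex$excluded$strain == "noqc", ]$reason,
                   "no stationary-phase data")
  # caller-supplied flags join the log
  ex2 <- exclude_strains(viab, growth_flags = data.frame(
    strain = "ok3", reason = "no regrowth on spots"))
  expect_setequal(ex2$retained, c("ok1", "ok2"))
  expect_identical(nrow(ex2$excluded), 3L)
  # downstream: classifier input counts only the retained strains
  keep <- viab[viab$strain %in% ex2$retained, ]
  curves <- build_curves(keep)
  expect_identical(length(unique(curves$strain)), 2L)
})
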