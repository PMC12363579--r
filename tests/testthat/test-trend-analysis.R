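pointsFrom <- function(fraction, deviation, patient = "P01") {
  data.frame(patient_id = patient, fraction = fraction, deviation = deviation)
}

test_that("olsTrend recovers exact lines and matches the closed form", {
  # noiseless line
  f <- rep(1:10, 3)
  fit <- olsTrend(pointsFrom(f, -0.33 * f - 4.675))
  expect_equal(fit$slope, -0.33, tolerance = 1e-12)
  expect_equal(fit$intercept, -4.675, tolerance = 1e-12)

  # four hand-listed points: slope 0.6, intercept 0.5
  fit <- olsTrend(pointsFrom(1:4, c(1, 2, 2, 3)))
  expect_equal(fit$slope, 0.6)
  expect_equal(fit$intercept, 0.5)

  # constant response
  expect_equal(olsTrend(pointsFrom(1:5, rep(2, 5)))$slope, 0)

  # degenerate design
  expect_error(olsTrend(pointsFrom(rep(3, 5), 1:5)), "degenerate")

  # oracle equivalence on random instances
  withr::with_seed(21, {
    for (rep in 1:20) {
      n <- sample(5:40, 1)
      x <- sample(1:30, n, replace = TRUE)
      if (length(unique(x)) < 2) next
      y <- rnorm(n, 2 - 0.1 * x, 3)
      fit <- olsTrend(pointsFrom(x, y))
      cf <- closedFormOls(x, y)
      expect_equal(fit$slope, unname(cf["slope"]), tolerance = 1e-10)
      expect_equal(fit$intercept, unname(cf["intercept"]), tolerance = 1e-10)
    }
  })
})

test_that("Cook's distances match the leave-one-out definition", {
  withr::with_seed(31, {
    for (rep in 1:15) {
      n <- sample(6:12, 1)
      x <- sample(1:10, n, replace = TRUE)
      if (length(unique(x)) < 3) next
      y <- rnorm(n, 1 + 0.5 * x, 1)
      pts <- pointsFrom(x, y)
      rep_out <- cooksOutliers(olsTrend(pts))
      expect_equal(rep_out$cooks, bruteCooks(x, y), tolerance = 1e-8)
    }
  })
})

test_that("outlier screening flags the gross outlier and respects the cap", {
  # collinear data: no influence anywhere
  pts <- pointsFrom(1:20, 2 * (1:20) + 1)
  rep_out <- cooksOutliers(olsTrend(pts))
  expect_true(all(rep_out$cooks < 1e-20))
  expect_false(any(rep_out$flagged))

  # one gross outlier among collinear points dominates
  y <- 2 * (1:20) + 1
  y[7] <- y[7] + 50
  rep_out <- cooksOutliers(olsTrend(pointsFrom(1:20, y)))
  expect_equal(which.max(rep_out$cooks), 7)
  expect_true(rep_out$flagged[7])

  # 6.2% cap: 1200 points, 100 gross outliers -> exactly 74 flagged
  withr::with_seed(41, {
    f <- rep(1:30, 40)
    y <- 0.1 * f + rnorm(1200, 0, 0.5)
    idx <- sample(1200, 100)
    y[idx] <- y[idx] + sample(c(-30, 30), 100, replace = TRUE)
    rep_out <- cooksOutliers(olsTrend(pointsFrom(f, y)), capRate = 0.062)
    expect_true(rep_out$capApplied)
    expect_equal(sum(rep_out$flagged), 74)
  })
})

test_that("refitting after exclusion restores the clean-data slope", {
  pts <- pointsFrom(1:20, 2 * (1:20) + 1)
  rep_out <- cooksOutliers(olsTrend(pts))
  expect_equal(refitAfterExclusion(pts, rep_out)$slope,
               olsTrend(pts)$slope)

  y <- 2 * (1:20) + 1
  y[3] <- y[3] - 80
  pts2 <- pointsFrom(1:20, y)
  dirty <- olsTrend(pts2)
  rep_out <- cooksOutliers(dirty)
  clean <- refitAfterExclusion(pts2, rep_out)
  expect_equal(clean$nOutliersRemoved, 1)
  expect_lt(abs(clean$slope - 2), abs(dirty$slope - 2))

  # flagging all but two points propagates the degenerate-design error
  fake <- list(flagged = c(rep(TRUE, 18), FALSE, FALSE))
  expect_error(refitAfterExclusion(pts2, fake), "3 points|degenerate")
})

test_that("the mixed model matches known slopes on noiseless designs", {
  # zero offsets, zero noise
  f <- rep(1:12, 4)
  pid <- rep(sprintf("P%02d", 1:4), each = 12)
  pts <- data.frame(patient_id = pid, fraction = f,
                    deviation = -0.2 * f + 1)
  fit <- lmmTrend(pts)
  expect_equal(fit$slope, -0.2, tolerance = 1e-6)

  # distinct patient offsets, balanced noiseless data: within-patient slope
  off <- rep(c(-4, -1, 2, 6), each = 12)
  pts$deviation <- -0.2 * f + off
  fit <- lmmTrend(pts)
  expect_equal(fit$slope, -0.2, tolerance = 1e-6)
  expect_true(fit$ciLow <= fit$slope && fit$slope <= fit$ciHigh)

  expect_error(lmmTrend(pts[pts$patient_id == "P01", ]), "2 patients")
})

test_that("per-fraction tests locate a planted step onset", {
  withr::with_seed(51, {
    m <- matrix(0, 40, 30)
    m[, 10:30] <- 10 + rnorm(40 * 21, 0, 0.01)
    res <- perFractionTests(m)
    expect_equal(res$earliest, 10L)
    expect_equal(res$threshold, 0.05 / 30)
  })

  # identically zero deviations: nothing significant
  res0 <- perFractionTests(matrix(0, 10, 30))
  expect_true(is.na(res0$earliest))

  # fractions with fewer than 2 patients are masked
  m <- matrix(rnorm(5 * 30), 5, 30)
  m[2:5, 4] <- NA
  expect_true(is.na(perFractionTests(m)$pValues[4]))
})

test_that("lowering alpha never makes the earliest fraction earlier", {
  withr::with_seed(61, {
    for (rep in 1:10) {
      m <- matrix(rnorm(20 * 30, mean = rep(seq(0, 1.5, length.out = 30),
                                            each = 20)), 20, 30)
      alphas <- c(0.2, 0.05, 0.01, 0.001)
      es <- vapply(alphas, function(a) {
        e <- perFractionTests(m, alpha = a)$earliest
        if (is.na(e)) 99L else e
      }, integer(1))
      expect_true(all(diff(es) >= 0))
    }
  })
})

test_that("fitTrend assembles a coherent TrendFit", {
  sim <- simulateCohort(defaultCohortConfig(), seed = 4)
  co <- buildCohort(sim$records)
  ft <- fitTrend(co, "GTV")
  expect_s4_class(ft, "TrendFit")
  expect_true(ft@ciLow <= ft@slope && ft@slope <= ft@ciHigh)
  expect_lte(ft@nOutliersRemoved / 1200, 0.062)
  expect_equal(ft@bonferroniAlpha, 0.05 / 30)
  p <- ft@pValues[!is.na(ft@pValues)]
  expect_true(all(p >= 0 & p <= 1))
})
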