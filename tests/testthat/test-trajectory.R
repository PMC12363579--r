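constantCohort <- function(values, F = 10, parameter = "Lung_Dmean",
                           planned = 15) {
  recs <- do.call(rbind, lapply(seq_along(values), function(i) {
    data.frame(patient_id = sprintf("P%02d", i), fraction = seq_len(F),
               parameter = parameter,
               value = planned * (1 + values[i] / 100),
               planned_value = planned)
  }))
  buildCohort(recs, nFractions = F)
}

test_that("mean trajectory applies the normal approximation exactly", {
  # identical members: zero-width band at the common value
  co <- constantCohort(rep(2.5, 4))
  tr <- meanTrajectory(co, "Lung_Dmean")
  expect_equal(tr$mean, rep(2.5, 10), tolerance = 1e-10)
  expect_equal(tr$ci_high - tr$ci_low, rep(0, 10), tolerance = 1e-10)

  # members {1, 2, 3}%: mean 2, band 2 +/- z * 1/sqrt(3) (sample SD = 1)
  co <- constantCohort(c(1, 2, 3))
  tr <- meanTrajectory(co, "Lung_Dmean")
  z <- qnorm(0.975)
  expect_equal(tr$mean[1], 2, tolerance = 1e-10)
  expect_equal(tr$ci_low[1], 2 - z * 1 / sqrt(3), tolerance = 1e-10)
  expect_equal(tr$ci_high[1], 2 + z * 1 / sqrt(3), tolerance = 1e-10)

  expect_error(meanTrajectory(co, "Lung_Dmean", members = character(0)),
               "empty cluster")
  expect_error(meanTrajectory(co, "Lung_Dmean", members = "P99"),
               "not in cohort")
})

test_that("duplicating members keeps means, shrinks bands by ~1/sqrt(2)", {
  withr::with_seed(101, {
    vals <- rnorm(6, 0, 2)
    co1 <- constantCohort(vals)
    co2 <- constantCohort(c(vals, vals))
    t1 <- meanTrajectory(co1, "Lung_Dmean")
    t2 <- meanTrajectory(co2, "Lung_Dmean")
    expect_equal(t2$mean, t1$mean, tolerance = 1e-10)
    w1 <- t1$ci_high - t1$ci_low
    w2 <- t2$ci_high - t2$ci_low
    # duplication halves the variance estimate's denominator n but keeps SD
    # (up to the n-1 correction), so the band shrinks by about 1/sqrt(2)
    expect_equal(w2 / w1, rep(sqrt(5 / 11), 10), tolerance = 1e-10)
    expect_lt(max(w2 / w1), 0.75)
  })
})

test_that("fractions with fewer than two members are masked", {
  rec <- rbind(
    data.frame(patient_id = "P01", fraction = 1:5, parameter = "GTV",
               value = 95, planned_value = 100),
    data.frame(patient_id = "P02", fraction = 1:4, parameter = "GTV",
               value = 93, planned_value = 100))
  co <- buildCohort(rec, nFractions = 5)
  tr <- meanTrajectory(co, "GTV")
  expect_false(anyNA(tr$mean[1:4]))
  expect_true(is.na(tr$mean[5]))
  expect_equal(tr$n[5], 1L)
})

test_that("the 95% band covers the true mean at nominal-like rates", {
  withr::with_seed(111, {
    hit <- 0; tot <- 0
    for (rep in 1:200) {
      true_mean <- runif(1, -5, 5)
      co <- constantCohort(rnorm(10, true_mean, 2), F = 1)
      tr <- meanTrajectory(co, "Lung_Dmean")
      hit <- hit + (tr$ci_low[1] <= true_mean && true_mean <= tr$ci_high[1])
      tot <- tot + 1
    }
    expect_gte(hit / tot, 0.90)
  })
})

test_that("report bundles assemble, round-trip, and flag absent sections", {
  sim <- simulateCohort(defaultCohortConfig(), seed = 6)
  co <- buildCohort(sim$records)
  tt <- trendTable(co, parameters = c("GTV", "CTV_D95"))

  dir <- withr::local_tempdir()
  # trends-only report: clustering marked absent
  idx <- assembleReport(dir, trends = tt)
  expect_false(idx$sections$clustering)
  back <- readReport(dir)
  expect_equal(back$trends$slope, tt$slope, tolerance = 1e-12)
  expect_null(back$cluster_assignments)

  # full report round-trips
  cl <- suppressWarnings(clusterCohort(co, oar = "Lung_Dmean", seed = 2))
  dt <- distinctivenessTable(co)
  traj <- clusterTrajectories(co, cl)
  dir2 <- withr::local_tempdir()
  idx2 <- assembleReport(dir2, trends = tt, distinct = dt, clusters = cl,
                         trajectories = traj)
  expect_true(idx2$sections$clustering)
  back2 <- readReport(dir2)
  expect_equal(nrow(back2$cluster_assignments), 40)
  expect_equal(back2$trajectories$mean, traj$mean, tolerance = 1e-10)
  expect_equal(sort(unique(back2$cluster_assignments$cluster[
    back2$cluster_assignments$retained])), retainedClusters(cl))

  # mismatched patient sets are rejected
  dt_bad <- dt
  rownames(dt_bad$values) <- paste0("X", seq_len(nrow(dt_bad$values)))
  expect_error(assembleReport(withr::local_tempdir(), trends = tt,
                              distinct = dt_bad, clusters = cl),
               "mismatched patient sets")
})

test_that("a full default run reports all fourteen parameters", {
  sim <- simulateCohort(defaultCohortConfig(), seed = 2)
  co <- buildCohort(sim$records)
  expect_equal(length(cohortParameters(co)), 14)
  expect_setequal(cohortParameters(co), deviationParameters())
})
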