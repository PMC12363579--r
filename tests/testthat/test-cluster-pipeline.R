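test_that("distinctiveness is the off-diagonal row mean", {
  # two series at distance d
  dm2 <- matrix(c(0, 3.5, 3.5, 0), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(unname(distinctiveness(dm2)), c(3.5, 3.5))

  # fixed 4x4 matrix, hand-computed row means
  dm4 <- matrix(c(0, 1, 2, 3,
                  1, 0, 4, 5,
                  2, 4, 0, 6,
                  3, 5, 6, 0), 4, 4, byrow = TRUE)
  dimnames(dm4) <- list(letters[1:4], letters[1:4])
  expect_equal(unname(distinctiveness(dm4)),
               c(2, 10 / 3, 4, 14 / 3))

  # identical series: all zero
  expect_equal(unname(distinctiveness(matrix(0, 3, 3))), rep(0, 3))
  expect_error(distinctiveness(matrix(0, 1, 1)), "at least 2")
})

test_that("the lowest-variance measure is selected, ties by precedence", {
  sel <- selectRepresentative(c(GTV_D95 = 5, CTV_D95 = 1, PTV_D95 = 1385.9))
  expect_equal(sel$parameter, "CTV_D95")
  expect_false(sel$tie)

  sel <- selectRepresentative(c(PTV_D95 = 2, GTV_D95 = 2, CTV_D95 = 2))
  expect_equal(sel$parameter, "GTV_D95")
  expect_true(sel$tie)

  sel <- selectRepresentative(c(CTV_D95 = 7))
  expect_equal(sel$parameter, "CTV_D95")
})

test_that("kmeansRows recovers planted groups and the exhaustive optimum", {
  # two groups of identical rows: perfect recovery, zero WSS
  base <- matrix(c(0, 0, 0, 9, 9, 9), 1)
  rows <- rbind(base[rep(1, 3), ], base[rep(1, 3), ] + 100)
  dm <- as.matrix(stats::dist(rows))
  dimnames(dm) <- list(paste0("S", 1:6), paste0("S", 1:6))
  km <- kmeansRows(dm, 2, seed = 5)
  expect_equal(length(unique(km$assignments[1:3])), 1)
  expect_equal(length(unique(km$assignments[4:6])), 1)
  expect_true(km$assignments[1] != km$assignments[4])
  expect_equal(km$totWss, 0)

  # exhaustive bipartition oracle on random instances, n <= 8
  withr::with_seed(81, {
    for (rep in 1:10) {
      n <- sample(5:8, 1)
      pts <- matrix(rnorm(2 * n), n)
      dm <- as.matrix(stats::dist(pts))
      dimnames(dm) <- list(paste0("S", seq_len(n)), paste0("S", seq_len(n)))
      km <- kmeansRows(dm, 2, seed = rep, nRestarts = 60)
      expect_equal(km$totWss, bruteBestBipartition(dm)$totWss,
                   tolerance = 1e-8)
    }
  })

  # k = n: singletons, zero WSS; k > n: error
  dm <- as.matrix(stats::dist(matrix(rnorm(8), 4)))
  dimnames(dm) <- list(paste0("S", 1:4), paste0("S", 1:4))
  km <- kmeansRows(dm, 4, seed = 1)
  expect_equal(sort(unname(km$assignments)), 1:4)
  expect_equal(km$totWss, 0)
  expect_error(kmeansRows(dm, 5, seed = 1), "exceeds")

  # determinism under a fixed seed
  dmr <- as.matrix(stats::dist(matrix(rnorm(20), 10)))
  dimnames(dmr) <- list(paste0("S", 1:10), paste0("S", 1:10))
  expect_identical(kmeansRows(dmr, 3, seed = 9)$assignments,
                   kmeansRows(dmr, 3, seed = 9)$assignments)
})

test_that("the elbow rule maximises discrete curvature", {
  expect_equal(elbowK(c(100, 20, 18, 17, 16))$k, 2L)
  expect_equal(elbowK(c(100, 60, 20, 19, 18))$k, 3L)

  # perfectly linear decay: smallest interior k, tie flagged
  lin <- elbowK(seq(100, 20, length.out = 6))
  expect_equal(lin$k, 2L)
  expect_true(lin$tie)

  # flat scree is degenerate: elbow defaults to 1
  flat <- elbowK(rep(0, 6))
  expect_true(flat$degenerate)
  expect_equal(flat$k, 1L)

  expect_error(elbowK(c(5, 4)), "at least 3")
})

test_that("small-cluster exclusion partitions the cohort exactly", {
  asg <- stats::setNames(rep(c(1L, 2L), c(32, 8)), sprintf("P%02d", 1:40))
  rc <- fxtrend:::retainClusters(asg, minSize = 10)
  expect_equal(rc$retained, 1L)
  expect_equal(length(rc$outliers), 8)
  expect_equal(sum(rc$sizes[as.character(rc$retained)]) +
                 length(rc$outliers), 40)

  # every member is either retained or an outlier, over random partitions
  withr::with_seed(91, {
    for (rep in 1:10) {
      asg <- stats::setNames(sample(1:4, 25, replace = TRUE),
                             paste0("P", 1:25))
      rc <- fxtrend:::retainClusters(asg, minSize = 7)
      n_ret <- sum(asg %in% rc$retained)
      expect_equal(n_ret + length(rc$outliers), 25)
    }
  })
})

test_that("clusterCohort separates planted variability groups", {
  tg <- twoGroupCohort(n1 = 12, n2 = 12, F = 12, sd1 = 0.2, sd2 = 4)
  cl <- suppressWarnings(
    clusterCohort(tg$cohort, oar = "Lung_Dmean", minSize = 5, seed = 3))
  expect_s4_class(cl, "ClusterResult")
  expect_gte(cl@kUsed, 2)
  expect_equal(cl@kUsed, cl@kElbow + 1L)
  # members of excluded clusters are exactly the outlier patients
  asg <- clusterAssignments(cl)
  expect_equal(sum(asg %in% retainedClusters(cl)) +
                 length(outlierPatients(cl)), 24)
  # the two planted groups are not merged: the dominant retained split
  # aligns with truth
  keep <- !(names(asg) %in% outlierPatients(cl))
  ari <- mclust::adjustedRandIndex(asg[keep], tg$truth[keep])
  expect_gte(ari, 0.8)

  # end-to-end determinism
  cl2 <- suppressWarnings(
    clusterCohort(tg$cohort, oar = "Lung_Dmean", minSize = 5, seed = 3))
  expect_identical(clusterAssignments(cl), clusterAssignments(cl2))
  expect_identical(cl@scree, cl2@scree)
})

test_that("identical patients give a degenerate flat scree", {
  rec <- do.call(rbind, lapply(sprintf("P%02d", 1:8), function(p) {
    rbind(data.frame(patient_id = p, fraction = 1:6, parameter = "CTV_D95",
                     value = 60.3, planned_value = 60),
          data.frame(patient_id = p, fraction = 1:6,
                     parameter = "Lung_Dmean", value = 15.4,
                     planned_value = 15))
  }))
  co <- buildCohort(rec, nFractions = 6)
  cl <- clusterCohort(co, oar = "Lung_Dmean", minSize = 2, seed = 1)
  expect_true(cl@degenerateElbow)
  expect_equal(cl@kUsed, 2L)
  expect_equal(length(retainedClusters(cl)), 1L)

  # all clusters below the minimum size is an explicit error
  expect_error(clusterCohort(co, oar = "Lung_Dmean", minSize = 20, seed = 1),
               "no retained clusters")
})
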