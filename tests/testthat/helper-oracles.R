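# Independent brute-force oracles used to validate the dynamic-programming,
# influence and clustering code paths on small instances.

# DTW by exhaustive enumeration of all monotone warping paths (moves:
# down, right, diagonal). Feasible for series lengths <= 5.
bruteDtw <- function(x, y, sym2 = TRUE) {
  n <- if (is.matrix(x)) nrow(x) else length(x)
  m <- if (is.matrix(y)) nrow(y) else length(y)
  cost <- function(i, j) {
    if (is.matrix(x)) sqrt(sum((x[i, ] - y[j, ])^2)) else abs(x[i] - y[j])
  }
  best <- Inf
  recur <- function(i, j, acc) {
    if (i == n && j == m) {
      best <<- min(best, acc)
      return(invisible(NULL))
    }
    if (i < n) recur(i + 1, j, acc + cost(i + 1, j))
    if (j < m) recur(i, j + 1, acc + cost(i, j + 1))
    if (i < n && j < m) {
      recur(i + 1, j + 1, acc + (if (sym2) 2 else 1) * cost(i + 1, j + 1))
    }
  }
  recur(1, 1, cost(1, 1))
  best
}

# Cook's distance by the leave-one-out definition: refit without point i and
# compare fitted values on the full design. p = 2 parameters.
bruteCooks <- function(fraction, deviation) {
  n <- length(deviation)
  X <- cbind(1, fraction)
  full <- stats::lm.fit(X, deviation)
  s2 <- sum(full$residuals^2) / (n - 2)
  yhat <- X %*% full$coefficients
  vapply(seq_len(n), function(i) {
    drop_fit <- stats::lm.fit(X[-i, , drop = FALSE], deviation[-i])
    yhat_i <- X %*% drop_fit$coefficients
    sum((yhat - yhat_i)^2) / (2 * s2)
  }, numeric(1))
}

# Optimal 2-partition of distance-matrix rows by exhaustive search over all
# bipartitions, scored by total within-cluster sum of squares.
bruteBestBipartition <- function(rows) {
  n <- nrow(rows)
  stopifnot(n <= 12)
  wssOf <- function(idx) {
    if (!length(idx)) return(0)
    ctr <- colMeans(rows[idx, , drop = FALSE])
    sum(sweep(rows[idx, , drop = FALSE], 2, ctr)^2)
  }
  best <- Inf
  bestSplit <- NULL
  for (mask in 1:(2^(n - 1) - 1)) {  # fix element n in group B: avoids mirrors
    a <- which(bitwAnd(mask, 2^(seq_len(n - 1) - 1)) > 0)
    b <- setdiff(seq_len(n), a)
    tot <- wssOf(a) + wssOf(b)
    if (tot < best) {
      best <- tot
      bestSplit <- list(a = a, b = b)
    }
  }
  list(totWss = best, split = bestSplit)
}

# Closed-form simple linear regression via the normal equations.
closedFormOls <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  c(intercept = mean(y) - slope * mean(x), slope = slope)
}

# Small valid record table for I/O round-trips.
randomRecords <- function(n_patients = 3, n_fractions = 4,
                          parameters = c("GTV", "Lung_Dmean")) {
  grid <- expand.grid(patient_id = sprintf("P%02d", seq_len(n_patients)),
                      fraction = seq_len(n_fractions),
                      parameter = parameters,
                      stringsAsFactors = FALSE)
  grid$planned_value <- stats::runif(nrow(grid), 50, 150)
  grid$value <- grid$planned_value * (1 + stats::rnorm(nrow(grid), 0, 0.05))
  grid[c("patient_id", "fraction", "parameter", "value", "planned_value")]
}

# A tiny deterministic cohort with two planted variability groups, built
# directly from records (no generator involved).
twoGroupCohort <- function(n1 = 6, n2 = 6, F = 12, sd1 = 0.2, sd2 = 3,
                           seed = 42) {
  withr::with_seed(seed, {
    ids <- sprintf("P%02d", seq_len(n1 + n2))
    recs <- do.call(rbind, lapply(seq_along(ids), function(i) {
      sdv <- if (i <= n1) sd1 else sd2
      dev_ctv <- stats::rnorm(F, 0, 0.1)
      dev_oar <- stats::rnorm(F, 0, sdv)
      rbind(
        data.frame(patient_id = ids[i], fraction = seq_len(F),
                   parameter = "CTV_D95", value = 60 * (1 + dev_ctv / 100),
                   planned_value = 60),
        data.frame(patient_id = ids[i], fraction = seq_len(F),
                   parameter = "Lung_Dmean", value = 15 * (1 + dev_oar / 100),
                   planned_value = 15))
    }))
    list(cohort = buildCohort(recs, nFractions = F),
         truth = rep(1:2, c(n1, n2)))
  })
}
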