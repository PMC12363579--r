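#' Specification of one simulated parameter
#'
#' Describes how one monitored parameter is generated: the planned baseline
#' distribution across patients, the linear percent-per-fraction trend, the
#' between-patient offset spread, and the within-patient AR(1) noise for the
#' two planted variability regimes (a low-variability majority cluster and a
#' high-variability minority cluster whose noise SD is, by default, three
#' times larger).
#'
#' The per-fraction mean deviation is \code{intercept + slope * f}; the
#' intercept is derived from the cohort-average deviation by the linear-ramp
#' identity \code{mean over f = 1..F equals intercept + slope * (F + 1) / 2}
#' (15.5 for F = 30), so \code{average_deviation} is the calibration surface.
#'
#' @param parameter Label from \code{\link{deviationParameters}}.
#' @param baseline_mean,baseline_sd Planned value distribution across patients
#'   (cm3 for volumes, Gy for doses); mean must be positive.
#' @param average_deviation Cohort-mean percentage deviation over the course.
#' @param slope Trend in percent per fraction.
#' @param patient_offset_sd SD (percent) of the patient-level random offset.
#' @param noise_sd_cluster1 AR(1) stationary noise SD (percent) in the
#'   low-variability cluster.
#' @param noise_sd_cluster2 Same for the high-variability cluster; defaults
#'   to three times cluster 1.
#' @param ar1_rho Within-patient serial correlation, |rho| < 1.
#' @return A \code{ParameterSpec} (list).
#' @export
parameterSpec <- function(parameter, baseline_mean, baseline_sd,
                          average_deviation, slope, patient_offset_sd,
                          noise_sd_cluster1,
                          noise_sd_cluster2 = 3 * noise_sd_cluster1,
                          ar1_rho = 0.3) {
  stopifnot(parameter %in% deviationParameters(),
            baseline_mean > 0, baseline_sd >= 0,
            patient_offset_sd >= 0,
            noise_sd_cluster1 >= 0, noise_sd_cluster2 >= 0,
            abs(ar1_rho) < 1)
  structure(list(parameter = parameter,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 average_deviation = average_deviation, slope = slope,
                 patient_offset_sd = patient_offset_sd,
                 noise_sd_cluster1 = noise_sd_cluster1,
                 noise_sd_cluster2 = noise_sd_cluster2,
                 ar1_rho = ar1_rho),
            class = "ParameterSpec")
}

#' Intercept of a linear deviation ramp from its course average
#'
#' For a linear trend over fractions 1..F the course-mean deviation is
#' \code{intercept + slope * (F + 1) / 2}; this inverts that identity.
#'
#' @param average_deviation Cohort-mean deviation (percent).
#' @param slope Percent per fraction.
#' @param nFractions Course length F.
#' @return The intercept (deviation at a hypothetical fraction 0 trend line).
#' @export
trendIntercept <- function(average_deviation, slope, nFractions = 30L) {
  average_deviation - slope * (nFractions + 1) / 2
}

#' Cohort simulation configuration
#'
#' @param n_patients Cohort size (default 40).
#' @param n_fractions Course length (default 30; 60 Gy in 2 Gy fractions).
#' @param cluster1_proportion Share of patients in the low-variability
#'   cluster (default 0.65).
#' @param outlier_point_rate Fraction of (patient, fraction) slots per
#'   parameter replaced by a high-leverage point; must not exceed 0.062
#'   (74/1200), the screening cap used downstream. Default 0.03.
#' @param outlier_magnitude Magnitude (percent) of injected outliers, applied
#'   with a random sign in place of the noise term. \code{NULL} (default)
#'   scales per parameter: \code{outlier_magnitude_factor} times that
#'   parameter's cluster-1 noise SD, so outliers are high-leverage on every
#'   parameter's own scale.
#' @param outlier_magnitude_factor Per-parameter magnitude multiplier used
#'   when \code{outlier_magnitude} is NULL (default 12).
#' @param seed Default RNG seed used by \code{\link{simulateCohort}} when no
#'   seed argument is given.
#' @param specs Named list of \code{\link{parameterSpec}} objects.
#' @return A \code{CohortConfig} (list).
#' @seealso \code{\link{defaultCohortConfig}}
#' @export
cohortConfig <- function(n_patients = 40L, n_fractions = 30L,
                         cluster1_proportion = 0.65,
                         outlier_point_rate = 0.03,
                         outlier_magnitude = NULL,
                         outlier_magnitude_factor = 12,
                         seed = 1L,
                         specs = defaultParameterSpecs()) {
  stopifnot(n_patients >= 1, n_fractions >= 1,
            cluster1_proportion > 0, cluster1_proportion < 1,
            outlier_point_rate >= 0, outlier_point_rate <= 0.062,
            outlier_magnitude_factor >= 0,
            is.null(outlier_magnitude) ||
              (is.numeric(outlier_magnitude) && outlier_magnitude >= 0))
  if (!length(specs) || !all(vapply(specs, inherits, logical(1),
                                    "ParameterSpec"))) {
    stop("specs must be a list of parameterSpec objects", call. = FALSE)
  }
  names(specs) <- vapply(specs, `[[`, character(1), "parameter")
  structure(list(n_patients = as.integer(n_patients),
                 n_fractions = as.integer(n_fractions),
                 cluster1_proportion = cluster1_proportion,
                 outlier_point_rate = outlier_point_rate,
                 outlier_magnitude = outlier_magnitude,
                 outlier_magnitude_factor = outlier_magnitude_factor,
                 seed = as.integer(seed),
                 specs = specs),
            class = "CohortConfig")
}

#' Default parameter specifications
#'
#' Slopes and course-average deviations follow the published per-fraction
#' rates for a 40-patient NSCLC cohort (GTV -0.33, CTV -0.24, PTV -0.18 %/fx
#' for target volumes; Lung_Dmean +0.13 %/fx, etc.). Baseline volumes use the
#' cohort's target-volume summary (GTV 287.5 +/- 208.5 cm3, ...); OAR volumes
#' and doses use typical thoracic planning values. Dispersion defaults are
#' derived analytically, not fitted: for volumetric parameters the
#' between-patient SD is sized so the Bonferroni-corrected per-fraction test
#' first fires at the published earliest significant fraction; for dose
#' parameters the dispersion is kept small enough that mixed-model slope CIs
#' match the published precision and the cluster-noise contrast (3x) remains
#' the dominant signal for DTW clustering. See the methods vignette.
#'
#' @return Named list of \code{\link{parameterSpec}} objects.
#' @export
defaultParameterSpecs <- function() {
  tab <- list(
    #              base.mean base.sd   avg   slope  off.sd   c1
    GTV             = c(287.5, 208.5, -9.79, -0.33, 11.50, 1.30),
    CTV             = c(496.8, 282.5, -7.14, -0.24,  8.20, 0.80),
    PTV             = c(730.5, 354.3, -5.34, -0.18,  6.70, 0.80),
    Lung            = c(3500,  800,    0.53,  0.02,  2.80, 0.50),
    Esophagus       = c(35,    10,     2.56,  0.09,  8.80, 0.80),
    Heart           = c(600,   120,   -1.67, -0.06,  3.40, 0.50),
    SpinalCord      = c(45,    10,    -0.38, -0.01,  1.90, 0.30),
    GTV_D95         = c(60.8,  0.8,    0.37,  0.01,  0.24, 0.15),
    CTV_D95         = c(60.4,  0.7,    0.29,  0.01,  0.15, 0.10),
    PTV_D95         = c(59.2,  1.0,    0.65,  0.02,  2.00, 0.35),
    Lung_Dmean      = c(14,    4,      3.87,  0.13,  0.50, 0.45),
    Esophagus_Dmean = c(22,    6,      3.40,  0.11,  0.60, 0.50),
    Heart_Dmean     = c(9,     4,      2.07,  0.07,  0.80, 0.60),
    SpinalCord_Dmax = c(38,    5,      0.57,  0.02,  0.70, 0.50))
  out <- lapply(names(tab), function(p) {
    v <- tab[[p]]
    parameterSpec(p, baseline_mean = v[1], baseline_sd = v[2],
                  average_deviation = v[3], slope = v[4],
                  patient_offset_sd = v[5], noise_sd_cluster1 = v[6])
  })
  names(out) <- names(tab)
  out
}

#' @rdname cohortConfig
#' @export
defaultCohortConfig <- function() cohortConfig()

#' Simulate a synthetic per-fraction cohort
#'
#' Generates fraction records with the statistical structure the analysis
#' assumes. For patient i, parameter p, fraction f the percentage deviation is
#' \deqn{d_{if} = a_p + b_p f + u_i + e_{if}}
#' with intercept \code{a_p} derived from the course-average calibration
#' (\code{\link{trendIntercept}}), patient offsets \code{u_i} Gaussian with
#' the spec's SD and centred to sum to zero (so the cohort mean tracks the
#' calibrated ramp rather than the luck of the offset draws), and
#' \code{e_{if}} stationary AR(1) noise whose SD depends on the patient's
#' planted cluster. A fixed share of uniformly chosen slots per parameter
#' carry a high-leverage outlier (random sign) in place of the noise term.
#' Absolute values are reconstructed as \code{planned * (1 + d/100)} from a
#' per-patient planned baseline. CTV_D95 deviations are rescaled, if ever
#' necessary, so the cohort mean stays within 1\% of plan at every fraction
#' (at the default calibration the ramp peaks well below that and no
#' rescaling occurs).
#'
#' @param config A \code{\link{cohortConfig}}.
#' @param seed Integer seed; identical seeds give byte-identical cohorts.
#'   Defaults to \code{config$seed}.
#' @return List with \code{records} (fraction-record data.frame) and
#'   \code{truth}: per-patient cluster labels, per-parameter generating
#'   slope/intercept table, patient offsets, injected outlier slots, and any
#'   CTV_D95 rescale factor.
#' @examples
#' sim <- simulateCohort(defaultCohortConfig(), seed = 7)
#' head(sim$records)
#' table(sim$truth$cluster)
#' @export
simulateCohort <- function(config = defaultCohortConfig(),
                           seed = config$seed) {
  stopifnot(inherits(config, "CohortConfig"))
  n <- config$n_patients
  F <- config$n_fractions
  patients <- sprintf("P%02d", seq_len(n))
  n1 <- round(config$cluster1_proportion * n)
  cluster <- rep(c(1L, 2L), c(n1, n - n1))
  names(cluster) <- patients

  withSeed(seed, {
    per_param <- lapply(config$specs, function(sp) {
      a <- trendIntercept(sp$average_deviation, sp$slope, F)
      planned <- stats::rnorm(n, sp$baseline_mean, sp$baseline_sd)
      planned <- pmax(planned, 0.05 * sp$baseline_mean)  # physical floor
      # conditional draw: offsets are centred and rescaled so each simulated
      # cohort carries exactly the specified between-patient mean (0) and SD,
      # keeping the cohort-level calibration free of offset sampling luck
      offsets <- stats::rnorm(n, 0, sp$patient_offset_sd)
      offsets <- offsets - mean(offsets)
      if (n > 2 && stats::sd(offsets) > 0) {
        offsets <- offsets * sp$patient_offset_sd / stats::sd(offsets)
      }
      sdv <- ifelse(cluster == 1L, sp$noise_sd_cluster1, sp$noise_sd_cluster2)
      rho <- sp$ar1_rho
      noise <- matrix(0, n, F)
      for (i in seq_len(n)) {
        e <- numeric(F)
        e[1] <- stats::rnorm(1, 0, sdv[i])
        if (F > 1) {
          innov <- stats::rnorm(F - 1, 0, sdv[i] * sqrt(1 - rho^2))
          for (f in 2:F) e[f] <- rho * e[f - 1] + innov[f - 1]
        }
        noise[i, ] <- e
      }
      dev <- outer(offsets, a + sp$slope * seq_len(F), `+`) + noise

      n_out <- floor(config$outlier_point_rate * n * F)
      out_slots <- NULL
      if (n_out > 0) {
        mag <- if (is.null(config$outlier_magnitude))
          config$outlier_magnitude_factor * sp$noise_sd_cluster1
        else config$outlier_magnitude
        slots <- sample.int(n * F, n_out)
        sgn <- sample(c(-1, 1), n_out, replace = TRUE)
        ii <- ((slots - 1L) %% n) + 1L
        ff <- ((slots - 1L) %/% n) + 1L
        dev[cbind(ii, ff)] <- outer(offsets, a + sp$slope * seq_len(F),
                                    `+`)[cbind(ii, ff)] + sgn * mag
        out_slots <- data.frame(patient_id = patients[ii], fraction = ff,
                                parameter = sp$parameter,
                                magnitude = sgn * mag,
                                stringsAsFactors = FALSE)
      }
      list(spec = sp, intercept = a, planned = planned, offsets = offsets,
           dev = dev, outliers = out_slots)
    })

    # keep mean CTV_D95 deviation within 1% of plan at every fraction
    ctv_scale <- 1
    if ("CTV_D95" %in% names(per_param)) {
      m <- colMeans(per_param$CTV_D95$dev)
      peak <- max(abs(m))
      if (peak >= 0.99) {
        ctv_scale <- 0.99 / peak
        per_param$CTV_D95$dev <- per_param$CTV_D95$dev * ctv_scale
      }
    }

    records <- do.call(rbind, lapply(per_param, function(pp) {
      data.frame(patient_id = rep(patients, F),
                 fraction = rep(seq_len(F), each = n),
                 parameter = pp$spec$parameter,
                 value = as.vector(pp$planned * (1 + pp$dev / 100)),
                 planned_value = rep(pp$planned, F),
                 stringsAsFactors = FALSE)
    }))
    rownames(records) <- NULL
    records <- records[order(records$patient_id, records$parameter,
                             records$fraction), ]
    rownames(records) <- NULL

    truth <- list(
      cluster = cluster,
      parameters = data.frame(
        parameter = names(per_param),
        slope = vapply(per_param, function(pp) pp$spec$slope, numeric(1)),
        intercept = vapply(per_param, function(pp) pp$intercept, numeric(1)),
        average_deviation = vapply(per_param, function(pp)
          pp$spec$average_deviation, numeric(1)),
        noise_sd_cluster1 = vapply(per_param, function(pp)
          pp$spec$noise_sd_cluster1, numeric(1)),
        noise_sd_cluster2 = vapply(per_param, function(pp)
          pp$spec$noise_sd_cluster2, numeric(1)),
        patient_offset_sd = vapply(per_param, function(pp)
          pp$spec$patient_offset_sd, numeric(1)),
        row.names = NULL, stringsAsFactors = FALSE),
      offsets = lapply(per_param, function(pp)
        stats::setNames(pp$offsets, patients)),
      outliers = do.call(rbind, c(lapply(per_param, function(pp) pp$outliers),
                                  list(make.row.names = FALSE))),
      ctv_d95_scale = ctv_scale,
      seed = seed)
    list(records = records, truth = truth)
  })
}

#' Echo the generating truth of a simulated cohort
#'
#' Returns the generator's ground-truth table (one row per parameter: slope,
#' intercept, average deviation, noise regime SDs) for parameter-recovery
#' checks, plus cluster sizes.
#'
#' @param truth The \code{truth} element of \code{\link{simulateCohort}}.
#' @return Data frame of generating parameters with cluster sizes in
#'   \code{attr(, "cluster_sizes")}.
#' @export
truthReport <- function(truth) {
  stopifnot(is.list(truth), !is.null(truth$parameters))
  out <- truth$parameters
  attr(out, "cluster_sizes") <- as.vector(table(truth$cluster))
  out
}

#' @export
print.CohortConfig <- function(x, ...) {
  cat("CohortConfig:", x$n_patients, "patients x", x$n_fractions,
      "fractions\n")
  cat("  cluster 1 proportion:", x$cluster1_proportion,
      "| outlier point rate:", x$outlier_point_rate, "\n")
  cat("  parameters:", paste(names(x$specs), collapse = ", "), "\n")
  invisible(x)
}
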