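#' Mean deviation trajectory with 95% confidence band
#'
#' Per-fraction mean percentage deviation across a set of patients (one
#' cluster, typically) with the standard-normal-approximation 95\% band:
#' mean +/- 1.96 * SD / sqrt(n), sample SD with the n - 1 denominator.
#' Exactly z = 1.96 is used, not a t quantile, even for small clusters —
#' the normal approximation is part of the method and its small-sample
#' optimism is documented rather than corrected. Fractions observed in
#' fewer than two members are masked (NA band).
#'
#' @param cohort A \linkS4class{DeviationCohort}.
#' @param parameter Parameter to summarise.
#' @param members Patient ids to average over (default: whole cohort).
#' @param cluster Optional cluster id carried into the output.
#' @return Data frame: \code{cluster}, \code{parameter}, \code{fraction},
#'   \code{n}, \code{mean}, \code{ci_low}, \code{ci_high}.
#' @export
meanTrajectory <- function(cohort, parameter, members = patientIds(cohort),
                           cluster = NA_integer_) {
  if (!length(members)) stop("empty cluster: no members to summarise",
                             call. = FALSE)
  missing_ids <- setdiff(members, patientIds(cohort))
  if (length(missing_ids)) {
    stop("members not in cohort: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  m <- deviationMatrix(cohort, parameter)[members, , drop = FALSE]
  z <- stats::qnorm(0.975)  # 1.959964; reported as the 1.96 normal band
  n <- colSums(!is.na(m))
  mu <- ifelse(n >= 1, colMeans(m, na.rm = TRUE), NA_real_)
  sd <- apply(m, 2, stats::sd, na.rm = TRUE)
  se <- ifelse(n >= 2, sd / sqrt(n), NA_real_)
  mask <- n < 2
  mu[mask] <- NA_real_
  data.frame(cluster = cluster, parameter = parameter,
             fraction = seq_len(ncol(m)), n = as.integer(n),
             mean = mu,
             ci_low = mu - z * se, ci_high = mu + z * se,
             stringsAsFactors = FALSE)
}

#' Per-cluster mean trajectories for retained clusters
#'
#' @param cohort A \linkS4class{DeviationCohort}.
#' @param clusters A \linkS4class{ClusterResult} on the same cohort.
#' @param parameters Parameters to summarise (default: the clustered pair).
#' @return Data frame stacking \code{\link{meanTrajectory}} over retained
#'   clusters and parameters.
#' @export
clusterTrajectories <- function(cohort, clusters,
                                parameters = c(clusters@target,
                                               clusters@oar)) {
  stopifnot(methods::is(clusters, "ClusterResult"))
  asg <- clusterAssignments(clusters)
  if (!all(names(asg) %in% patientIds(cohort))) {
    stop("cluster result does not match this cohort's patients",
         call. = FALSE)
  }
  out <- lapply(retainedClusters(clusters), function(cl) {
    members <- names(asg)[asg == cl]
    do.call(rbind, lapply(parameters, function(p)
      meanTrajectory(cohort, p, members = members, cluster = cl)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Assemble an analysis report bundle
#'
#' Writes one machine-readable bundle for a cohort run: the trend table,
#' the distinctiveness table, cluster assignments, and per-cluster
#' trajectories as CSVs plus a JSON index. Sections not supplied are marked
#' absent in the index (a trends-only report is valid). Deterministic given
#' its inputs; \code{\link{readReport}} round-trips the bundle.
#'
#' @param dir Output directory (created if needed).
#' @param trends Data frame from \code{\link{trendTable}}.
#' @param distinct Optional result of \code{\link{distinctivenessTable}}.
#' @param clusters Optional \linkS4class{ClusterResult}.
#' @param trajectories Optional data frame from
#'   \code{\link{clusterTrajectories}}.
#' @return The index (list), invisibly.
#' @export
assembleReport <- function(dir, trends, distinct = NULL, clusters = NULL,
                           trajectories = NULL) {
  stopifnot(is.data.frame(trends))
  if (!is.null(distinct) && !is.null(clusters)) {
    if (!setequal(rownames(distinct$values),
                  names(clusterAssignments(clusters)))) {
      stop("mismatched patient sets between distinctiveness and clustering",
           call. = FALSE)
    }
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  index <- list(sections = list(trends = TRUE,
                                distinctiveness = !is.null(distinct),
                                clustering = !is.null(clusters),
                                trajectories = !is.null(trajectories)))
  utils::write.csv(trends, file.path(dir, "trends.csv"), row.names = FALSE)
  if (!is.null(distinct)) {
    dd <- data.frame(patient_id = rownames(distinct$values),
                     distinct$values, row.names = NULL, check.names = FALSE)
    utils::write.csv(dd, file.path(dir, "distinctiveness.csv"),
                     row.names = FALSE)
    index$distinctiveness_variance <- as.list(distinct$variance)
  }
  if (!is.null(clusters)) {
    asg <- clusterAssignments(clusters)
    ca <- data.frame(patient_id = names(asg), cluster = as.integer(asg),
                     retained = asg %in% retainedClusters(clusters),
                     row.names = NULL)
    utils::write.csv(ca, file.path(dir, "cluster_assignments.csv"),
                     row.names = FALSE)
    index$clustering_summary <- list(
      target = clusters@target, oar = clusters@oar,
      k_elbow = clusters@kElbow, k_used = clusters@kUsed,
      scree = as.numeric(clusters@scree),
      retained = as.integer(retainedClusters(clusters)),
      n_outlier_patients = length(outlierPatients(clusters)))
  }
  if (!is.null(trajectories)) {
    utils::write.csv(trajectories, file.path(dir, "trajectories.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(index, file.path(dir, "index.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(index)
}

#' @rdname assembleReport
#' @export
readReport <- function(dir) {
  index <- jsonlite::read_json(file.path(dir, "index.json"),
                               simplifyVector = TRUE)
  out <- list(index = index,
              trends = utils::read.csv(file.path(dir, "trends.csv"),
                                       stringsAsFactors = FALSE))
  sections <- index$sections
  if (isTRUE(sections$distinctiveness)) {
    out$distinctiveness <- utils::read.csv(
      file.path(dir, "distinctiveness.csv"), stringsAsFactors = FALSE,
      check.names = FALSE)
  }
  if (isTRUE(sections$clustering)) {
    out$cluster_assignments <- utils::read.csv(
      file.path(dir, "cluster_assignments.csv"), stringsAsFactors = FALSE)
  }
  if (isTRUE(sections$trajectories)) {
    out$trajectories <- utils::read.csv(file.path(dir, "trajectories.csv"),
                                        stringsAsFactors = FALSE)
  }
  out
}

#' Plot cluster mean trajectories
#'
#' Fraction-by-fraction mean deviation with its 95\% band, one panel per
#' parameter, coloured by cluster. Requires ggplot2.
#'
#' @param trajectories Data frame from \code{\link{clusterTrajectories}}.
#' @return A ggplot object.
#' @export
plotTrajectories <- function(trajectories) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plotTrajectories requires the ggplot2 package", call. = FALSE)
  }
  trajectories$cluster <- factor(trajectories$cluster)
  ggplot2::ggplot(trajectories,
                  ggplot2::aes(x = .data$fraction, y = .data$mean,
                               colour = .data$cluster,
                               fill = .data$cluster)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey40") +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = "Fraction", y = "Deviation from plan (%)")
}
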