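#' Distinctiveness: average dissimilarity to the rest of the cohort
#'
#' For each series, the mean of its DTW dissimilarities to every other
#' series — a per-patient measure of how unusual that patient's deviation
#' trajectory is. All values are >= 0 and are 0 only when a series is
#' identical (distance zero) to every other.
#'
#' @param dmat Symmetric dissimilarity matrix (\code{\link{distanceMatrix}}).
#' @return Named numeric vector, one value per series.
#' @export
distinctiveness <- function(dmat) {
  validateDistanceMatrix(dmat)
  n <- nrow(dmat)
  if (n < 2) stop("need at least 2 series", call. = FALSE)
  (rowSums(dmat) - diag(dmat)) / (n - 1)
}

#' Distinctiveness of candidate target-coverage measures
#'
#' Computes per-patient distinctiveness for each candidate dosimetric
#' parameter (univariate DTW on that parameter's series) together with its
#' across-patient variance — the stability criterion used to pick the
#' representative target measure.
#'
#' @param cohort A \linkS4class{DeviationCohort}.
#' @param parameters Candidate labels (default: the three target D95s).
#' @param config A \code{\link{dtwConfig}}.
#' @return List: \code{values} (patients-by-parameters matrix) and
#'   \code{variance} (named vector of across-patient variances).
#' @export
distinctivenessTable <- function(cohort,
                                 parameters = c("GTV_D95", "CTV_D95",
                                                "PTV_D95"),
                                 config = dtwConfig()) {
  vals <- sapply(parameters, function(p) {
    m <- deviationMatrix(cohort, p)
    series <- lapply(seq_len(nrow(m)), function(i) m[i, !is.na(m[i, ])])
    names(series) <- rownames(m)
    distinctiveness(distanceMatrix(series, config))
  })
  list(values = vals, variance = apply(vals, 2, stats::var))
}

#' Select the representative target-coverage measure
#'
#' The candidate with the lowest across-patient variance of distinctiveness
#' is the most stable, generalisable temporal feature and represents the
#' target dose in the two-dimensional clustering. Ties break by fixed
#' precedence (GTV_D95 < CTV_D95 < PTV_D95, then input order) and are
#' reported.
#'
#' @param variance Named numeric vector of distinctiveness variances (e.g.
#'   \code{distinctivenessTable(...)$variance}).
#' @return List: \code{parameter}, \code{variance}, \code{tie} (logical).
#' @examples
#' selectRepresentative(c(GTV_D95 = 5, CTV_D95 = 1, PTV_D95 = 1385.9))
#' @export
selectRepresentative <- function(variance) {
  stopifnot(is.numeric(variance), length(variance) >= 1,
            !is.null(names(variance)))
  precedence <- c("GTV_D95", "CTV_D95", "PTV_D95")
  ord <- order(match(names(variance), precedence,
                     nomatch = length(precedence) + 1))
  v <- variance[ord]
  best <- which(v == min(v))
  list(parameter = names(v)[best[1]], variance = unname(v[best[1]]),
       tie = length(best) > 1)
}

#' K-means on the rows of a dissimilarity matrix
#'
#' Treats each series' row of DTW distances as its feature vector and
#' partitions the cohort with Lloyd's k-means, keeping the best of
#' \code{nRestarts} random initialisations by total within-cluster sum of
#' squares. Deterministic given \code{seed}.
#'
#' @param dmat Symmetric dissimilarity matrix.
#' @param k Number of clusters, 1 <= k <= n.
#' @param seed Integer seed for the restarts.
#' @param nRestarts Random restarts (default 50).
#' @return List: \code{assignments} (named integer vector), \code{sizes},
#'   \code{totWss}, \code{wss} (per cluster).
#' @export
kmeansRows <- function(dmat, k, seed = 1L, nRestarts = 50L) {
  validateDistanceMatrix(dmat)
  n <- nrow(dmat)
  if (k > n) stop("k = ", k, " exceeds the number of series (", n, ")",
                  call. = FALSE)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  rows <- dmat
  if (k == 1) {
    ctr <- colMeans(rows)
    tot <- sum(sweep(rows, 2, ctr)^2)
    return(list(assignments = stats::setNames(rep(1L, n), rownames(rows)),
                sizes = n, totWss = tot, wss = tot))
  }
  ndistinct <- nrow(unique(rows))
  if (ndistinct < k) {
    # degenerate: fewer distinct rows than clusters — group identical rows
    key <- apply(rows, 1, paste, collapse = "\r")
    asg <- as.integer(factor(key, levels = unique(key)))
    names(asg) <- rownames(rows)
    return(list(assignments = asg, sizes = as.vector(table(asg)),
                totWss = 0, wss = rep(0, ndistinct)))
  }
  km <- withSeed(seed,
                 stats::kmeans(rows, centers = k, nstart = nRestarts,
                               iter.max = 100L, algorithm = "Lloyd"))
  list(assignments = stats::setNames(as.integer(km$cluster), rownames(rows)),
       sizes = as.vector(km$size), totWss = km$tot.withinss,
       wss = km$withinss)
}

#' Elbow rule on a within-cluster sum-of-squares scree
#'
#' Picks the elbow as the interior k maximising the (discrete) curvature
#' \code{WSS(k-1) - 2 WSS(k) + WSS(k+1)} of the monotonised scree, the
#' smallest maximiser on ties. A flat scree (no structure at any k) is
#' degenerate: the elbow defaults to k = 1 and is flagged.
#'
#' @param wss Numeric vector of total WSS for k = 1..k_max (k_max >= 3).
#' @return List: \code{k} (elbow), \code{tie}, \code{degenerate},
#'   \code{curvature} (NA at the ends).
#' @examples
#' elbowK(c(100, 20, 18, 17, 16))$k   # 2
#' elbowK(c(100, 60, 20, 19, 18))$k   # 3
#' @export
elbowK <- function(wss) {
  stopifnot(is.numeric(wss))
  K <- length(wss)
  if (K < 3) stop("need WSS for at least 3 values of k", call. = FALSE)
  w <- cummin(wss)  # monotonise restart noise
  scale <- max(w[1], 1)
  if ((w[1] - w[K]) <= 1e-12 * scale) {
    return(list(k = 1L, tie = TRUE, degenerate = TRUE,
                curvature = rep(NA_real_, K)))
  }
  curv <- rep(NA_real_, K)
  for (k in 2:(K - 1)) curv[k] <- w[k - 1] - 2 * w[k] + w[k + 1]
  mx <- max(curv, na.rm = TRUE)
  best <- which(!is.na(curv) & abs(curv - mx) <= 1e-12 * max(abs(mx), 1))
  list(k = as.integer(best[1]), tie = length(best) > 1, degenerate = FALSE,
       curvature = curv)
}

# Partition assignments into retained clusters (size >= minSize) and
# outlier patients (members of excluded clusters).
retainClusters <- function(assignments, minSize) {
  sizes <- table(assignments)
  retained <- as.integer(names(sizes)[sizes >= minSize])
  outliers <- names(assignments)[!(assignments %in% retained)]
  list(retained = retained, outliers = outliers,
       sizes = stats::setNames(as.integer(sizes), names(sizes)))
}

#' ClusterResult: stratification of a cohort by deviation trajectory
#'
#' S4 result of \code{\link{clusterCohort}}: the WSS scree, the elbow and the
#' conservative k+1 cluster count actually used, per-patient assignments,
#' the clusters retained under the minimum-size rule, and the patients
#' excluded as outliers.
#'
#' @slot target,oar The two parameters whose paired series were clustered.
#' @slot scree Total WSS for k = 1..kMax.
#' @slot kElbow,kUsed Elbow k and k+1 actually clustered with (kUsed >= 2).
#' @slot assignments Named integer vector, patient -> cluster id.
#' @slot retained Ids of clusters with >= minSize members.
#' @slot outlierPatients Patients in excluded (small) clusters.
#' @slot minSize,seed,nRestarts Pipeline settings.
#' @slot degenerateElbow,elbowTie Diagnostic flags from \code{\link{elbowK}}.
#' @exportClass ClusterResult
setClass("ClusterResult", representation(
  target = "character", oar = "character", scree = "numeric",
  kElbow = "integer", kUsed = "integer", assignments = "integer",
  retained = "integer", outlierPatients = "character",
  minSize = "integer", seed = "integer", nRestarts = "integer",
  degenerateElbow = "logical", elbowTie = "logical"))

setValidity("ClusterResult", function(object) {
  if (object@kUsed < 2) return("kUsed must be >= 2")
  sizes <- table(object@assignments)
  if (length(object@retained) &&
      any(sizes[as.character(object@retained)] < object@minSize)) {
    return("retained clusters must meet the minimum size")
  }
  n_out <- sum(!(object@assignments %in% object@retained))
  if (n_out != length(object@outlierPatients)) {
    return("outlier patients must be exactly the members of excluded clusters")
  }
  TRUE
})

#' @rdname ClusterResult-class
#' @name ClusterResult-class
#' @param x A \code{ClusterResult}.
#' @export
setGeneric("clusterAssignments",
           function(x) standardGeneric("clusterAssignments"))

#' @rdname ClusterResult-class
#' @export
setMethod("clusterAssignments", "ClusterResult", function(x) x@assignments)

#' @rdname ClusterResult-class
#' @export
setGeneric("retainedClusters", function(x) standardGeneric("retainedClusters"))

#' @rdname ClusterResult-class
#' @export
setMethod("retainedClusters", "ClusterResult", function(x) x@retained)

#' @rdname ClusterResult-class
#' @export
setGeneric("outlierPatients", function(x) standardGeneric("outlierPatients"))

#' @rdname ClusterResult-class
#' @export
setMethod("outlierPatients", "ClusterResult", function(x) x@outlierPatients)

setMethod("show", "ClusterResult", function(object) {
  sizes <- table(object@assignments)
  cat(sprintf("ClusterResult [%s + %s]: k_elbow = %d, k_used = %d\n",
              object@target, object@oar, object@kElbow, object@kUsed))
  cat("  cluster sizes:", paste(sprintf("%s:%d", names(sizes), sizes),
                                collapse = " "), "\n")
  cat(sprintf("  retained (>= %d members): %s | outlier patients: %d\n",
              object@minSize,
              ifelse(length(object@retained),
                     paste(object@retained, collapse = ", "), "none"),
              length(object@outlierPatients)))
  if (object@degenerateElbow) cat("  note: degenerate (flat) scree\n")
})

#' Two-dimensional time-series clustering of a cohort
#'
#' The clustering half of the pipeline for one target/OAR pair: builds the
#' paired percent-deviation series, computes the dependent-DTW distance
#' matrix, runs k-means on its rows over k = 1..kMax to obtain the WSS
#' scree, takes the elbow k, conservatively clusters with k + 1 (never fewer
#' than 2), and excludes clusters smaller than \code{minSize} as outliers.
#'
#' @param cohort A \linkS4class{DeviationCohort}.
#' @param oar OAR dose parameter for the second series dimension.
#' @param target Target-coverage parameter (default CTV_D95, the typical
#'   lowest-distinctiveness-variance representative).
#' @param kMax Largest k on the scree (default 8).
#' @param minSize Minimum retained-cluster size (default 10).
#' @param seed RNG seed governing all restarts (end-to-end deterministic).
#' @param nRestarts K-means restarts per k.
#' @param config A \code{\link{dtwConfig}}.
#' @return A \linkS4class{ClusterResult}. Errors if every cluster falls
#'   below \code{minSize} (no retained clusters).
#' @export
clusterCohort <- function(cohort, oar, target = "CTV_D95", kMax = 8L,
                          minSize = 10L, seed = 1L, nRestarts = 50L,
                          config = dtwConfig()) {
  series <- bivariateSeries(cohort, target = target, oar = oar)
  dmat <- distanceMatrix(series, config)
  n <- nrow(dmat)
  kMax <- min(as.integer(kMax), n)
  scree <- vapply(seq_len(kMax), function(k)
    kmeansRows(dmat, k, seed = seed + k, nRestarts = nRestarts)$totWss,
    numeric(1))
  eb <- elbowK(scree)
  kUsed <- max(2L, eb$k + 1L)
  km <- kmeansRows(dmat, kUsed, seed = seed, nRestarts = nRestarts)
  rc <- retainClusters(km$assignments, minSize)
  if (!length(rc$retained)) {
    stop("no retained clusters: every cluster has fewer than ", minSize,
         " members", call. = FALSE)
  }
  methods::new("ClusterResult", target = target, oar = oar, scree = scree,
               kElbow = as.integer(eb$k), kUsed = as.integer(kUsed),
               assignments = km$assignments, retained = rc$retained,
               outlierPatients = rc$outliers, minSize = as.integer(minSize),
               seed = as.integer(seed), nRestarts = as.integer(nRestarts),
               degenerateElbow = eb$degenerate, elbowTie = eb$tie)
}
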