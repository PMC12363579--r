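#' Dynamic time warping configuration
#'
#' @param stepPattern \code{"symmetric2"} (default: diagonal steps weighted
#'   2, the convention of the standard DTW literature and packages) or
#'   \code{"symmetric1"} (all steps weighted 1).
#' @param window \code{NULL} for unconstrained warping, or a Sakoe-Chiba
#'   radius r >= 0 constraining the path to |i - j| <= r.
#' @param normalize \code{"none"} (default) or \code{"pathLength"}, which for
#'   symmetric2 divides by the weight sum n + m. symmetric1 has no closed
#'   normalisation constant and rejects \code{"pathLength"}.
#' @return A \code{DtwConfig} (list).
#' @details Series are compared in raw percent-deviation units — no
#'   z-normalisation — because amplitude differences are exactly what
#'   separates a high-variability patient from a stable one.
#' @export
dtwConfig <- function(stepPattern = c("symmetric2", "symmetric1"),
                      window = NULL,
                      normalize = c("none", "pathLength")) {
  stepPattern <- match.arg(stepPattern)
  normalize <- match.arg(normalize)
  if (!is.null(window)) {
    stopifnot(is.numeric(window), length(window) == 1, window >= 0)
    window <- as.integer(window)
  }
  if (normalize == "pathLength" && stepPattern == "symmetric1") {
    stop("pathLength normalisation is defined for symmetric2 only",
         call. = FALSE)
  }
  structure(list(stepPattern = stepPattern, window = window,
                 normalize = normalize), class = "DtwConfig")
}

# Local cost matrix: absolute difference for univariate series, Euclidean
# row distance for multivariate (dependent alignment: one shared path).
dtwCostMatrix <- function(x, y) {
  if (is.matrix(x) || is.matrix(y)) {
    if (!is.matrix(x) || !is.matrix(y) || ncol(x) != ncol(y)) {
      stop("multivariate DTW needs two matrices with matching columns",
           call. = FALSE)
    }
    cost <- matrix(0, nrow(x), nrow(y))
    for (d in seq_len(ncol(x))) {
      cost <- cost + outer(x[, d], y[, d], `-`)^2
    }
    sqrt(cost)
  } else {
    abs(outer(as.numeric(x), as.numeric(y), `-`))
  }
}

#' Dynamic time warping distance
#'
#' Minimum cumulative local cost over monotone warping paths between two
#' series, by dynamic programming. Univariate series use absolute local
#' cost; two-column matrices are aligned dependently (a single shared path,
#' Euclidean local cost on the paired rows) — the form used to cluster
#' target-coverage/OAR deviation pairs jointly. Symmetric in its arguments.
#'
#' @param x,y Numeric vectors, or matrices with equal column count (rows =
#'   time points). Must be non-empty.
#' @param config A \code{\link{dtwConfig}}.
#' @return Non-negative distance; 0 for identical series.
#' @examples
#' dtwDistance(c(1, 2), c(1, 2, 2), dtwConfig("symmetric1"))  # 0: warped away
#' dtwDistance(0, 5)                                          # 5
#' @export
dtwDistance <- function(x, y, config = dtwConfig()) {
  stopifnot(inherits(config, "DtwConfig"))
  len <- function(v) if (is.matrix(v)) nrow(v) else length(v)
  n <- len(x); m <- len(y)
  if (n == 0 || m == 0) stop("series must be non-empty", call. = FALSE)
  w <- config$window
  if (!is.null(w) && abs(n - m) > w) {
    stop("Sakoe-Chiba radius ", w, " admits no warping path for lengths ",
         n, " and ", m, call. = FALSE)
  }
  cost <- dtwCostMatrix(x, y)
  d <- .dtwDp(cost, config$stepPattern == "symmetric2",
              if (is.null(w)) -1L else w)
  if (!is.finite(d)) {
    stop("window too tight: no admissible warping path", call. = FALSE)
  }
  if (config$normalize == "pathLength") d <- d / (n + m)
  d
}

#' Pairwise DTW distance matrix for a cohort
#'
#' Computes \code{\link{dtwDistance}} over all unordered pairs (upper
#' triangle, mirrored), yielding the symmetric, zero-diagonal dissimilarity
#' matrix that distinctiveness and clustering consume.
#'
#' @param series Named list (>= 2) of series (vectors or matrices).
#' @param config A \code{\link{dtwConfig}}.
#' @return Symmetric numeric matrix with the series names as dimnames.
#' @export
distanceMatrix <- function(series, config = dtwConfig()) {
  stopifnot(is.list(series))
  n <- length(series)
  if (n < 2) stop("need at least 2 series", call. = FALSE)
  ids <- names(series)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  dm <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dm[i, j] <- dm[j, i] <- dtwDistance(series[[i]], series[[j]], config)
    }
  }
  dm
}

# Sanity checks for a dissimilarity matrix (symmetry, zero diagonal,
# non-negative finite entries). Used by the clustering entry points.
validateDistanceMatrix <- function(dmat) {
  stopifnot(is.matrix(dmat), nrow(dmat) == ncol(dmat))
  if (any(!is.finite(dmat))) stop("distance matrix has non-finite entries",
                                  call. = FALSE)
  if (any(dmat < 0)) stop("distance matrix has negative entries",
                          call. = FALSE)
  if (max(abs(dmat - t(dmat))) > 1e-8) {
    stop("distance matrix is not symmetric", call. = FALSE)
  }
  if (any(abs(diag(dmat)) > 1e-8)) {
    stop("distance matrix diagonal is not zero", call. = FALSE)
  }
  invisible(dmat)
}
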