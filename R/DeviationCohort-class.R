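#' DeviationCohort: per-fraction percentage deviations for a patient cohort
#'
#' S4 container for a cohort's deviation time series, extending
#' \link[SummarizedExperiment]{SummarizedExperiment}: rows are patients,
#' columns are treatment fractions (1-based, 1..F), and each assay is a
#' patients-by-fractions matrix of percentage deviations for one parameter
#' from \code{\link{deviationParameters}}. Missing fractions are \code{NA}
#' (masked, never imputed); downstream trend fits and DTW operate on present
#' points only.
#'
#' @seealso \code{\link{buildCohort}} to construct one from fraction records.
#' @name DeviationCohort-class
#' @aliases DeviationCohort
#' @exportClass DeviationCohort
setClass("DeviationCohort", contains = "SummarizedExperiment")

setValidity("DeviationCohort", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (is.null(an) || !length(an)) return("cohort must hold at least one assay")
  unknown <- setdiff(an, deviationParameters())
  if (length(unknown)) {
    return(paste0("assay name(s) outside the parameter vocabulary: ",
                  paste(unknown, collapse = ", ")))
  }
  for (a in an) {
    m <- SummarizedExperiment::assay(object, a)
    if (!is.numeric(m)) return(paste0("assay '", a, "' is not numeric"))
    if (any(is.infinite(m))) return(paste0("assay '", a, "' has infinite entries"))
  }
  cd <- SummarizedExperiment::colData(object)
  if (!"fraction" %in% names(cd)) return("colData must carry 'fraction'")
  if (!identical(as.integer(cd$fraction), seq_len(ncol(object)))) {
    return("colData fraction index must be 1..F")
  }
  TRUE
})

#' Build a deviation cohort from fraction records
#'
#' Converts tidy (patient, fraction, parameter) records into a
#' \linkS4class{DeviationCohort}: one percentage-deviation series of length
#' \code{nFractions} per (patient, parameter), with absent fractions masked
#' as \code{NA}.
#'
#' @param records Fraction-record table (see \code{\link{readFractionRecords}}).
#' @param nFractions Series length F (default 30, a conventional 60 Gy / 30 fx
#'   course). Records with \code{fraction > nFractions} are an error.
#' @return A \linkS4class{DeviationCohort}.
#' @examples
#' rec <- simulateCohort(defaultCohortConfig(), seed = 1)$records
#' cohort <- buildCohort(rec)
#' cohort
#' @export
buildCohort <- function(records, nFractions = 30L) {
  records <- validateFractionRecords(records)
  nFractions <- as.integer(nFractions)
  if (length(nFractions) != 1L || is.na(nFractions) || nFractions < 1L) {
    stop("nFractions must be a single integer >= 1", call. = FALSE)
  }
  if (nrow(records) && any(records$fraction > nFractions)) {
    stop("records contain fraction indices beyond nFractions = ", nFractions,
         call. = FALSE)
  }
  patients <- sort(unique(records$patient_id))
  params <- intersect(deviationParameters(), unique(records$parameter))
  if (!length(patients) || !length(params)) {
    stop("no valid records to build a cohort from", call. = FALSE)
  }
  dev <- percentDeviation(records$value, records$planned_value)
  ri <- match(records$patient_id, patients)
  ci <- records$fraction
  assays <- lapply(params, function(p) {
    m <- matrix(NA_real_, nrow = length(patients), ncol = nFractions,
                dimnames = list(patients, paste0("fx", seq_len(nFractions))))
    sel <- records$parameter == p
    m[cbind(ri[sel], ci[sel])] <- dev[sel]
    m
  })
  names(assays) <- params

  planned <- S4Vectors::DataFrame(row.names = patients)
  for (p in params) {
    sel <- records$parameter == p
    v <- rep(NA_real_, length(patients))
    # planned baseline is constant within (patient, parameter); keep the first
    first <- sel & !duplicated(paste(records$patient_id, records$parameter,
                                     sep = "\r"))
    v[ri[first]] <- records$planned_value[first]
    planned[[paste0("planned.", p)]] <- v
  }

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = planned,
    colData = S4Vectors::DataFrame(fraction = seq_len(nFractions),
                                   row.names = paste0("fx",
                                                      seq_len(nFractions))))
  methods::new("DeviationCohort", se)
}

#' @rdname DeviationCohort-class
#' @param x A \linkS4class{DeviationCohort}.
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @rdname DeviationCohort-class
#' @export
setMethod("patientIds", "DeviationCohort", function(x) rownames(x))

#' @rdname DeviationCohort-class
#' @export
setGeneric("cohortParameters", function(x) standardGeneric("cohortParameters"))

#' @rdname DeviationCohort-class
#' @export
setMethod("cohortParameters", "DeviationCohort",
          function(x) SummarizedExperiment::assayNames(x))

#' @rdname DeviationCohort-class
#' @export
setGeneric("numFractions", function(x) standardGeneric("numFractions"))

#' @rdname DeviationCohort-class
#' @export
setMethod("numFractions", "DeviationCohort", function(x) ncol(x))

#' Extract deviation series from a cohort
#'
#' \code{deviationMatrix} returns the patients-by-fractions percentage
#' deviation matrix for one parameter; \code{deviationPoints} returns the
#' long form (one row per present point) consumed by the trend fits.
#'
#' @param x A \linkS4class{DeviationCohort}.
#' @param parameter A label from \code{cohortParameters(x)}.
#' @return \code{deviationMatrix}: numeric matrix (NA = masked fraction);
#'   \code{deviationPoints}: data.frame with \code{patient_id},
#'   \code{fraction}, \code{deviation}.
#' @export
deviationMatrix <- function(x, parameter) {
  stopifnot(methods::is(x, "DeviationCohort"))
  if (!parameter %in% cohortParameters(x)) {
    stop("parameter '", parameter, "' is not present in this cohort",
         call. = FALSE)
  }
  SummarizedExperiment::assay(x, parameter)
}

#' @rdname deviationMatrix
#' @export
deviationPoints <- function(x, parameter) {
  m <- deviationMatrix(x, parameter)
  idx <- which(!is.na(m), arr.ind = TRUE)
  data.frame(patient_id = rownames(m)[idx[, 1]],
             fraction = as.integer(idx[, 2]),
             deviation = m[idx],
             stringsAsFactors = FALSE)
}

#' Paired target/OAR deviation series
#'
#' Builds the two-dimensional series clustered jointly downstream: for each
#' patient, an F-by-2 matrix whose first column is the target-coverage
#' deviation (\code{target}, typically \code{CTV_D95}) and second column one
#' OAR dose deviation. Both columns share one fraction axis; fractions missing
#' in either are dropped from that patient's matrix.
#'
#' @param x A \linkS4class{DeviationCohort}.
#' @param target Target dosimetric parameter (first column).
#' @param oar OAR dose parameter (second column).
#' @return Named list (per patient) of matrices with columns
#'   \code{c(target, oar)}.
#' @export
bivariateSeries <- function(x, target = "CTV_D95", oar) {
  mt <- deviationMatrix(x, target)
  mo <- deviationMatrix(x, oar)
  out <- lapply(patientIds(x), function(p) {
    keep <- !is.na(mt[p, ]) & !is.na(mo[p, ])
    m <- cbind(mt[p, keep], mo[p, keep])
    colnames(m) <- c(target, oar)
    m
  })
  names(out) <- patientIds(x)
  out
}

setMethod("show", "DeviationCohort", function(object) {
  cat("DeviationCohort:", nrow(object), "patients x", ncol(object),
      "fractions\n")
  cat("  parameters:", paste(cohortParameters(object), collapse = ", "), "\n")
  miss <- sum(vapply(cohortParameters(object),
                     function(p) sum(is.na(deviationMatrix(object, p))),
                     numeric(1)))
  cat("  masked points:", miss, "\n")
})
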