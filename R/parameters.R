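#' Parameter vocabulary for per-fraction monitoring
#'
#' The closed set of structures and dose metrics tracked per treatment
#' fraction: volumes (cm3) of the three targets (GTV, CTV, PTV) and four
#' organs at risk, plus the target D95 coverage doses and OAR mean/max
#' doses (Gy). Labels are case-sensitive; every record must use one of them.
#'
#' @return Character vector of parameter labels.
#' @examples
#' volumeParameters()
#' dosimetricParameters()
#' @export
volumeParameters <- function() {
  c("GTV", "CTV", "PTV", "Lung", "Esophagus", "Heart", "SpinalCord")
}

#' @rdname volumeParameters
#' @export
dosimetricParameters <- function() {
  c("GTV_D95", "CTV_D95", "PTV_D95",
    "Lung_Dmean", "Esophagus_Dmean", "Heart_Dmean", "SpinalCord_Dmax")
}

#' @rdname volumeParameters
#' @export
deviationParameters <- function() {
  c(volumeParameters(), dosimetricParameters())
}

#' Percentage deviation from the planned baseline
#'
#' Expresses a recalculated per-fraction value as the percentage change from
#' its planning-CT baseline: \code{100 * (value - planned) / planned}.
#' Vectorised; the two arguments are recycled to a common length.
#'
#' @param value Measured quantity (cm3 for volumes, Gy for doses).
#' @param planned_value Planned baseline in the same units; must be non-zero.
#' @return Numeric vector of deviations in percent units (-9.79 means -9.79%).
#' @examples
#' percentDeviation(90, 100)    # -10
#' percentDeviation(60.6, 60)   # +1
#' @export
percentDeviation <- function(value, planned_value) {
  if (!is.numeric(value) || !is.numeric(planned_value)) {
    stop("'value' and 'planned_value' must be numeric", call. = FALSE)
  }
  if (any(planned_value == 0, na.rm = TRUE)) {
    stop("planned_value = 0: relative change from a zero baseline is undefined",
         call. = FALSE)
  }
  100 * (value - planned_value) / planned_value
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. `seed = NULL` leaves the RNG alone.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}
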