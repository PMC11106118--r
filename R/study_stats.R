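#' Relative standard deviation from printed moments
#'
#' RSD = 100 x SD / mean, the dispersion statistic used to report
#' replicate particle counts of spiking suspensions. Printed tables give
#' integer percentages; set \code{rounded = TRUE} to reproduce them.
#'
#' @param mean mean value(s), > 0.
#' @param sd standard deviation(s), >= 0.
#' @param rounded round to the nearest integer percent.
#' @return RSD in percent.
#' @examples
#' rsdFromMoments(478, 295, rounded = TRUE)  # 62
#' @export
rsdFromMoments <- function(mean, sd, rounded = FALSE) {
  if (any(!is.finite(mean)) || any(mean <= 0)) {
    stop("mean must be > 0", call. = FALSE)
  }
  if (any(!is.finite(sd)) || any(sd < 0)) {
    stop("sd must be >= 0", call. = FALSE)
  }
  out <- 100 * sd / mean
  if (rounded) round(out) else out
}

#' Relative standard deviation of replicate values
#'
#' Sample SD (n - 1 denominator) over the mean, in percent.
#'
#' @param values numeric vector of at least two replicate values with
#'   positive mean.
#' @param rounded round to the nearest integer percent.
#' @return RSD in percent.
#' @export
rsd <- function(values, rounded = FALSE) {
  if (length(values) < 2L) {
    stop("at least two values are required", call. = FALSE)
  }
  m <- mean(values)
  if (!is.finite(m) || m <= 0) stop("mean must be > 0", call. = FALSE)
  rsdFromMoments(m, stats::sd(values), rounded = rounded)
}

#' Expected particle spike per aliquot
#'
#' Scales a suspension's particle concentration (mean and SD, particles
#' per mL) to the pipetted aliquot volume. The standard 100 uL aliquot of
#' a suspension at 478 +/- 295 MP/mL is expected to deliver
#' 47.8 +/- 29.5 MP.
#'
#' @param count_per_ml_mean,count_per_ml_sd suspension concentration
#'   moments in particles/mL (vectors allowed).
#' @param aliquot_ml pipetted volume in mL (default 0.1).
#' @return data.frame with columns \code{mean} and \code{sd} (particles
#'   per aliquot).
#' @export
expectedSpikeCount <- function(count_per_ml_mean, count_per_ml_sd = 0,
                               aliquot_ml = 0.1) {
  if (any(count_per_ml_mean < 0) || any(count_per_ml_sd < 0) ||
      aliquot_ml <= 0) {
    stop("concentrations must be >= 0 and aliquot_ml > 0", call. = FALSE)
  }
  data.frame(mean = count_per_ml_mean * aliquot_ml,
             sd = count_per_ml_sd * aliquot_ml)
}

#' Recovery in percent
#'
#' 100 x measured / expected, the bookkeeping used for mass-estimate
#' recoveries of spiking suspensions.
#'
#' @param measured measured value(s), >= 0.
#' @param expected expected (reference) value(s), > 0.
#' @param rounded round to the nearest integer percent.
#' @return recovery in percent.
#' @export
recoveryPercent <- function(measured, expected, rounded = FALSE) {
  if (any(!is.finite(expected)) || any(expected <= 0)) {
    stop("expected must be > 0", call. = FALSE)
  }
  out <- 100 * measured / expected
  if (rounded) round(out) else out
}

#' MP share of a particle count
#'
#' Percentage of a total particle count identified as microplastic; used
#' to compare particle totals of the fluorescence screen against a
#' chemical-identification reference run.
#'
#' @param total_particles total particle count (> 0).
#' @param mp_particles MP count (0 <= mp <= total).
#' @return MP percentage.
#' @examples
#' mpFraction(10820, 72)   # 0.665...
#' @export
mpFraction <- function(total_particles, mp_particles) {
  if (any(total_particles <= 0)) stop("total must be > 0", call. = FALSE)
  if (any(mp_particles < 0) || any(mp_particles > total_particles)) {
    stop("mp count must lie in [0, total]", call. = FALSE)
  }
  100 * mp_particles / total_particles
}

#' Filter membrane area
#'
#' Area of a circular filter membrane from its diameter, reported to
#' 0.1 cm^2 (a 47 mm membrane has 17.3 cm^2, a 25 mm membrane 4.9 cm^2).
#'
#' @param diameter_mm membrane diameter in millimetres (> 0).
#' @return area in cm^2, rounded to one decimal.
#' @export
filterAreaCm2 <- function(diameter_mm) {
  if (any(!is.finite(diameter_mm)) || any(diameter_mm <= 0)) {
    stop("diameter must be > 0", call. = FALSE)
  }
  round(pi * (diameter_mm / 20)^2, 1)
}

#' Classification error report
#'
#' Confusion statistics of an MP/PNO classification against ground truth:
#' overall accuracy, alpha error (share of true natural particles falsely
#' flagged MP-suspect), beta error (share of true MP missed), and the
#' per-polymer beta error on each polymer's subset.
#'
#' @param truth character vector of \code{"MP"} / \code{"PNO"} true
#'   labels.
#' @param predicted_mp logical vector of MP-suspect flags.
#' @param polymer optional character vector of polymer (or class) labels,
#'   used for the per-class beta errors of true-MP particles.
#' @return list with \code{accuracy_pct}, \code{alpha_error_pct},
#'   \code{beta_error_pct}, \code{per_class_beta} (named numeric, may be
#'   empty) and \code{n}.
#' @export
classificationErrorReport <- function(truth, predicted_mp, polymer = NULL) {
  if (length(truth) == 0L) stop("empty labelled set", call. = FALSE)
  stopifnot(length(truth) == length(predicted_mp),
            all(truth %in% c("MP", "PNO")))
  is_mp <- truth == "MP"
  acc <- 100 * mean(is_mp == predicted_mp)
  alpha <- if (any(!is_mp)) 100 * mean(predicted_mp[!is_mp]) else 0
  beta <- if (any(is_mp)) 100 * mean(!predicted_mp[is_mp]) else 0
  per_class <- numeric(0)
  if (!is.null(polymer) && any(is_mp)) {
    per_class <- vapply(split(!predicted_mp[is_mp], polymer[is_mp]),
                        function(x) 100 * mean(x), numeric(1))
  }
  list(accuracy_pct = acc, alpha_error_pct = alpha, beta_error_pct = beta,
       per_class_beta = per_class, n = length(truth))
}

#' Packaged spiking-suspension reference table
#'
#' The composition of the seven polymer spiking suspensions used for
#' method validation: replicate particle concentrations (mean and SD,
#' particles/mL), the printed integer RSD and mass-recovery values for
#' cross-checking, mass estimates, and nominal polymer densities.
#'
#' @return data.frame with one row per suspension.
#' @export
suspensionTable <- function() {
  path <- system.file("extdata", "suspensions_table.csv",
                      package = "mpscreen", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
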