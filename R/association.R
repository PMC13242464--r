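#' Align a dense quenching series to the sparse pigment sampling times
#'
#' The destructively sampled pigment series is the anchor: the dense
#' quenching record is linearly interpolated onto the pigment sampling
#' times that lie within the quenching record's span, and only time points
#' with valid data for both series are retained.
#'
#' @param quenchingTimes,quenchingValues the dense quenching record.
#' @param pigmentTimes,pigmentValues the sparse pigment record; `NA`
#'   pigment values are dropped.
#' @return A data.frame `time_s, quenching, pigment` with >= 3 rows.
#' @export
alignSeries <- function(quenchingTimes, quenchingValues, pigmentTimes,
                        pigmentValues) {
  stopifnot(length(quenchingTimes) == length(quenchingValues),
            length(pigmentTimes) == length(pigmentValues))
  keep <- pigmentTimes >= min(quenchingTimes) &
    pigmentTimes <= max(quenchingTimes) & !is.na(pigmentValues)
  if (sum(keep) < 3L)
    stop("fewer than 3 common valid time points after alignment")
  q <- stats::approx(quenchingTimes, quenchingValues,
                     xout = pigmentTimes[keep])$y
  data.frame(time_s = pigmentTimes[keep], quenching = q,
             pigment = pigmentValues[keep])
}

#' Pearson correlation with its p-value
#'
#' Sample Pearson correlation of two paired vectors with the two-sided
#' p-value from the t-distribution with n - 2 degrees of freedom.
#'
#' @param x,y paired numeric vectors (n >= 3, both with nonzero variance).
#' @param label optional label carried into the result.
#' @return A data.frame `label, r, p_value, n_points`.
#' @export
pearsonAssociation <- function(x, y, label = NA_character_) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 paired points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in one of the inputs; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  data.frame(label = label, r = unname(ct$estimate), p_value = ct$p.value,
             n_points = length(x))
}

#' Composite pigment pool
#'
#' Per-time sum of a named set of pigments, e.g. the carotenoids that
#' significantly increased by the end of the transient (selection typically
#' supplied from [deNovoMatrix()] verdicts at t = 180 s, or by the user).
#'
#' @param pigments a [PigmentTimeSeries-class].
#' @param members non-empty character vector of pigment names to sum.
#' @return Numeric vector of the summed pool per time point
#'   (mol (mol Chl a)^-1).
#' @export
compositePigment <- function(pigments, members) {
  stopifnot(is(pigments, "PigmentTimeSeries"))
  if (length(members) == 0L) stop("empty pigment selection")
  conc <- concentrations(pigments)
  miss <- setdiff(members, rownames(conc))
  if (length(miss))
    stop("pigment(s) not present: ", paste(miss, collapse = ", "))
  colSums(conc[members, , drop = FALSE])
}

#' Correlate fluorescence quenching with a pigment trajectory
#'
#' End-to-end helper: computes the replicate-mean pigment (or composite
#' pool) trajectory, aligns the quenching record onto the pigment sampling
#' times and returns the Pearson association.
#'
#' @param quenchingTimes,quenchingValues the dense quenching record.
#' @param serieslist list of [PigmentTimeSeries-class] replicates.
#' @param members pigment name(s); several names are summed per replicate
#'   before averaging.
#' @return A data.frame as from [pearsonAssociation()].
#' @export
correlateQuenchingPigment <- function(quenchingTimes, quenchingValues,
                                      serieslist, members) {
  times <- timePoints(serieslist[[1L]])
  traj <- rowMeans(vapply(serieslist, function(p)
    compositePigment(p, members), numeric(length(times))), na.rm = TRUE)
  al <- alignSeries(quenchingTimes, quenchingValues, times, traj)
  pearsonAssociation(al$quenching, al$pigment,
                     label = paste(members, collapse = "+"))
}
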