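#' Dynamic pool percentage of a carotenoid transient
#'
#' The fraction of a pigment's Chl a-normalized pool that changes during the
#' light transient:
#' \deqn{Dynamic\ pool\ [\%] = \frac{max - min}{max} \times 100}
#' with max and min taken over the non-missing sampled time points of one
#' replicate. A pigment absent in darkness and formed entirely under light
#' (min = 0) therefore scores exactly 100.
#'
#' @param values pigment concentrations over the transient
#'   (mol (mol Chl a)^-1); `NA` marks missing samples, which are skipped.
#' @return Scalar percentage in `[0, 100]`, or `NA` if fewer than 2
#'   non-missing samples remain or the maximum is 0.
#' @export
dynamicPoolPercent <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L) return(NA_real_)
  mx <- max(v)
  if (mx <= 0) return(NA_real_)
  (mx - min(v)) / mx * 100
}

#' Dynamic pool summary across replicates (Table-1-style)
#'
#' Computes [dynamicPoolPercent()] per replicate and per pigment, then
#' summarizes each species x light-condition group as mean +/- standard
#' error across replicates.
#'
#' @param serieslist list of [PigmentTimeSeries-class] replicates.
#' @return A data.frame with columns `species, light_condition, pigment,
#'   mean_percent, se_percent, n`.
#' @export
dynamicPoolSummary <- function(serieslist) {
  if (is(serieslist, "PigmentTimeSeries")) serieslist <- list(serieslist)
  per <- do.call(rbind, lapply(serieslist, function(p) {
    conc <- concentrations(p)
    data.frame(species = p@species, light_condition = p@lightCondition,
               replicate = p@replicate, pigment = rownames(conc),
               percent = apply(conc, 1L, dynamicPoolPercent))
  }))
  agg <- split(per, interaction(per$species, per$light_condition,
                                per$pigment, drop = TRUE))
  out <- do.call(rbind, lapply(agg, function(d) {
    v <- d$percent[!is.na(d$percent)]
    data.frame(species = d$species[1L],
               light_condition = d$light_condition[1L],
               pigment = d$pigment[1L],
               mean_percent = if (length(v)) mean(v) else NA_real_,
               se_percent = if (length(v) > 1L)
                 stats::sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v))
  }))
  rownames(out) <- NULL
  out
}

#' Normalized carotenoid trend relative to the dark state
#'
#' Variation of the pigment pool at each sampling time relative to its
#' dark-adapted (t0) value, normalized over the maximum variable pool:
#' \deqn{Normalized\ Car(t_i) = \frac{[Car/Chla]_{t_i} - [Car/Chla]_{t_0}}
#'   {[Car/Chla]^{max} - [Car/Chla]^{min}}}
#'
#' @param values pigment concentrations over the transient; the first entry
#'   is the dark state. `NA` entries propagate as `NA`; min/max are taken
#'   over non-missing samples.
#' @return Numeric vector of the same length (0 at t0), or all-`NA` when the
#'   series is constant (max = min).
#' @export
normalizedTrend <- function(values) {
  v <- values[!is.na(values)]
  if (length(v) < 2L || max(v) == min(v))
    return(rep(NA_real_, length(values)))
  (values - values[1L]) / (max(v) - min(v))
}

.BRANCHES <- list(
  alpha_branch = c("alphaCar", "Lut", "Lx"),
  beta_branch = c("betaCar", "Vio", "Ant", "Zea", "Neo"),
  vaz_cycle = c("Vio", "Ant", "Zea"),
  lxl_cycle = c("Lx", "Lut")
)

#' Carotenoid branch and cycle pool sums
#'
#' Per time point sums of the alpha-branch (alpha-Car + Lut + Lx),
#' beta-branch (beta-Car + Vio + Ant + Zea + Neo), VAZ cycle (Vio + Ant +
#' Zea) and LxL cycle (Lx + Lut) pools. A missing addend at a time point
#' makes that sum missing at that point (never silently dropped).
#'
#' @param pigments a [PigmentTimeSeries-class] containing all required
#'   pigments.
#' @return A data.frame `time_s, alpha_branch, beta_branch, vaz_cycle,
#'   lxl_cycle` in mol (mol Chl a)^-1.
#' @export
branchSums <- function(pigments) {
  stopifnot(is(pigments, "PigmentTimeSeries"))
  conc <- concentrations(pigments)
  need <- unique(unlist(.BRANCHES))
  miss <- setdiff(need, rownames(conc))
  if (length(miss))
    stop("missing required pigment(s): ", paste(miss, collapse = ", "))
  sums <- lapply(.BRANCHES, function(members) {
    colSums(conc[members, , drop = FALSE])  # NA if any addend missing
  })
  data.frame(time_s = pigments@times, sums)
}

.stars <- function(p) {
  if (is.na(p)) "" else if (p < 0.001) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else ""
}

#' De novo synthesis test of a pool against the dark state
#'
#' For each sampled time t > 0, a two-sample two-sided Student's t-test
#' (classic equal-variance form) of the pool across replicates against the
#' dark-state (t = 0) pool. Verdicts are `increase`/`decrease` at p < 0.05
#' (star-coded `*` p < 0.05, `**` p < 0.01, `***` p < 0.001) or `ns`.
#' Shapiro-Wilk normality (per group) and Levene homoscedasticity p-values
#' are reported as flags alongside; they do not gate the t-test. No
#' multiple-testing correction is applied across time points (per-time
#' stars).
#'
#' @param values matrix `[n_replicates x n_times]` of the pool.
#' @param times sampling times (s); must start at 0.
#' @return A data.frame, one row per time > 0: `time_s, mean_diff, t, df,
#'   p_value, verdict, stars, shapiro_p_dark, shapiro_p_light, levene_p`.
#'   Verdict is `NA` where fewer than 2 replicates are available.
#' @export
deNovoTest <- function(values, times) {
  values <- as.matrix(values)
  stopifnot(ncol(values) == length(times))
  if (times[1L] != 0) stop("first time point must be the dark state (t = 0)")
  dark <- values[, 1L]
  dark <- dark[!is.na(dark)]
  shapiroP <- function(x) {
    if (length(x) < 3L) return(NA_real_)
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) NA_real_)
  }
  out <- lapply(seq_along(times)[-1L], function(j) {
    light <- values[, j]
    light <- light[!is.na(light)]
    row <- data.frame(time_s = times[j], mean_diff = NA_real_, t = NA_real_,
                      df = NA_real_, p_value = NA_real_,
                      verdict = NA_character_, stars = "",
                      shapiro_p_dark = shapiroP(dark),
                      shapiro_p_light = shapiroP(light),
                      levene_p = NA_real_)
    if (length(dark) < 2L || length(light) < 2L) return(row)
    tt <- tryCatch(stats::t.test(light, dark, var.equal = TRUE),
                   error = function(e) NULL)
    if (is.null(tt)) return(row)
    lev <- tryCatch({
      g <- factor(rep(c("dark", "light"), c(length(dark), length(light))))
      car::leveneTest(c(dark, light), g)[["Pr(>F)"]][1L]
    }, error = function(e) NA_real_)
    row$mean_diff <- mean(light) - mean(dark)
    row$t <- unname(tt$statistic)
    row$df <- unname(tt$parameter)
    row$p_value <- tt$p.value
    row$levene_p <- lev
    row$verdict <- if (tt$p.value >= 0.05 || is.na(tt$p.value)) "ns"
                   else if (row$mean_diff > 0) "increase" else "decrease"
    row$stars <- .stars(tt$p.value)
    row
  })
  do.call(rbind, out)
}

#' De novo significance matrix across pigments or pools
#'
#' Runs [deNovoTest()] for every pigment (and the four branch/cycle sums)
#' across a replicate set, producing the significance matrix used to read
#' off which pools rose or fell relative to darkness.
#'
#' @param serieslist list of [PigmentTimeSeries-class] replicates sharing a
#'   time grid.
#' @param pools which series to test: `"pigments"`, `"branches"` or
#'   `"both"`.
#' @return A long data.frame with a `pool` column plus the [deNovoTest()]
#'   columns.
#' @export
deNovoMatrix <- function(serieslist, pools = c("both", "pigments",
                                               "branches")) {
  pools <- match.arg(pools)
  times <- timePoints(serieslist[[1L]])
  grab <- function(f) t(vapply(serieslist, f, numeric(length(times))))
  out <- list()
  if (pools != "branches") {
    for (pg in pigmentNames(serieslist[[1L]])) {
      vals <- grab(function(p) concentrations(p)[pg, ])
      out[[pg]] <- cbind(pool = pg, deNovoTest(vals, times))
    }
  }
  if (pools != "pigments") {
    bs <- lapply(serieslist, branchSums)
    for (b in names(.BRANCHES)) {
      vals <- t(vapply(bs, function(d) d[[b]], numeric(length(times))))
      out[[b]] <- cbind(pool = b, deNovoTest(vals, times))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mirror-trend diagnostic for two pigment pools
#'
#' Compares the early-transient trends of two pools on a shared difference
#' range: both series are smoothed with the 2-period moving mean, rebased to
#' their dark-state value (delta from t0), and the Pearson correlation of
#' the two delta-trends is reported. A strongly negative r indicates mirror
#' (balancing) behaviour.
#'
#' @param times common sampling times (s).
#' @param a,b the two pool series on `times` (mol (mol Chl a)^-1).
#' @param tMax analysis horizon in s (default 100).
#' @param window moving-mean window (default 2).
#' @return A list: `times`, `trend_a`, `trend_b` (rebased trends), `r`
#'   (Pearson correlation of the delta-trends), `difference_range` (shared
#'   plotting range width).
#' @export
mirrorTrend <- function(times, a, b, tMax = 100, window = 2) {
  stopifnot(length(times) == length(a), length(times) == length(b))
  keep <- times <= tMax & !is.na(a) & !is.na(b)
  if (sum(keep) < 3L) stop("fewer than 3 common points within [0, tMax]")
  tt <- times[keep]
  da <- movingMean(a[keep], window); da <- da - da[1L]
  db <- movingMean(b[keep], window); db <- db - db[1L]
  list(times = tt, trend_a = da, trend_b = db,
       r = stats::cor(da, db),
       difference_range = max(diff(range(da)), diff(range(db))))
}
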