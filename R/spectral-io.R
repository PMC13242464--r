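#' Read a wide-format spectral CSV into a SpectralTimeSeries
#'
#' The file dialect is plain UTF-8 CSV with '.' decimal separator: first
#' column `wavelength_nm`, remaining column headers numeric acquisition
#' times in seconds. Rows are sorted by wavelength and columns by time on
#' read, so a shuffled file yields the same object as a sorted one.
#'
#' @param path path to the CSV file.
#' @param quantity one of [spectralQuantities].
#' @return A [SpectralTimeSeries-class].
#' @seealso [writeSpectralCsv()]
#' @export
readSpectralCsv <- function(path, quantity) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2L)
    stop("spectral CSV needs a wavelength column plus >= 1 time column: ",
         path)
  tt <- suppressWarnings(as.numeric(names(df)[-1L]))
  if (any(is.na(tt)))
    stop("non-numeric time header(s) in ", path, ": ",
         paste(names(df)[-1L][is.na(tt)], collapse = ", "))
  wl <- df[[1L]]
  if (anyDuplicated(wl))
    stop("duplicated wavelength row(s) in ", path)
  ord_w <- order(wl)
  ord_t <- order(tt)
  vals <- as.matrix(df[ord_w, -1L, drop = FALSE])[, ord_t, drop = FALSE]
  SpectralTimeSeries(wl[ord_w], tt[ord_t], vals, quantity)
}

#' Write a SpectralTimeSeries to wide CSV
#'
#' @param x a [SpectralTimeSeries-class].
#' @param path output path.
#' @return `path`, invisibly. Values are written with 15 significant digits
#'   so a write/read round trip preserves them to at least 12.
#' @export
writeSpectralCsv <- function(x, path) {
  stopifnot(is(x, "SpectralTimeSeries"))
  df <- data.frame(wavelength_nm = format(x@wavelengths, digits = 15,
                                          trim = TRUE),
                   format(x@values, digits = 15, trim = TRUE),
                   check.names = FALSE)
  names(df)[-1L] <- format(x@times, digits = 15, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a SpectralTimeSeries to a closed wavelength window
#'
#' The window is a closed interval: both endpoints are retained when they
#' sit on the grid, matching the closed integral bounds used for the
#' photon-flux integral.
#'
#' @param x a [SpectralTimeSeries-class].
#' @param lambdaMin,lambdaMax window bounds in nm, `lambdaMin <= lambdaMax`.
#' @return The restricted [SpectralTimeSeries-class].
#' @export
restrictWavelength <- function(x, lambdaMin, lambdaMax) {
  stopifnot(is(x, "SpectralTimeSeries"))
  if (lambdaMin > lambdaMax)
    stop(sprintf("inverted wavelength window [%g, %g]", lambdaMin, lambdaMax))
  keep <- x@wavelengths >= lambdaMin & x@wavelengths <= lambdaMax
  if (!any(keep))
    stop(sprintf("no grid wavelengths inside [%g, %g]", lambdaMin, lambdaMax))
  SpectralTimeSeries(x@wavelengths[keep], x@times,
                     x@values[keep, , drop = FALSE], x@quantity)
}

#' Read a long-format pigment table
#'
#' Expects columns `species, light_condition, replicate, time_s, pigment,
#' value, units` and returns one [PigmentTimeSeries-class] per
#' (species, condition, replicate). The literal value `"nd"` (not detected /
#' not determined) becomes a missing `NA` entry, never zero. Rows with units
#' `mass_per_area` are converted to mol (mol Chl a)^-1 using
#' [pigmentMolarMasses]; mass tables must then include `Chla` rows at each
#' sampled time.
#'
#' @param path path to the CSV file.
#' @return A list of [PigmentTimeSeries-class] objects.
#' @export
readPigmentTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("species", "light_condition", "replicate", "time_s", "pigment",
            "value", "units")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("pigment table missing column(s): ", paste(miss, collapse = ", "))
  df$value_num <- suppressWarnings(as.numeric(df$value))
  nd <- trimws(df$value) == "nd"
  if (any(is.na(df$value_num) & !nd))
    stop("non-numeric pigment value(s) other than 'nd' in ", path)
  df$value_num[nd] <- NA_real_
  if (any(df$value_num < 0, na.rm = TRUE))
    stop("negative pigment concentration(s) in ", path)
  badu <- setdiff(unique(df$units), c("mol_per_mol_chla", "mass_per_area"))
  if (length(badu))
    stop("unknown units: ", paste(badu, collapse = ", "))
  badp <- setdiff(unique(df$pigment), c(pigmentNamesAccepted, "Chla"))
  if (length(badp))
    stop("unknown pigment name(s): ", paste(badp, collapse = ", "),
         "; accepted: ", paste(pigmentNamesAccepted, collapse = ", "))
  df$time_num <- as.numeric(df$time_s)
  key <- interaction(df$species, df$light_condition, df$replicate,
                     drop = TRUE)
  lapply(split(df, key), function(d) {
    tt <- sort(unique(d$time_num))
    pig <- setdiff(unique(d$pigment), "Chla")
    conc <- matrix(NA_real_, length(pig), length(tt),
                   dimnames = list(pig, NULL))
    mass <- d$units == "mass_per_area"
    if (any(mass)) {
      chla <- d[d$pigment == "Chla" & mass, ]
      if (!nrow(chla))
        stop("mass_per_area units require Chla rows for group ",
             d$species[1L], "/", d$light_condition[1L])
      chla_mol <- stats::setNames(
        chla$value_num / pigmentMolarMasses[["Chla"]], chla$time_num)
    }
    for (i in seq_len(nrow(d))) {
      if (d$pigment[i] == "Chla") next
      val <- d$value_num[i]
      if (d$units[i] == "mass_per_area" && !is.na(val)) {
        denom <- chla_mol[as.character(d$time_num[i])]
        if (is.na(denom))
          stop("no Chla mass at time ", d$time_num[i], " for conversion")
        val <- (val / pigmentMolarMasses[[d$pigment[i]]]) / denom
      }
      conc[d$pigment[i], match(d$time_num[i], tt)] <- val
    }
    PigmentTimeSeries(d$species[1L], d$light_condition[1L],
                      as.integer(d$replicate[1L]), tt, conc)
  })
}

#' Write a list of PigmentTimeSeries to a long-format CSV
#'
#' Inverse of [readPigmentTable()]; missing entries are written as `"nd"`.
#'
#' @param serieslist a list of [PigmentTimeSeries-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePigmentTable <- function(serieslist, path) {
  if (is(serieslist, "PigmentTimeSeries")) serieslist <- list(serieslist)
  rows <- lapply(serieslist, function(p) {
    conc <- p@concentrations
    data.frame(
      species = p@species,
      light_condition = p@lightCondition,
      replicate = p@replicate,
      time_s = rep(p@times, each = nrow(conc)),
      pigment = rep(rownames(conc), ncol(conc)),
      value = ifelse(is.na(c(conc)), "nd",
                     format(c(conc), digits = 15, trim = TRUE)),
      units = "mol_per_mol_chla"
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
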