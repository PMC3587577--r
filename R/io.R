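.read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s) in ", basename(path), ": ",
         paste(missing, collapse = ", "))
  bad <- integer(0)
  for (cl in required) {
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- union(bad, which(is.na(v) & !is.na(df[[cl]]) | is.na(df[[cl]])))
    df[[cl]] <- v
  }
  if (length(bad))
    stop("malformed rows in ", basename(path), " (data line ",
         paste(sort(bad), collapse = ", "), ")")
  df
}

.conc_factor <- function(units = c("uM", "M")) {
  switch(match.arg(units), uM = 1e-6, M = 1)
}

#' Read an ensemble titration CSV
#'
#' Expects columns `quencher_conc_uM` (or `_M` with `units = "M"`),
#' `probe_conc_uM`, `absorbance`, `fluorescence`; one row per measurement.
#' Rows sharing a quencher concentration become one [fluor_abs_series].
#'
#' @param path CSV path (comma separator, decimal point, header required).
#' @param units Concentration unit in the file: `"uM"` (default) or `"M"`.
#' @return List of [fluor_abs_series] sorted by quencher concentration.
#' @export
read_titration_csv <- function(path, units = c("uM", "M")) {
  units <- match.arg(units)
  cols <- paste0(c("quencher_conc_", "probe_conc_"), units)
  df <- .read_csv_checked(path, c(cols, "absorbance", "fluorescence"))
  fac <- .conc_factor(units)
  qc <- df[[cols[1]]] * fac
  out <- lapply(sort(unique(qc)), function(cq) {
    i <- qc == cq
    fluor_abs_series(cq, df$absorbance[i], df$fluorescence[i])
  })
  out
}

#' Write an ensemble titration CSV
#'
#' Inverse of [read_titration_csv].
#'
#' @param series_list List of [fluor_abs_series].
#' @param path Output CSV path.
#' @param probe_concs Optional probe concentrations (mol/L) per point within
#'   each series; defaults to absorbance-proportional placeholders.
#' @param units `"uM"` or `"M"`.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(series_list, path, probe_concs = NULL,
                                units = c("uM", "M")) {
  units <- match.arg(units)
  fac <- .conc_factor(units)
  rows <- do.call(rbind, lapply(series_list, function(s) {
    pc <- if (is.null(probe_concs)) s$absorbance / 2.5e4 else probe_concs
    data.frame(q = s$quencher_conc / fac, p = pc / fac,
               absorbance = s$absorbance, fluorescence = s$fluorescence)
  }))
  names(rows)[1:2] <- paste0(c("quencher_conc_", "probe_conc_"), units)
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Read an absorbance titration CSV
#'
#' Expects columns `metal_conc_uM` (or `_M`) and `absorbance`.  Probe
#' concentration, path length and baseline come from the arguments since
#' they are per-experiment constants.
#'
#' @param path CSV path.
#' @param L0,d,A0,lambda_eval See [absorbance_titration].
#' @param units `"uM"` or `"M"`.
#' @return An [absorbance_titration].
#' @export
read_absorbance_csv <- function(path, L0, d, A0, lambda_eval = NA_real_,
                                units = c("uM", "M")) {
  units <- match.arg(units)
  col <- paste0("metal_conc_", units)
  df <- .read_csv_checked(path, c(col, "absorbance"))
  fac <- .conc_factor(units)
  o <- order(df[[col]])
  absorbance_titration(df[[col]][o] * fac, df$absorbance[o],
                       L0 = L0, d = d, A0 = A0, lambda_eval = lambda_eval)
}

#' Write an absorbance titration CSV
#'
#' @param titr An [absorbance_titration].
#' @param path Output CSV path.
#' @param units `"uM"` or `"M"`.
#' @return `path`, invisibly.
#' @export
write_absorbance_csv <- function(titr, path, units = c("uM", "M")) {
  units <- match.arg(units)
  fac <- .conc_factor(units)
  df <- data.frame(m = titr$metal_conc / fac, absorbance = titr$absorbance)
  names(df)[1] <- paste0("metal_conc_", units)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a single-molecule trace CSV
#'
#' Expects columns `time_s` (bin start times, evenly spaced) and `counts`.
#'
#' @param path CSV path.
#' @param id Molecule identifier; defaults to the file name.
#' @param quencher_conc Metadata, mol/L.
#' @return A [photon_trace].
#' @export
read_trace_csv <- function(path, id = basename(path),
                           quencher_conc = NA_real_) {
  df <- .read_csv_checked(path, c("time_s", "counts"))
  dt <- diff(df$time_s)
  if (length(dt) < 1L || any(dt <= 0))
    stop("time_s must be strictly increasing with at least 2 bins")
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("time_s must be evenly spaced bins")
  photon_trace(df$counts, dt[1], id = id, quencher_conc = quencher_conc)
}

#' Write a single-molecule trace CSV
#'
#' @param trace A [photon_trace].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(
    time_s = (seq_along(trace$counts) - 1L) * trace$bin_width,
    counts = trace$counts), path, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum CSV
#'
#' Expects columns `wavelength_nm` and `value`.
#'
#' @param path CSV path.
#' @param kind `"emission"` or `"extinction"`.
#' @return A [spectrum].
#' @export
read_spectrum_csv <- function(path, kind = c("emission", "extinction")) {
  df <- .read_csv_checked(path, c("wavelength_nm", "value"))
  o <- order(df$wavelength_nm)
  spectrum(df$wavelength_nm[o], df$value[o], match.arg(kind))
}

#' Write a spectrum CSV
#'
#' @param sp A [spectrum].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(sp, path) {
  utils::write.csv(data.frame(wavelength_nm = sp$wavelength,
                              value = sp$value), path, row.names = FALSE)
  invisible(path)
}
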