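#' Construct a single reduced 1-D scattering curve
#'
#' A `scattering_curve` holds one reduced small-angle scattering frame:
#' the scattering-vector grid `q` (\eqn{\mathrm{\AA}^{-1}}), absolute
#' intensities `I(q)` (\eqn{\mathrm{cm}^{-1}}), optional per-point
#' uncertainties, and the acquisition time in minutes since trigger
#' addition. Non-finite or non-positive intensities are retained but
#' flagged; downstream fitting (which works in log space) excludes
#' flagged points, so reduction artefacts stay visible in the data.
#'
#' @param q numeric, strictly increasing, positive scattering vector grid.
#' @param intensity numeric, same length as `q`.
#' @param uncertainty optional numeric, same length as `q`, or `NULL`.
#' @param time_min scalar acquisition time in minutes.
#' @return an object of class `scattering_curve`: a list with elements
#'   `q`, `intensity`, `uncertainty`, `time_min` and a logical `flag`
#'   marking non-finite or non-positive intensities.
#' @export
scattering_curve <- function(q, intensity, uncertainty = NULL, time_min = NA_real_) {
  q <- as.numeric(q)
  intensity <- as.numeric(intensity)
  if (length(q) != length(intensity))
    stop("q and intensity must have equal length")
  if (!is.null(uncertainty)) {
    uncertainty <- as.numeric(uncertainty)
    if (length(uncertainty) != length(q))
      stop("uncertainty must match q in length")
  }
  if (any(!is.finite(q)) || any(q <= 0))
    stop("q must be finite and positive")
  if (is.unsorted(q, strictly = TRUE))
    stop("q must be strictly increasing")
  flag <- !is.finite(intensity) | intensity <= 0
  structure(
    list(q = q, intensity = intensity, uncertainty = uncertainty,
         time_min = as.numeric(time_min)[1], flag = flag),
    class = "scattering_curve"
  )
}

#' @export
print.scattering_curve <- function(x, ...) {
  cat(sprintf("<scattering_curve> %d points, q in [%.4g, %.4g] A^-1, t = %s min, %d flagged\n",
              length(x$q), min(x$q), max(x$q),
              format(x$time_min), sum(x$flag)))
  invisible(x)
}

#' Construct an ordered series of scattering curves
#'
#' All frames must share an identical q grid (see [read_series()] for
#' harmonisation of near-identical grids) and strictly increasing times.
#'
#' @param frames list of [scattering_curve()] objects, any order; they are
#'   sorted by `time_min`.
#' @param sample_label free-text sample description.
#' @param trigger gelation trigger, `"gdl"` or `"methanol"`.
#' @param trigger_percent trigger concentration (w/v % for GdL, v/v % for
#'   methanol).
#' @param rsf_mg_ml protein concentration, mg/ml.
#' @return object of class `curve_series`.
#' @export
curve_series <- function(frames, sample_label = "", trigger = c("gdl", "methanol"),
                         trigger_percent = NA_real_, rsf_mg_ml = NA_real_) {
  trigger <- match.arg(trigger)
  if (!length(frames)) stop("frames must be non-empty")
  ok <- vapply(frames, inherits, logical(1), "scattering_curve")
  if (!all(ok)) stop("all frames must be scattering_curve objects")
  times <- vapply(frames, function(f) f$time_min, numeric(1))
  if (anyNA(times)) stop("all frames need a time_min")
  if (anyDuplicated(times)) stop("duplicate frame timestamps")
  frames <- frames[order(times)]
  q0 <- frames[[1]]$q
  for (f in frames)
    if (length(f$q) != length(q0) || any(f$q != q0))
      stop("all frames must share an identical q grid; use read_series() to harmonise")
  structure(
    list(frames = frames, sample_label = sample_label, trigger = trigger,
         trigger_percent = trigger_percent, rsf_mg_ml = rsf_mg_ml),
    class = "curve_series"
  )
}

#' @export
print.curve_series <- function(x, ...) {
  times <- series_times(x)
  cat(sprintf("<curve_series> %s: %d frames (%g-%g min), trigger %s, %d q-points\n",
              x$sample_label, length(x$frames), min(times), max(times),
              x$trigger, length(x$frames[[1]]$q)))
  invisible(x)
}

#' Frame acquisition times of a curve series
#' @param series a `curve_series`.
#' @return numeric vector of times in minutes, strictly increasing.
#' @export
series_times <- function(series) {
  vapply(series$frames, function(f) f$time_min, numeric(1))
}

#' Construct a scalar kinetic trace
#'
#' A time-stamped scalar signal: ThT fluorescence at 485 nm, the 450 nm
#' turbidity proxy, off-line pH, or a normalised FTIR band intensity.
#'
#' @param time_min strictly increasing times, minutes.
#' @param value signal values in native units.
#' @param kind one of `"tht"`, `"turbidity"`, `"ph"`, `"ftir_band"`.
#' @return object of class `kinetic_trace`.
#' @export
kinetic_trace <- function(time_min, value,
                          kind = c("tht", "turbidity", "ph", "ftir_band")) {
  kind <- match.arg(kind)
  time_min <- as.numeric(time_min); value <- as.numeric(value)
  if (length(time_min) != length(value))
    stop("time_min and value must have equal length")
  if (is.unsorted(time_min, strictly = TRUE))
    stop("time_min must be strictly increasing")
  structure(list(time_min = time_min, value = value, kind = kind),
            class = "kinetic_trace")
}

#' Construct a time series of spectra on a shared axis
#'
#' @param axis wavelength (nm) or wavenumber (cm^-1) grid, shared by all
#'   spectra.
#' @param spectra numeric matrix, one column per timestamp, rows matching
#'   `axis`.
#' @param time_min strictly increasing acquisition times, minutes.
#' @param kind `"fluorescence_emission"` or `"ftir"`.
#' @return object of class `spectrum_series`.
#' @export
spectrum_series <- function(axis, spectra, time_min,
                            kind = c("fluorescence_emission", "ftir")) {
  kind <- match.arg(kind)
  axis <- as.numeric(axis)
  spectra <- as.matrix(spectra)
  time_min <- as.numeric(time_min)
  if (nrow(spectra) != length(axis))
    stop("spectra rows must match axis length")
  if (ncol(spectra) != length(time_min))
    stop("spectra columns must match time_min length")
  if (is.unsorted(time_min, strictly = TRUE))
    stop("time_min must be strictly increasing")
  structure(list(axis = axis, spectra = spectra, time_min = time_min, kind = kind),
            class = "spectrum_series")
}
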