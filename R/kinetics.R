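# Scalar kinetics: 4-parameter logistic fits of ThT fluorescence with
# onset/midpoint/plateau landmarks, extraction of the 485 nm ThT and
# 450 nm turbidity-proxy channels from emission spectra, and amide-I
# band preprocessing and kinetics for FTIR series.

#' Fit a 4-parameter logistic to a kinetic trace
#'
#' `value(t) = baseline + A / (1 + exp(-(t - t_m)/tau))`. The midpoint
#' `t_m` is where the fitted curve reaches 50% of its total amplitude `A`
#' (by construction), and `tau` is the characteristic transition time.
#' Initialisation is deterministic, from data quantiles (baseline and
#' amplitude from the 5%/95% quantiles, `t_m` from the half-amplitude
#' crossing, `tau` from the 25-75% crossing separation). A trace the
#' logistic fits no better than a flat (mean) model is flagged as a
#' failed fit.
#'
#' @param trace a [kinetic_trace()].
#' @return object of class `sigmoid_fit`: `baseline, A, t_m, tau,
#'   residual` (SSE), `ok` (logical), `converged`.
#' @export
fit_sigmoid <- function(trace) {
  t <- trace$time_min; y <- trace$value
  stopifnot(length(t) >= 5)
  q05 <- stats::quantile(y, 0.05, names = FALSE)
  q95 <- stats::quantile(y, 0.95, names = FALSE)
  A0 <- max(q95 - q05, 1e-12)
  cross <- function(frac) {
    lev <- q05 + frac * A0
    i <- which(y >= lev)
    if (!length(i)) t[length(t)] else t[min(i)]
  }
  tm0 <- cross(0.5)
  tau0 <- max((cross(0.75) - cross(0.25)) / (2 * log(3)), diff(range(t)) / 50)
  model <- function(p, t) p[["baseline"]] + p[["A"]] / (1 + exp(-(t - p[["t_m"]]) / p[["tau"]]))
  fit <- tryCatch(minpack.lm::nls.lm(
    par = c(baseline = q05, A = A0, t_m = tm0, tau = tau0),
    lower = c(baseline = -Inf, A = 1e-12, t_m = -Inf, tau = 1e-9),
    fn = function(p, t, y) model(p, t) - y, t = t, y = y,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit)) {
    p <- c(baseline = q05, A = A0, t_m = tm0, tau = tau0)
    sse <- sum((model(p, t) - y)^2); conv <- FALSE
  } else {
    p <- fit$par; sse <- fit$deviance; conv <- fit$info %in% 1:4
  }
  flat_sse <- sum((y - mean(y))^2)
  structure(list(baseline = p[["baseline"]], A = p[["A"]], t_m = p[["t_m"]],
                 tau = p[["tau"]], residual = sse,
                 ok = conv && sse < flat_sse, converged = conv),
            class = "sigmoid_fit")
}

#' Evaluate a fitted logistic
#' @param fit a `sigmoid_fit`.
#' @param t times, minutes.
#' @return fitted values.
#' @export
predict_sigmoid <- function(fit, t) {
  fit$baseline + fit$A / (1 + exp(-(t - fit$t_m) / fit$tau))
}

#' Kinetic landmarks of a sigmoidal transition
#'
#' Onset `tht_on = t_m - 2*tau`: at two time constants before the
#' midpoint the logistic sits at `1/(1 + e^2)` (about 11.9%, "roughly
#' 12%") of its amplitude — an analytic identity of the 4-parameter
#' logistic, so onset and the ~12% level are the same definition.
#' Midpoint `tht_m = t_m` (50% of A). The plateau `tht_p` has no
#' closed-form definition; the default rule takes the first time at which
#' the 3-point-smoothed measured trace enters and stays within
#' `plateau_frac` (2%) of the amplitude `A` around the median of the final
#' 10% of samples. `rule = "fit"` uses `t_m + 2*tau` instead.
#'
#' @param fit a `sigmoid_fit`.
#' @param trace the measured [kinetic_trace()] (needed for the default
#'   plateau rule).
#' @param rule `"trace"` (default) or `"fit"`.
#' @param plateau_frac band half-width as a fraction of `A`.
#' @return list `tht_on, tht_m, tht_p` (minutes; `tht_p` `NA` with a
#'   warning when the plateau is not reached within the trace).
#' @export
landmarks <- function(fit, trace = NULL, rule = c("trace", "fit"),
                      plateau_frac = 0.02) {
  rule <- match.arg(rule)
  tht_on <- fit$t_m - 2 * fit$tau
  tht_m <- fit$t_m
  if (rule == "fit") {
    tht_p <- fit$t_m + 2 * fit$tau
  } else {
    if (is.null(trace)) stop("trace needed for the plateau rule")
    y <- as.numeric(stats::filter(trace$value, rep(1 / 3, 3), sides = 2))
    y[is.na(y)] <- trace$value[is.na(y)]
    ntail <- max(2L, ceiling(0.1 * length(y)))
    final <- stats::median(y[(length(y) - ntail + 1):length(y)])
    inband <- abs(y - final) <= plateau_frac * fit$A
    # first index from which the trace stays in-band
    stays <- rev(cumprod(rev(inband))) > 0
    if (!any(stays)) {
      warning("plateau not reached within trace")
      tht_p <- NA_real_
    } else tht_p <- trace$time_min[min(which(stays))]
  }
  list(tht_on = tht_on, tht_m = tht_m, tht_p = tht_p)
}

# Mean spectral intensity around a nominal axis position, +/- halfwidth in
# axis units; grid-robust band read-out shared by the channel extractors.
band_readout <- function(series, center, halfwidth = 2) {
  idx <- which(abs(series$axis - center) <= halfwidth)
  if (!length(idx))
    stop("axis does not cover ", center, " +/- ", halfwidth)
  colMeans(series$spectra[idx, , drop = FALSE])
}

#' Turbidity-proxy trace from emission spectra
#'
#' Attenuation of the 450 nm excitation signal measured at 90 degrees is
#' a proxy for sample turbidity: per timestamp, the mean intensity over
#' the axis points within 2 nm of 450 nm.
#'
#' @param spectra a fluorescence [spectrum_series()].
#' @return a [kinetic_trace()] of kind `"turbidity"`.
#' @export
turbidity_trace <- function(spectra) {
  kinetic_trace(spectra$time_min, band_readout(spectra, 450), kind = "turbidity")
}

#' ThT fluorescence trace from emission spectra
#'
#' ThT emission at 485 nm reports on beta-sheet surface formation: per
#' timestamp, the mean intensity within 2 nm of 485 nm.
#'
#' @param spectra a fluorescence [spectrum_series()].
#' @return a [kinetic_trace()] of kind `"tht"`.
#' @export
tht_trace <- function(spectra) {
  kinetic_trace(spectra$time_min, band_readout(spectra, 485), kind = "tht")
}

#' Preprocess one FTIR spectrum to a normalised amide-I band
#'
#' Buffer subtraction (1:1 by default, or scaled by `buffer_scale`),
#' isolation of the amide-I window, subtraction of the straight line
#' through the window endpoints (so the output is anchored at 0 at both
#' ends), and division by the trapezoidal area so the band integrates
#' to 1. A non-positive post-baseline area is a flagged failure.
#'
#' @param spectrum intensity vector on `axis`.
#' @param buffer_spectrum buffer intensity on the same axis.
#' @param axis wavenumber grid, cm^-1.
#' @param window amide-I interval, default `c(1590, 1720)` cm^-1.
#' @param buffer_scale scalar multiplier on the buffer before subtraction.
#' @return list `axis, intensity, ok`; when `ok` is `FALSE` the intensity
#'   is the (unnormalised) baseline-corrected band.
#' @export
ftir_preprocess <- function(spectrum, buffer_spectrum, axis,
                            window = c(1590, 1720), buffer_scale = 1) {
  stopifnot(length(spectrum) == length(axis),
            length(buffer_spectrum) == length(axis))
  y <- spectrum - buffer_scale * buffer_spectrum
  idx <- which(axis >= window[1] & axis <= window[2])
  if (length(idx) < 3) stop("amide-I window contains too few points")
  x <- axis[idx]; y <- y[idx]
  i1 <- 1L; i2 <- length(idx)
  base <- y[i1] + (y[i2] - y[i1]) * (x - x[i1]) / (x[i2] - x[i1])
  y <- y - base
  area <- pracma::trapz(x, y)
  if (!is.finite(area) || area <= 0) {
    warning("non-positive amide-I area after baseline correction")
    return(list(axis = x, intensity = y, ok = FALSE))
  }
  list(axis = x, intensity = y / area, ok = TRUE)
}

#' Preprocess every spectrum of an FTIR series
#'
#' @param series an FTIR [spectrum_series()].
#' @param buffer_spectrum buffer intensity on the series axis.
#' @param window amide-I interval, cm^-1.
#' @return a [spectrum_series()] on the window axis; spectra that failed
#'   preprocessing become NA columns with a warning.
#' @export
ftir_preprocess_series <- function(series, buffer_spectrum,
                                   window = c(1590, 1720)) {
  cols <- lapply(seq_along(series$time_min), function(j) {
    p <- ftir_preprocess(series$spectra[, j], buffer_spectrum, series$axis,
                         window = window)
    if (p$ok) p$intensity else rep(NA_real_, length(p$intensity))
  })
  idx <- which(series$axis >= window[1] & series$axis <= window[2])
  spectrum_series(series$axis[idx], do.call(cbind, cols), series$time_min,
                  kind = "ftir")
}

#' Amide-I band kinetics
#'
#' Per requested band (default the canonical beta-sheet pair: 1620 cm^-1,
#' crystalline beta-sheet; 1695 cm^-1, antiparallel beta contacts), the
#' mean intensity within 2 cm^-1 of the band centre over time, min-max
#' normalised over the time course to `[0, 1]`. A constant band has a
#' degenerate normalisation and is returned as all zeros with a warning.
#'
#' @param series a preprocessed FTIR [spectrum_series()].
#' @param bands band centres, cm^-1.
#' @return named list of [kinetic_trace()] objects (kind `"ftir_band"`),
#'   one per band.
#' @export
ftir_band_kinetics <- function(series, bands = c(1620, 1695)) {
  out <- lapply(bands, function(bc) {
    v <- band_readout(series, bc, halfwidth = 2)
    rng <- range(v, na.rm = TRUE)
    if (diff(rng) == 0) {
      warning("constant band at ", bc, " cm^-1; returning zeros")
      v <- rep(0, length(v))
    } else v <- (v - rng[1]) / diff(rng)
    kinetic_trace(series$time_min, v, kind = "ftir_band")
  })
  names(out) <- paste0("band_", bands)
  out
}

#' Half-rise time of a normalised trace
#'
#' First time the trace crosses 0.5 (linear interpolation between the
#' bracketing samples); used to order the 1695 vs 1620 cm^-1 kinetics.
#'
#' @param trace a [kinetic_trace()] with values in `[0, 1]`.
#' @return time in minutes, `NA` if 0.5 is never crossed.
#' @export
half_rise_time <- function(trace) {
  t <- trace$time_min; v <- trace$value
  i <- which(v >= 0.5)
  if (!length(i)) return(NA_real_)
  i <- min(i)
  if (i == 1) return(t[1])
  t[i - 1] + (0.5 - v[i - 1]) / (v[i] - v[i - 1]) * (t[i] - t[i - 1])
}
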