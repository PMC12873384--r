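# Model-free per-frame scattering metrics: the apparent invariant
# (integral of I q^2 over the measured range), the mid-q correlation peak
# q+, and the low-q intensity — and their time traces with the landmark
# times t(q+) and t(q_on).

#' Apparent scattering invariant
#'
#' Trapezoidal integral of `I(q) * q^2` over the measured q grid only — no
#' Porod or Guinier extrapolation beyond the data, hence "apparent". A
#' proxy for the total scattering contrast from density fluctuations.
#'
#' @param curve a [scattering_curve()].
#' @return the invariant, cm^-1 A^-3.
#' @export
apparent_invariant <- function(curve) {
  stopifnot(length(curve$q) >= 2)
  pracma::trapz(curve$q, curve$intensity * curve$q^2)
}

#' Detect the mid-q correlation peak
#'
#' Among strict local maxima of the (optionally 3-point moving-average
#' smoothed) intensity inside the mid-q window, returns the one with the
#' greatest topographic prominence; `NULL` if the window contains no
#' strict local maximum (e.g. a monotone power-law curve). Equal
#' prominences break to the smallest q.
#'
#' @param curve a [scattering_curve()].
#' @param window q interval searched, default `c(0.013, 0.025)` A^-1; must
#'   lie inside the measured range.
#' @param smooth apply a 3-point moving average before peak picking.
#' @param min_prominence minimum prominence to accept, default 0 (any
#'   strict local maximum).
#' @return `NULL`, or a list with `q_plus`, `i_q_plus` (intensity at the
#'   peak, from the unsmoothed curve) and `prominence`.
#' @export
find_correlation_peak <- function(curve, window = c(0.013, 0.025),
                                  smooth = FALSE, min_prominence = 0) {
  q <- curve$q; I <- curve$intensity
  if (window[1] < min(q) || window[2] > max(q))
    stop("peak window lies outside the measured q range")
  y <- if (smooth) stats::filter(I, rep(1 / 3, 3), sides = 2) else I
  y <- as.numeric(y)
  idx <- which(q >= window[1] & q <= window[2])
  if (length(idx) < 3) return(NULL)
  # strict interior local maxima within the window (window-local neighbours)
  cand <- idx[-c(1, length(idx))]
  cand <- cand[is.finite(y[cand]) &
                 y[cand] > y[cand - 1] & y[cand] > y[cand + 1]]
  if (!length(cand)) return(NULL)
  prom <- vapply(cand, function(i) peak_prominence(y[idx], match(i, idx)),
                 numeric(1))
  keep <- prom >= min_prominence
  if (!any(keep)) return(NULL)
  cand <- cand[keep]; prom <- prom[keep]
  best <- cand[which.max(prom)]  # which.max -> first (smallest q) on ties
  list(q_plus = q[best], i_q_plus = I[best], prominence = max(prom))
}

# Topographic prominence of peak at position i within vector y: height
# minus the higher of the two key saddles (walk out in each direction
# until a point higher than the peak, track the minimum on the way).
peak_prominence <- function(y, i) {
  h <- y[i]
  left <- y[seq_len(i - 1)]
  right <- if (i < length(y)) y[(i + 1):length(y)] else numeric(0)
  saddle <- function(v) {
    if (!length(v)) return(-Inf)
    higher <- which(v > h)
    if (length(higher)) v <- v[(max(higher) + 1):length(v)]
    if (!length(v)) -Inf else min(v)
  }
  ls <- saddle(left)
  rs <- saddle(rev(right))  # walk outward = away from peak
  base <- max(ls, rs)
  if (!is.finite(base)) base <- min(ls, rs, min(y))
  h - base
}

#' Mean low-q intensity
#'
#' Mean of `I` over grid points with q inside the window, default
#' `[q_min, 0.003]` A^-1 — well below the correlation-peak window, in the
#' power-law-dominated regime.
#'
#' @param curve a [scattering_curve()].
#' @param window low-q interval, A^-1; `NULL` lower edge means `min(q)`.
#' @return mean intensity, cm^-1.
#' @export
low_q_intensity <- function(curve, window = c(NA, 0.003)) {
  lo <- if (is.na(window[1])) min(curve$q) else window[1]
  idx <- curve$q >= lo & curve$q <= window[2]
  if (!any(idx)) stop("low-q window contains no data points")
  mean(curve$intensity[idx])
}

#' Per-frame metric traces for a series
#'
#' Computes the apparent invariant, low-q intensity and correlation peak
#' for every frame, plus two landmark times on the `I(q+)` trace:
#' `t_q_plus`, the time of maximum peak intensity (earliest frame on
#' plateaus), and `t_q_on`, the onset of the second rise — the first time
#' after the post-peak minimum at which `I(q+)` exceeds that minimum by
#' `onset_frac` of the trace's total range (the trace typically peaks
#' early, dips, then rises again as the network assembles).
#'
#' @param series a [curve_series()].
#' @param window mid-q peak window, A^-1.
#' @param low_q_window low-q window, A^-1.
#' @param onset_frac fraction of the total `I(q+)` range defining the
#'   second-rise onset, default 0.10.
#' @param smooth passed to [find_correlation_peak()].
#' @return data.frame with one row per frame (`time_min, q_plus, i_q_plus,
#'   i_low_q, q_star`; `q_plus`/`i_q_plus` are `NA` when no peak), with
#'   attributes `t_q_plus` and `t_q_on` (the latter `NA` when undefined).
#' @export
metric_traces <- function(series, window = c(0.013, 0.025),
                          low_q_window = c(NA, 0.003), onset_frac = 0.10,
                          smooth = FALSE) {
  rows <- lapply(series$frames, function(fr) {
    pk <- find_correlation_peak(fr, window = window, smooth = smooth)
    data.frame(time_min = fr$time_min,
               q_plus = if (is.null(pk)) NA_real_ else pk$q_plus,
               i_q_plus = if (is.null(pk)) NA_real_ else pk$i_q_plus,
               i_low_q = low_q_intensity(fr, window = low_q_window),
               q_star = apparent_invariant(fr))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ip <- out$i_q_plus
  t_q_plus <- if (all(is.na(ip))) NA_real_ else
    out$time_min[which.max(replace(ip, is.na(ip), -Inf))]
  attr(out, "t_q_plus") <- t_q_plus
  attr(out, "t_q_on") <- second_rise_onset(out$time_min, ip, onset_frac)
  out
}

# Onset of the second rise of a peak-dip-rise trace: locate the global
# maximum, then the minimum after it, then the first later time exceeding
# that minimum by frac * total range. NA when the shape is absent.
second_rise_onset <- function(time, value, frac = 0.10) {
  ok <- !is.na(value)
  if (sum(ok) < 3) return(NA_real_)
  t <- time[ok]; v <- value[ok]
  ipk <- which.max(v)
  if (ipk >= length(v)) return(NA_real_)
  after <- (ipk + 1):length(v)
  imin <- after[which.min(v[after])]
  if (imin >= length(v)) return(NA_real_)
  thr <- v[imin] + frac * (max(v) - min(v))
  later <- ((imin + 1):length(v))
  hit <- later[v[later] >= thr]
  if (!length(hit)) NA_real_ else t[min(hit)]
}
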