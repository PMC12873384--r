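# CSV interchange: per-frame curves (q,I,dI), a YAML/JSON manifest carrying
# frame times and sample metadata, 2-column kinetic traces, and wide spectra.

#' Read one reduced scattering curve from CSV
#'
#' Expects a header and at least two numeric columns. The default dialect
#' maps columns `q`, `I`, `dI`; deposited data with other headers are
#' absorbed by passing a different `dialect`. Rows with non-finite or
#' non-positive intensity are kept and flagged, never dropped: whether to
#' use them is a fitting-layer decision.
#'
#' @param path CSV file path.
#' @param dialect named list mapping roles to column names,
#'   `list(q=, intensity=, uncertainty=)`. Column positions (1-based
#'   integers) are also accepted.
#' @param time_min acquisition time to attach, minutes.
#' @return a [scattering_curve()].
#' @export
read_curve <- function(path,
                       dialect = list(q = "q", intensity = "I", uncertainty = "dI"),
                       time_min = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(utils::read.csv(path, check.names = FALSE),
                 error = function(e) stop("parse error in ", path, ": ",
                                          conditionMessage(e)))
  if (ncol(df) < 2) stop("parse error in ", path, ": need >= 2 columns")
  pick <- function(role, required = TRUE) {
    key <- dialect[[role]]
    if (is.numeric(key)) {
      if (key > ncol(df)) {
        if (required) stop("column ", key, " absent in ", path) else return(NULL)
      }
      return(df[[key]])
    }
    if (!is.null(key) && key %in% names(df)) return(df[[key]])
    if (required) stop("column '", key, "' absent in ", path)
    NULL
  }
  q <- pick("q")
  intensity <- pick("intensity")
  uncertainty <- pick("uncertainty", required = FALSE)
  bad <- which(!is.finite(suppressWarnings(as.numeric(q))))
  if (length(bad))
    stop("parse error in ", path, ": non-numeric q at data line ", bad[1])
  if (is.unsorted(as.numeric(q), strictly = TRUE))
    stop("validation error in ", path, ": q not strictly increasing")
  scattering_curve(q, intensity, uncertainty, time_min = time_min)
}

#' Write a scattering curve to CSV
#'
#' Full `%.17g` precision so that read/write round-trips are bit-identical
#' for finite doubles.
#'
#' @param curve a [scattering_curve()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  has_u <- !is.null(curve$uncertainty)
  fmt <- function(x) sprintf("%.17g", x)
  header <- if (has_u) "q,I,dI" else "q,I"
  rows <- if (has_u)
    paste(fmt(curve$q), fmt(curve$intensity), fmt(curve$uncertainty), sep = ",")
  else paste(fmt(curve$q), fmt(curve$intensity), sep = ",")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a time series of curves from a manifest
#'
#' The manifest (YAML or JSON) lists per-frame files and times plus sample
#' metadata:
#' \preformatted{
#' sample_label: rsf10-gdl1
#' trigger: gdl
#' trigger_percent: 1.0
#' rsf_mg_ml: 10
#' frames:
#'   - {path: frame_0005.csv, time_min: 5}
#'   - {path: frame_0010.csv, time_min: 10}
#' }
#' Relative frame paths resolve against the manifest's directory. Frames are
#' sorted by time. q grids are harmonised: grids equal within a relative
#' tolerance of `1e-6` per point are accepted as identical; otherwise the
#' exact intersection of the grids (matched within tolerance) is used, and
#' an empty intersection is an error — intensities are never silently
#' interpolated onto a new grid.
#'
#' @param manifest path to a YAML or JSON manifest.
#' @param dialect column dialect passed to [read_curve()].
#' @param tol relative q-grid match tolerance.
#' @return a [curve_series()].
#' @export
read_series <- function(manifest,
                        dialect = list(q = "q", intensity = "I", uncertainty = "dI"),
                        tol = 1e-6) {
  if (!file.exists(manifest)) stop("manifest not found: ", manifest)
  meta <- if (grepl("\\.json$", manifest, ignore.case = TRUE))
    jsonlite::read_json(manifest, simplifyVector = FALSE)
  else yaml::read_yaml(manifest)
  if (is.null(meta$frames) || !length(meta$frames))
    stop("manifest lists no frames")
  base <- dirname(manifest)
  times <- vapply(meta$frames, function(f) as.numeric(f$time_min), numeric(1))
  if (anyNA(times)) stop("unparseable frame time in manifest")
  if (anyDuplicated(times)) stop("duplicate timestamps in manifest")
  frames <- Map(function(f, t) {
    p <- f$path
    if (!file.exists(p)) p <- file.path(base, f$path)
    read_curve(p, dialect = dialect, time_min = t)
  }, meta$frames, times)
  frames <- harmonise_q_grids(frames, tol = tol)
  curve_series(frames,
               sample_label = meta$sample_label %||% "",
               trigger = meta$trigger %||% "gdl",
               trigger_percent = as.numeric(meta$trigger_percent %||% NA),
               rsf_mg_ml = as.numeric(meta$rsf_mg_ml %||% NA))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Make every frame share one q grid. Grids already equal within relative
# tol are snapped to the first frame's grid; otherwise frames are cut to
# the common intersection of grid points.
harmonise_q_grids <- function(frames, tol = 1e-6) {
  q0 <- frames[[1]]$q
  same <- vapply(frames, function(f) {
    length(f$q) == length(q0) && all(abs(f$q - q0) <= tol * pmax(abs(q0), 1e-300))
  }, logical(1))
  if (all(same)) {
    return(lapply(frames, function(f) {
      f$q <- q0
      f
    }))
  }
  keys <- lapply(frames, function(f) round(log(f$q) / tol / 10) ) # coarse match key
  common <- Reduce(intersect, keys)
  if (!length(common))
    stop("inconsistent q grids beyond tolerance: no common q points")
  frames <- Map(function(f, k) {
    idx <- match(common, k)
    scattering_curve(f$q[idx], f$intensity[idx],
                     if (is.null(f$uncertainty)) NULL else f$uncertainty[idx],
                     time_min = f$time_min)
  }, frames, keys)
  qref <- frames[[1]]$q
  lapply(frames, function(f) { f$q <- qref; f })
}

#' Read a 2-column kinetic trace CSV (`time_min,value`)
#' @param path CSV path.
#' @param kind trace kind, see [kinetic_trace()].
#' @return a [kinetic_trace()].
#' @export
read_trace <- function(path, kind = "tht") {
  df <- utils::read.csv(path)
  if (ncol(df) < 2) stop("trace file needs 2 columns: ", path)
  kinetic_trace(df[[1]], df[[2]], kind = kind)
}

#' Write a kinetic trace as 2-column CSV
#' @param trace a [kinetic_trace()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  writeLines(c("time_min,value",
               paste(sprintf("%.17g", trace$time_min),
                     sprintf("%.17g", trace$value), sep = ",")), path)
  invisible(path)
}

#' Read a wide spectra CSV (first column axis, one column per timestamp)
#'
#' Column headers after the first must be parseable as times in minutes
#' (e.g. `t5`, `t10` or plain numbers).
#'
#' @param path CSV path.
#' @param kind series kind, see [spectrum_series()].
#' @return a [spectrum_series()].
#' @export
read_spectra <- function(path, kind = "fluorescence_emission") {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) stop("spectra file needs >= 2 columns: ", path)
  tm <- suppressWarnings(as.numeric(gsub("[^0-9.eE+-]", "", names(df)[-1])))
  if (anyNA(tm)) stop("unparseable time in spectra header: ", path)
  spectrum_series(df[[1]], as.matrix(df[-1]), tm, kind = kind)
}

#' Write a spectrum series as wide CSV
#' @param series a [spectrum_series()].
#' @param path output path.
#' @param axis_name header for the axis column.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(series, path, axis_name = "axis") {
  hdr <- paste(c(axis_name, paste0("t", format(series$time_min, trim = TRUE))),
               collapse = ",")
  body <- apply(cbind(series$axis, series$spectra), 1L,
                function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Resample a kinetic trace onto the SANS frame times
#'
#' Linear interpolation of the trace at each frame time, truncated to the
#' overlapping time interval (no extrapolation). Required before any
#' correlation or joint-matrix analysis, which assume matched time points.
#'
#' @param trace a [kinetic_trace()].
#' @param series a [curve_series()] supplying the target frame times.
#' @return a [kinetic_trace()] on the (possibly truncated) frame grid.
#' @export
align_to_frames <- function(trace, series) {
  ft <- series_times(series)
  keep <- ft >= min(trace$time_min) & ft <= max(trace$time_min)
  if (!any(keep)) stop("trace and series do not overlap in time")
  tt <- ft[keep]
  v <- stats::approx(trace$time_min, trace$value, xout = tt, method = "linear")$y
  kinetic_trace(tt, v, kind = trace$kind)
}
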