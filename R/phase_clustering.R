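# Phase mapping of the fitted parameter trajectories: z-score the
# eight-parameter set (a, n, c, eta, m, d, q0, sigma), cluster with
# DBSCAN (eps = 1.0, min_samples = 5, Euclidean), assign clusters to the
# four gelation phases by their dominant time windows, and size each
# phase's envelope by its convex-hull volume in the (n, m, d) subspace.

PHASE_LEVELS <- c("Initiation", "Pre-assembly", "NetworkAssembly", "Maturation")
CLUSTER_PARAMS <- c("a", "n", "c", "eta", "m", "d", "q0", "sigma")

#' Z-score the eight-parameter fit matrix
#'
#' Standardises each of `a, n, c, eta, m, d, q0, sigma` to mean 0, sd 1
#' across the trajectory (the background `b` is not part of the clustered
#' set). A zero-variance parameter is set to all zeros with a warning
#' rather than dividing by zero.
#'
#' @param traj a `param_trajectory` from [fit_series()] (stage-2 fits), or
#'   its `table` data.frame.
#' @return numeric matrix, rows = frames, columns = the eight parameters,
#'   with attribute `time_min`.
#' @export
zscore_matrix <- function(traj) {
  tab <- if (inherits(traj, "param_trajectory")) traj$table else traj
  if (nrow(tab) < 2) stop("need >= 2 frames to standardise")
  if (anyNA(tab[, CLUSTER_PARAMS]))
    stop("z-scoring needs stage-2 fits for every frame (found NA parameters)")
  m <- as.matrix(tab[, CLUSTER_PARAMS])
  mu <- colMeans(m)
  # population sd (the standard scaler convention): two frames map to +/-1
  sdv <- sqrt(colMeans(sweep(m, 2, mu)^2))
  zero <- sdv == 0 | !is.finite(sdv)
  if (any(zero)) {
    warning("zero-variance parameter(s) set to 0: ",
            paste(CLUSTER_PARAMS[zero], collapse = ", "))
    sdv[zero] <- 1
  }
  z <- sweep(sweep(m, 2, mu), 2, sdv, "/")
  z[, zero] <- 0
  attr(z, "time_min") <- tab$time_min
  z
}

#' DBSCAN clustering (Euclidean, closed ball, self-counting)
#'
#' Standard DBSCAN semantics: a point is a core point when its closed
#' eps-ball contains at least `min_samples` points (itself included);
#' clusters grow by expanding density-reachability from core points;
#' border points join the first core cluster that reaches them; points
#' reachable from no core are noise, labelled `-1`. Partitions are
#' invariant to point order up to cluster-id relabelling.
#'
#' @param points numeric matrix, rows = observations.
#' @param eps neighbourhood radius (distance <= eps).
#' @param min_samples core threshold, self counted.
#' @return integer vector of cluster ids (0-based in discovery order;
#'   noise = -1).
#' @export
dbscan_cluster <- function(points, eps = 1.0, min_samples = 5L) {
  stopifnot(eps > 0, min_samples >= 1)
  points <- as.matrix(points)
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_samples
  labels <- rep(NA_integer_, n)
  cl <- -1L
  for (i in seq_len(n)) {
    if (!is.na(labels[i]) || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (is.na(labels[j]) || labels[j] == -1L) {
        newly <- is.na(labels[j])
        labels[j] <- cl
        if (newly && core[j]) queue <- c(queue, nb[[j]])
      }
    }
  }
  labels[is.na(labels)] <- -1L
  labels
}

#' Assign DBSCAN clusters to the four gelation phases
#'
#' Clusters are ordered by the median acquisition time of their members
#' and labelled Initiation, Pre-assembly, NetworkAssembly, Maturation in
#' that order — the phases are time regimes, so the dominant time-point
#' distribution identifies them. With more than 4 clusters, the 4 most
#' populous keep labels (re-ordered by median time) and the rest are
#' demoted to Noise with a warning; with fewer, only the earliest labels
#' are used (warning). DBSCAN noise stays Noise.
#'
#' @param cluster_ids integer ids from [dbscan_cluster()].
#' @param times per-frame times, minutes.
#' @return factor of phase labels with levels
#'   `Initiation, Pre-assembly, NetworkAssembly, Maturation, Noise`.
#' @export
assign_phases <- function(cluster_ids, times) {
  stopifnot(length(cluster_ids) == length(times))
  ids <- sort(unique(cluster_ids[cluster_ids >= 0]))
  if (!length(ids)) stop("all points are noise; no clusters to label")
  med <- vapply(ids, function(k) stats::median(times[cluster_ids == k]), numeric(1))
  siz <- vapply(ids, function(k) sum(cluster_ids == k), integer(1))
  keep <- ids
  if (length(ids) > 4) {
    keep <- ids[order(-siz, med)][1:4]
    warning(length(ids) - 4, " extra cluster(s) demoted to Noise")
  }
  keep <- keep[order(med[match(keep, ids)])]
  if (length(keep) < 4)
    warning("only ", length(keep), " cluster(s) recovered; phases ",
            paste(PHASE_LEVELS[seq_along(keep)], collapse = ", "), " used")
  lab <- rep("Noise", length(cluster_ids))
  for (i in seq_along(keep)) lab[cluster_ids == keep[i]] <- PHASE_LEVELS[i]
  factor(lab, levels = c(PHASE_LEVELS, "Noise"))
}

#' Convex-hull phase volumes in a parameter subspace
#'
#' For each non-noise phase, the 3-D convex-hull volume of its members in
#' the z-scored subspace (default `(n, m, d)`, the most correlated triple
#' and the one in which the phase envelopes are visualised), expressed as
#' a percentage of the summed volumes. Phases with fewer than 4 points or
#' degenerate (coplanar) geometry get volume 0. An 8-D option is not
#' offered here: on ~60-frame trajectories high-dimensional hulls are
#' noise-dominated.
#'
#' @param z z-scored matrix from [zscore_matrix()].
#' @param labels phase factor from [assign_phases()].
#' @param subspace character triple of parameter names.
#' @return data.frame `phase, n_frames, volume, volume_pct` over phases
#'   present (noise excluded); percentages sum to 100.
#' @export
hull_volumes <- function(z, labels, subspace = c("n", "m", "d")) {
  stopifnot(length(subspace) == 3, all(subspace %in% colnames(z)))
  phases <- PHASE_LEVELS[PHASE_LEVELS %in% labels]
  vols <- vapply(phases, function(ph) {
    pts <- z[labels == ph, subspace, drop = FALSE]
    if (nrow(pts) < 4) 0 else convex_hull_volume(pts)
  }, numeric(1))
  if (all(vols == 0))
    stop("all phase hulls are degenerate; volume percentages undefined")
  data.frame(phase = phases,
             n_frames = vapply(phases, function(ph) sum(labels == ph), integer(1)),
             volume = vols,
             volume_pct = 100 * vols / sum(vols),
             row.names = NULL)
}

#' Per-phase correlation-length and spacing statistics
#'
#' Mean and population standard deviation (divide by N — a single-member
#' phase reports sd 0) of the Lorentzian correlation length `eta` and the
#' inter-domain spacing `d* = 2*pi/q0` over each phase's member frames.
#'
#' @param traj a `param_trajectory` (stage-2) or its `table`.
#' @param labels phase factor from [assign_phases()] matching the rows.
#' @return data.frame `phase, n_frames, eta_mean, eta_sd, dstar_mean,
#'   dstar_sd` over non-empty, non-noise phases.
#' @export
phase_statistics <- function(traj, labels) {
  tab <- if (inherits(traj, "param_trajectory")) traj$table else traj
  stopifnot(nrow(tab) == length(labels))
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  phases <- PHASE_LEVELS[PHASE_LEVELS %in% labels]
  out <- do.call(rbind, lapply(phases, function(ph) {
    i <- labels == ph
    data.frame(phase = ph, n_frames = sum(i),
               eta_mean = mean(tab$eta[i]), eta_sd = pop_sd(tab$eta[i]),
               dstar_mean = mean(tab$d_star[i]), dstar_sd = pop_sd(tab$d_star[i]))
  }))
  rownames(out) <- NULL
  out
}

#' Full phase-mapping step
#'
#' Convenience wrapper: z-score, DBSCAN, phase assignment, hull volumes
#' and phase statistics in one call.
#'
#' @param traj stage-2 `param_trajectory`.
#' @param eps,min_samples DBSCAN settings.
#' @param subspace hull subspace, default `(n, m, d)`.
#' @return list `labels, cluster_ids, z, volumes, stats`.
#' @export
map_phases <- function(traj, eps = 1.0, min_samples = 5L,
                       subspace = c("n", "m", "d")) {
  z <- zscore_matrix(traj)
  ids <- dbscan_cluster(z, eps = eps, min_samples = min_samples)
  labels <- assign_phases(ids, attr(z, "time_min"))
  list(labels = labels, cluster_ids = ids, z = z,
       volumes = hull_volumes(z, labels, subspace = subspace),
       stats = phase_statistics(traj, labels))
}
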