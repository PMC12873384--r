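# Joint multivariate curve resolution of the SANS + fluorescence time
# series. The two probes share one time dimension, so the data are
# arranged as an augmented matrix D (rows = SANS frame times, columns =
# the q-grid block followed by the emission-wavelength block) and
# factorised as D ~ C S^T with non-negativity on the concentration
# profiles C and on both signature blocks S. Using complementary probes
# in one factorisation narrows the rotational ambiguity that either
# block alone would leave.

#' Build the row-augmented joint SANS + fluorescence matrix
#'
#' The fluorescence series is resampled onto the SANS frame times
#' (linear interpolation per wavelength, truncation to the overlapping
#' interval). Each block is max-normalised to 1 and the fluorescence
#' block is then rescaled so the two blocks carry equal total variance
#' (sum of column variances) — otherwise the larger block dominates the
#' least-squares objective.
#'
#' @param sans a [curve_series()].
#' @param fluor a fluorescence [spectrum_series()].
#' @param equal_variance rescale blocks to equal summed variance.
#' @return object of class `joint_matrix`: `D` (matrix), `time_min`,
#'   `block` (factor `"sans"`/`"fluor"` per column), `col_axis` (q or
#'   wavelength per column), `block_weights`.
#' @export
build_joint_matrix <- function(sans, fluor, equal_variance = TRUE) {
  ft <- series_times(sans)
  keep <- ft >= min(fluor$time_min) & ft <= max(fluor$time_min)
  if (!any(keep)) stop("SANS and fluorescence series do not overlap in time")
  tt <- ft[keep]
  S <- t(vapply(sans$frames[keep], function(f) f$intensity,
                numeric(length(sans$frames[[1]]$q))))
  FL <- t(apply(fluor$spectra, 1, function(row)
    stats::approx(fluor$time_min, row, xout = tt)$y))
  FL <- t(FL)  # rows = times, cols = wavelengths
  if (anyNA(S) || anyNA(FL)) stop("joint matrix entries must be finite")
  w_s <- 1 / max(S); w_f <- 1 / max(FL)
  S <- S * w_s; FL <- FL * w_f
  if (equal_variance) {
    vs <- sum(apply(S, 2, stats::var)); vf <- sum(apply(FL, 2, stats::var))
    if (vf > 0 && vs > 0) {
      adj <- sqrt(vs / vf)
      FL <- FL * adj
      w_f <- w_f * adj
    }
  }
  D <- cbind(S, FL)
  structure(list(
    D = D, time_min = tt,
    block = factor(rep(c("sans", "fluor"), c(ncol(S), ncol(FL))),
                   levels = c("sans", "fluor")),
    col_axis = c(sans$frames[[1]]$q, fluor$axis),
    block_weights = c(sans = w_s, fluor = w_f)),
    class = "joint_matrix")
}

#' Rank selection by explained singular-value variance
#'
#' Smallest k whose leading singular values explain at least `threshold`
#' of the total variance (sum of squared singular values). The full scree
#' is returned so the default choice of 3 components stays auditable.
#'
#' @param jm a `joint_matrix` or plain matrix.
#' @param threshold explained-variance fraction, default 0.995.
#' @return list `k`, `explained` (cumulative fractions), `singular_values`.
#' @export
select_rank <- function(jm, threshold = 0.995) {
  D <- if (inherits(jm, "joint_matrix")) jm$D else as.matrix(jm)
  sv <- svd(D, nu = 0, nv = 0)$d
  tot <- sum(sv^2)
  if (tot == 0) stop("matrix has no variance; rank undefined")
  cum <- cumsum(sv^2) / tot
  list(k = min(which(cum >= threshold)), explained = cum, singular_values = sv)
}

# Non-negative least squares of X ~ A B^T for B; A is (n x k), X is
# (n x m), returns (m x k). For the small component counts used here the
# exact optimum is found by enumerating the 2^k candidate active sets,
# vectorised across all m right-hand sides (the normal-equation blocks
# G = A'A and H = A'X are shared); each column keeps the first candidate
# satisfying primal feasibility (x >= 0) and dual optimality (gradient of
# the dropped coordinates >= 0), which is the unique NNLS solution. Falls
# back to Lawson-Hanson per column for larger k.
nnls_block <- function(A, X, tol = 1e-10) {
  k <- ncol(A)
  m <- ncol(X)
  if (k > 10) {
    out <- matrix(0, m, k)
    for (j in seq_len(m)) out[j, ] <- pracma::lsqnonneg(A, X[, j])$x
    return(out)
  }
  G <- crossprod(A)
  H <- crossprod(A, X)                 # k x m
  scale <- max(diag(G), 1)
  out <- matrix(NA_real_, k, m)
  unresolved <- rep(TRUE, m)
  subsets <- lapply((2^k - 1):0, function(bits) which(bitwAnd(bits, 2^(seq_len(k) - 1)) > 0))
  subsets <- subsets[order(-vapply(subsets, length, integer(1)))]
  for (S in subsets) {
    if (!any(unresolved)) break
    idx <- which(unresolved)
    x <- matrix(0, k, length(idx))
    if (length(S)) {
      sol <- tryCatch(solve(G[S, S, drop = FALSE], H[S, idx, drop = FALSE]),
                      error = function(e) NULL)
      if (is.null(sol)) next
      x[S, ] <- sol
    }
    feas <- colSums(x < -tol * scale) == 0
    grad <- G %*% x - H[, idx, drop = FALSE]
    free <- setdiff(seq_len(k), S)
    opt <- if (length(free)) colSums(grad[free, , drop = FALSE] < -tol * scale) == 0
           else rep(TRUE, length(idx))
    ok <- feas & opt
    if (any(ok)) {
      out[, idx[ok]] <- pmax(x[, ok, drop = FALSE], 0)
      unresolved[idx[ok]] <- FALSE
    }
  }
  if (any(unresolved))                  # numerically awkward columns
    for (j in which(unresolved)) out[, j] <- pracma::lsqnonneg(A, X[, j])$x
  t(out)
}

#' MCR-ALS factorisation of a joint matrix
#'
#' Alternating non-negativity-constrained least squares: with signatures
#' S fixed, each time row of D is regressed on S to update C; with C
#' fixed, each column is regressed on C to update S. Both subproblems are
#' solved exactly (Lawson-Hanson NNLS), so the lack of fit,
#' `100 * sqrt(SSE / sum(D^2))`, is non-increasing across iterations
#' (asserted). After every iteration each component's signature is
#' rescaled to unit maximum with the inverse scale moved into C, which
#' leaves the reconstruction unchanged and pins the scale indeterminacy.
#'
#' Initialisation: `"purest"` (default) picks k rows of D of maximal
#' mutual dissimilarity (largest norm first, then largest residual after
#' projection onto the span of those already chosen) as initial
#' signatures; `"random"` draws non-negative uniform signatures from
#' `seed`.
#'
#' @param jm a `joint_matrix` (or plain matrix).
#' @param k number of components, default 3.
#' @param init `"purest"` or `"random"`.
#' @param tol relative lack-of-fit change declaring convergence.
#' @param max_iter iteration cap.
#' @param seed RNG seed for `init = "random"` and perturbed restarts.
#' @param init_S optional explicit initial signature matrix (cols x k).
#' @return object of class `mcr_result`: `C` (times x k), `S` (cols x k),
#'   `S_sans`, `S_fluor` (block rows of S), `lack_of_fit` (%), `lof_trace`
#'   (per iteration), `converged`, `time_min`, `block`.
#' @export
mcr_als_solve <- function(jm, k = 3, init = c("purest", "random"),
                          tol = 1e-8, max_iter = 500, seed = 1,
                          init_S = NULL) {
  init <- match.arg(init)
  D <- if (inherits(jm, "joint_matrix")) jm$D else as.matrix(jm)
  stopifnot(k >= 1, k <= min(dim(D)))
  if (k == nrow(D)) warning("k equals the number of time points; overparameterised")
  tot <- sum(D^2)
  if (tot == 0) stop("matrix has no variance")
  if (is.null(init_S)) {
    init_S <- if (init == "purest") purest_rows(D, k) else {
      old <- .Random.seed_get()
      on.exit(.Random.seed_set(old), add = TRUE)
      set.seed(seed)
      matrix(stats::runif(ncol(D) * k), ncol(D), k)
    }
  }
  S <- pmax(init_S, 0)
  lof <- Inf
  lof_trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    C <- nnls_block(S, t(D))           # rows of D on S
    if (all(C == 0)) C[, 1] <- rowMeans(D)  # guard against total collapse
    S <- nnls_block(C, D)              # cols of D on C
    # unit-max signatures; compensating scale into C
    sc <- apply(S, 2, max)
    sc[sc == 0] <- 1
    S <- sweep(S, 2, sc, "/")
    C <- sweep(C, 2, sc, "*")
    sse <- sum((D - C %*% t(S))^2)
    new_lof <- 100 * sqrt(sse / tot)
    if (new_lof > lof + 1e-9)
      stop("internal error: lack of fit increased during ALS")
    lof_trace <- c(lof_trace, new_lof)
    if (is.finite(lof) && (lof - new_lof) <= tol * max(lof, 1e-12)) {
      lof <- new_lof
      converged <- TRUE
      break
    }
    lof <- new_lof
  }
  blk <- if (inherits(jm, "joint_matrix")) jm$block else
    factor(rep("sans", ncol(D)), levels = c("sans", "fluor"))
  structure(list(
    C = C, S = S,
    S_sans = S[blk == "sans", , drop = FALSE],
    S_fluor = S[blk == "fluor", , drop = FALSE],
    lack_of_fit = lof, lof_trace = lof_trace, converged = converged,
    time_min = if (inherits(jm, "joint_matrix")) jm$time_min else seq_len(nrow(D)),
    block = blk),
    class = "mcr_result")
}

# save/restore .Random.seed so seeded internals do not disturb the caller
.Random.seed_get <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

# k rows of maximal mutual dissimilarity: largest norm first, then
# repeatedly the row with the largest residual after projection onto the
# span of the chosen rows (SIMPLISMA-flavoured, deterministic).
purest_rows <- function(D, k) {
  norms <- sqrt(rowSums(D^2))
  sel <- which.max(norms)
  while (length(sel) < k) {
    B <- t(D[sel, , drop = FALSE])          # cols x |sel|
    qr_B <- qr(B)
    resid <- vapply(seq_len(nrow(D)), function(i) {
      r <- qr.resid(qr_B, D[i, ])
      sum(r^2)
    }, numeric(1))
    resid[sel] <- -Inf
    sel <- c(sel, which.max(resid))
  }
  t(D[sel, , drop = FALSE])
}

#' Restart-based uncertainty envelopes for MCR profiles
#'
#' Re-runs the ALS from `n_restarts` perturbed initialisations (the base
#' initial signatures scaled by seeded uniform factors in
#' `[1-amplitude, 1+amplitude]`), keeps the solutions whose lack of fit
#' lies within `keep_rel` (relative) of the best, matches their
#' components to the best solution by maximal profile correlation, and
#' returns the pointwise min/max band over the kept solutions. The band
#' always contains the best-fit profiles.
#'
#' @param jm a `joint_matrix`.
#' @param k components.
#' @param n_restarts number of perturbed runs (>= 2).
#' @param seed RNG seed.
#' @param keep_rel relative lack-of-fit acceptance band, default 0.05.
#' @param amplitude perturbation amplitude.
#' @param ... passed to [mcr_als_solve()].
#' @return list `best` (an `mcr_result`), `C_lower`, `C_upper`,
#'   `S_lower`, `S_upper`, `n_kept`.
#' @export
mcr_envelopes <- function(jm, k = 3, n_restarts = 20, seed = 1,
                          keep_rel = 0.05, amplitude = 0.3, ...) {
  stopifnot(n_restarts >= 2)
  D <- jm$D
  base_S <- purest_rows(D, k)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  perturb <- lapply(seq_len(n_restarts), function(i)
    base_S * matrix(stats::runif(length(base_S), 1 - amplitude, 1 + amplitude),
                    nrow(base_S), ncol(base_S)))
  runs <- c(list(mcr_als_solve(jm, k = k, ...)),
            lapply(perturb, function(S0)
              mcr_als_solve(jm, k = k, init_S = S0, ...)))
  lofs <- vapply(runs, function(r) r$lack_of_fit, numeric(1))
  best <- runs[[which.min(lofs)]]
  keep <- lofs <= min(lofs) * (1 + keep_rel)
  kept <- runs[keep]
  # component matching to the best solution by profile correlation
  aligned_C <- lapply(kept, function(r) {
    perm <- match_components(best$C, r$C)
    r$C[, perm, drop = FALSE]
  })
  aligned_S <- lapply(kept, function(r) {
    perm <- match_components(best$C, r$C)
    r$S[, perm, drop = FALSE]
  })
  pmin_all <- function(lst) Reduce(pmin, lst)
  pmax_all <- function(lst) Reduce(pmax, lst)
  list(best = best,
       C_lower = pmin_all(aligned_C), C_upper = pmax_all(aligned_C),
       S_lower = pmin_all(aligned_S), S_upper = pmax_all(aligned_S),
       n_kept = sum(keep))
}

# greedy correlation matching of columns of B to columns of A
match_components <- function(A, B) {
  k <- ncol(A)
  cors <- abs(stats::cor(A, B))
  cors[!is.finite(cors)] <- 0
  perm <- integer(k)
  for (step in seq_len(k)) {
    best <- which(cors == max(cors), arr.ind = TRUE)[1, ]
    perm[best[1]] <- best[2]
    cors[best[1], ] <- -Inf
    cors[, best[2]] <- -Inf
  }
  perm
}

#' Pearson correlation map between components and signals
#'
#' Each named signal (fitted-parameter traces, ThT, turbidity, ...) is
#' min-max normalised, linearly resampled onto the concentration-profile
#' time grid, and truncated to the overlapping interval; the Pearson
#' correlation of every (component, signal) pair over matched time points
#' is returned. Min-max normalisation does not change |r| or its sign; it
#' mirrors how the signals are prepared for the bubble-map display. A
#' constant signal has undefined correlation and is reported as NA with a
#' warning.
#'
#' @param C concentration matrix (times x k) or an `mcr_result`.
#' @param signals named list of [kinetic_trace()] objects or numeric
#'   vectors already on the C grid.
#' @param time_min time grid of C (taken from the `mcr_result` if given).
#' @return k x length(signals) matrix of Pearson r, rownames `C1..Ck`.
#' @export
correlation_map <- function(C, signals, time_min = NULL) {
  if (inherits(C, "mcr_result")) {
    time_min <- C$time_min
    C <- C$C
  }
  stopifnot(!is.null(time_min), nrow(C) == length(time_min))
  if (length(time_min) < 3) stop("need >= 3 matched time points")
  out <- matrix(NA_real_, ncol(C), length(signals),
                dimnames = list(paste0("C", seq_len(ncol(C))), names(signals)))
  for (j in seq_along(signals)) {
    s <- signals[[j]]
    if (inherits(s, "kinetic_trace")) {
      keep <- time_min >= min(s$time_min) & time_min <= max(s$time_min)
      v <- rep(NA_real_, length(time_min))
      v[keep] <- stats::approx(s$time_min, s$value, xout = time_min[keep])$y
    } else v <- as.numeric(s)
    ok <- !is.na(v)
    if (sum(ok) < 3) { warning("signal ", names(signals)[j], ": too few matched points"); next }
    rng <- range(v[ok])
    if (diff(rng) == 0) {
      warning("signal ", names(signals)[j], " is constant; r undefined")
      next
    }
    v[ok] <- (v[ok] - rng[1]) / diff(rng)
    for (i in seq_len(ncol(C)))
      out[i, j] <- stats::cor(C[ok, i], v[ok])
  }
  out
}
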