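# Independent oracles used across tests.

# DBSCAN oracle: a graph formulation independent of the queue-expansion
# implementation. Core points are vertices of a graph with edges between
# cores within eps; clusters are its connected components; each border
# point joins the component of a core within eps; everything else is
# noise. Requires igraph.
dbscan_oracle <- function(points, eps, min_samples) {
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))
  core <- vapply(seq_len(n), function(i) sum(d[i, ] <= eps) >= min_samples,
                 logical(1))
  labels <- rep(-1L, n)
  ci <- which(core)
  if (!length(ci)) return(labels)
  adj <- d[ci, ci, drop = FALSE] <= eps
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  labels[ci] <- comp
  for (i in which(!core)) {
    near <- ci[d[i, ci] <= eps]
    if (length(near)) labels[i] <- labels[near[1]]
  }
  labels
}

# TRUE when two labelings define the same partition (noise = -1 must
# match exactly; cluster ids may be permuted)
same_partition <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  if (!identical(a == -1L, b == -1L)) return(FALSE)
  ok <- a != -1L
  length(unique(paste(a[ok], b[ok]))) == length(unique(a[ok])) &&
    length(unique(a[ok])) == length(unique(b[ok]))
}

# well-separated Gaussian blobs + sprinkled noise in dim dimensions
make_blobs <- function(seed, n_blobs = 3, dim = 8, per = 12, sep = 12,
                       sd = 0.4, n_noise = 4) {
  set.seed(seed)
  centers <- matrix(stats::rnorm(n_blobs * dim), n_blobs) * sep
  pts <- do.call(rbind, lapply(seq_len(n_blobs), function(k)
    sweep(matrix(stats::rnorm(per * dim, 0, sd), per), 2, centers[k, ], "+")))
  if (n_noise > 0)
    pts <- rbind(pts, matrix(stats::runif(n_noise * dim, 40, 80),
                             nrow = n_noise, ncol = dim))
  pts
}

# noiseless logistic trace
logistic_trace <- function(t, baseline, A, t_m, tau)
  kinetic_trace(t, baseline + A / (1 + exp(-(t - t_m) / tau)), kind = "tht")

# reference synthetic sample, generated once per test run
reference_sample <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_sample(seed = 1)
    cache
  }
})

reference_trajectory <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- fit_series(reference_sample()$sans)
    cache
  }
})
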