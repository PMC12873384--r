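test_that("z-scoring standardises the eight-parameter set and handles degeneracy", {
  tab <- data.frame(time_min = c(10, 20), a = c(1, 3), n = c(2, 4), c = c(1, 2),
                    eta = c(50, 70), m = c(2, 3), d = c(0.1, 0.3),
                    q0 = c(0.015, 0.017), sigma = c(0.003, 0.004), b = 1,
                    d_star = 1, residual_norm = 0, converged = TRUE)
  z <- zscore_matrix(tab)
  # two frames: every (increasing) column becomes -1, +1
  expect_equal(unname(z[1, ]), rep(-1, 8), tolerance = 1e-12)
  expect_equal(unname(z[2, ]), rep(1, 8), tolerance = 1e-12)
  expect_false("b" %in% colnames(z))

  tab3 <- rbind(tab, tab[2, ]); tab3$time_min <- c(10, 20, 30)
  tab3$sigma <- 0.003  # zero-variance column
  expect_warning(z3 <- zscore_matrix(tab3), "zero-variance")
  expect_equal(unname(z3[, "sigma"]), c(0, 0, 0))
  expect_lt(max(abs(colMeans(z3))), 1e-12)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  sds <- apply(z3, 2, pop_sd)
  expect_equal(unname(sds[names(sds) != "sigma"]), rep(1, 7))
})

test_that("DBSCAN separates blobs, marks sparse points noise, matches the graph oracle", {
  skip_if_not_installed("igraph")
  set.seed(5)
  # two tight 10-point blobs far apart: exactly 2 clusters, no noise
  b1 <- matrix(rnorm(20, 0, 0.1), 10); b2 <- matrix(rnorm(20, 10, 0.1), 10)
  ids <- dbscan_cluster(rbind(b1, b2), eps = 1, min_samples = 5)
  expect_equal(length(unique(ids)), 2)
  expect_false(any(ids == -1))
  expect_equal(length(unique(ids[1:10])), 1)

  # fewer points than min_samples: all noise
  expect_equal(dbscan_cluster(matrix(rnorm(8, 0, 30), 4), 1, 5), rep(-1L, 4))

  # oracle equivalence on seeded 8-D point sets
  for (s in 1:10) {
    pts <- make_blobs(seed = 900 + s, n_blobs = sample(2:4, 1))
    ids <- dbscan_cluster(pts, eps = 3, min_samples = 5)
    expect_true(same_partition(ids, dbscan_oracle(pts, 3, 5)))
  }
})

test_that("DBSCAN partitions are invariant to point order", {
  pts <- make_blobs(seed = 77)
  base <- dbscan_cluster(pts, eps = 3, min_samples = 5)
  for (s in 1:5) {
    set.seed(s)
    perm <- sample(nrow(pts))
    shuffled <- dbscan_cluster(pts[perm, ], eps = 3, min_samples = 5)
    expect_true(same_partition(base[perm], shuffled))
  }
})

test_that("phase assignment orders clusters by median time with demotion rules", {
  ids <- rep(0:3, each = 10)
  times <- c(1:10, 101:110, 251:260, 401:410)
  lab <- assign_phases(ids, times)
  expect_equal(as.character(unique(lab)),
               c("Initiation", "Pre-assembly", "NetworkAssembly", "Maturation"))
  # cluster ids shuffled in time: labels follow median time, not id
  lab2 <- assign_phases(rep(c(2, 0, 3, 1), each = 10), times)
  expect_identical(lab, lab2)

  # two clusters only: earliest labels used, warning
  expect_warning(l2 <- assign_phases(rep(0:1, each = 10), times[1:20]), "2 cluster")
  expect_setequal(as.character(unique(l2)), c("Initiation", "Pre-assembly"))

  # five clusters: smallest demoted to noise
  ids5 <- c(rep(0:3, each = 10), rep(4, 3))
  t5 <- c(times, 501:503)
  expect_warning(l5 <- assign_phases(ids5, t5), "demoted")
  expect_equal(as.character(unique(l5[ids5 == 4])), "Noise")

  expect_error(assign_phases(rep(-1L, 5), 1:5), "noise")
})

test_that("hull volumes match closed-form geometry and sum to 100%", {
  # unit-cube corners (volume 1) vs regular tetrahedron edge 1
  # (volume 1/(6 sqrt(2))): shares 89.45% / 10.55%
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1)) + 50
  tet <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
               c(0.5, sqrt(3) / 6, sqrt(2 / 3)))
  z <- rbind(cube, tet)
  colnames(z) <- c("n", "m", "d")
  labels <- factor(rep(c("Initiation", "Pre-assembly"), c(8, 4)),
                   levels = c(silkgel:::PHASE_LEVELS, "Noise"))
  hv <- hull_volumes(z, labels)
  expect_equal(hv$volume, c(1, 1 / (6 * sqrt(2))), tolerance = 1e-12)
  vtet <- 1 / (6 * sqrt(2))
  expect_equal(hv$volume_pct, 100 * c(1, vtet) / (1 + vtet), tolerance = 1e-8)
  expect_equal(sum(hv$volume_pct), 100)

  # single phase: 100%; coplanar phase: volume 0
  cube_named <- cube; colnames(cube_named) <- c("n", "m", "d")
  hv1 <- hull_volumes(cube_named, factor(rep("Initiation", 8),
                                         levels = levels(labels)))
  expect_equal(hv1$volume_pct, 100)
  flat <- rbind(cube, cbind(tet[, 1:2] + 30, 0))
  colnames(flat) <- c("n", "m", "d")
  hvf <- hull_volumes(flat, labels)
  expect_equal(hvf$volume[2], 0)
  flat2 <- cbind(flat[, 1:2], 0); colnames(flat2) <- c("n", "m", "d")
  expect_error(hull_volumes(flat2, labels), "degenerate")
})

test_that("phase statistics use population sd and match a groupby oracle", {
  tab <- data.frame(time_min = 1:5, eta = c(40, 60, 100, 100, 100),
                    d_star = c(300, 350, 200, 210, 190))
  lab <- factor(c("Initiation", "Initiation", "Maturation", "Maturation",
                  "Maturation"), levels = c(silkgel:::PHASE_LEVELS, "Noise"))
  st <- phase_statistics(tab, lab)
  expect_equal(st$eta_mean[st$phase == "Initiation"], 50)
  expect_equal(st$eta_sd[st$phase == "Initiation"], 10)  # population sd

  # single-member phase reports sd = 0
  lab1 <- factor(c("Initiation", rep("Maturation", 4)),
                 levels = levels(lab))
  st1 <- phase_statistics(tab, lab1)
  expect_equal(st1$eta_sd[st1$phase == "Initiation"], 0)

  # independent aggregation oracle on seeded draws
  set.seed(31)
  tt <- data.frame(time_min = 1:40, eta = rnorm(40, 60, 10),
                   d_star = rnorm(40, 300, 30))
  ll <- factor(sample(c("Initiation", "Pre-assembly"), 40, TRUE),
               levels = levels(lab))
  st2 <- phase_statistics(tt, ll)
  agg <- tapply(tt$eta, droplevels(ll), mean)
  expect_equal(st2$eta_mean, as.numeric(agg[as.character(st2$phase)]),
               tolerance = 1e-12)
  psd <- tapply(tt$d_star, droplevels(ll),
                function(x) sqrt(mean((x - mean(x))^2)))
  expect_equal(st2$dstar_sd, as.numeric(psd[as.character(st2$phase)]),
               tolerance = 1e-12)
})

test_that("hull volume agrees with a quickhull oracle on random clouds", {
  # scipy.spatial.ConvexHull through the system python as an independent
  # geometric oracle
  py <- Sys.which("python3")
  skip_if(py == "", "python3 unavailable")
  tmp <- withr::local_tempfile(fileext = ".csv")
  set.seed(12)
  for (i in 1:3) {
    pts <- matrix(rnorm(3 * sample(15:50, 1)), ncol = 3)
    utils::write.csv(pts, tmp, row.names = FALSE)
    out <- system2(py, c("-c", shQuote(sprintf(
      "import numpy, scipy.spatial; p = numpy.loadtxt('%s', delimiter=',', skiprows=1); print(repr(scipy.spatial.ConvexHull(p).volume))",
      tmp))), stdout = TRUE)
    expect_equal(convex_hull_volume(pts), as.numeric(out), tolerance = 1e-10)
  }
})
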