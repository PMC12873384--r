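# 3-D convex hull volume by randomized incremental construction
# (beneath-beyond). Only the volume is needed (phase-envelope sizes), not
# the facet structure, so the implementation keeps a triangle soup and
# re-fans coplanar regions as points arrive. Degenerate inputs (fewer than
# 4 points, or affine rank < 3) have volume 0 by convention.

#' Volume of the 3-D convex hull of a point set
#'
#' @param pts numeric matrix with 3 columns, one row per point.
#' @param tol coplanarity tolerance, relative to the cloud scale.
#' @return hull volume (0 for degenerate sets).
#' @export
convex_hull_volume <- function(pts, tol = 1e-9) {
  pts <- unique(as.matrix(pts))
  if (ncol(pts) != 3) stop("convex_hull_volume expects 3 columns")
  n <- nrow(pts)
  if (n < 4) return(0)
  ctr <- colMeans(pts)
  scale <- max(sqrt(rowSums(sweep(pts, 2, ctr)^2)), 1e-12)
  eps <- tol * scale^3 * 6  # threshold on signed tetra volume (6V)
  # affine rank check
  sv <- svd(sweep(pts, 2, ctr))$d
  if (length(sv) < 3 || sv[3] <= 1e-10 * sv[1]) return(0)

  det3 <- function(a, b, c) {
    a[1] * (b[2] * c[3] - b[3] * c[2]) -
    a[2] * (b[1] * c[3] - b[3] * c[1]) +
    a[3] * (b[1] * c[2] - b[2] * c[1])
  }
  # signed 6*volume of tetra (p1,p2,p3,p4)
  orient <- function(p1, p2, p3, p4) det3(p2 - p1, p3 - p1, p4 - p1)

  # initial non-degenerate tetrahedron
  i1 <- 1L
  i2 <- which.max(rowSums(sweep(pts, 2, pts[i1, ])^2))
  d12 <- pts[i2, ] - pts[i1, ]
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  a3 <- apply(pts, 1L, function(p) sum(cr(d12, p - pts[i1, ])^2))
  i3 <- which.max(a3)
  v4 <- apply(pts, 1L, function(p) abs(orient(pts[i1, ], pts[i2, ], pts[i3, ], p)))
  i4 <- which.max(v4)
  if (v4[i4] <= eps) return(0)
  base <- c(i1, i2, i3, i4)
  # orient the 4 faces outward w.r.t. the tetra centroid
  tc <- colMeans(pts[base, ])
  faces <- list(c(i1, i2, i3), c(i1, i2, i4), c(i1, i3, i4), c(i2, i3, i4))
  faces <- lapply(faces, function(f) {
    if (orient(pts[f[1], ], pts[f[2], ], pts[f[3], ], tc) > 0) f[c(1, 3, 2)] else f
  })

  rest <- setdiff(seq_len(n), base)
  for (p in rest) {
    pp <- pts[p, ]
    vis <- vapply(faces, function(f)
      orient(pts[f[1], ], pts[f[2], ], pts[f[3], ], pp) > eps, logical(1))
    # points on a face plane: treat as visible from that face too, so
    # coplanar exterior points re-triangulate the face correctly
    onp <- vapply(faces, function(f) {
      o <- orient(pts[f[1], ], pts[f[2], ], pts[f[3], ], pp)
      o > -eps & o <= eps
    }, logical(1))
    if (!any(vis)) next            # interior (or on-hull) point
    vis <- vis | onp
    # horizon: edges shared by exactly one visible face
    edges <- new.env(parent = emptyenv())
    for (f in faces[vis]) {
      for (e in list(f[c(1, 2)], f[c(2, 3)], f[c(3, 1)])) {
        key <- paste(sort(e), collapse = "_")
        cur <- if (!is.null(edges[[key]])) edges[[key]] else NULL
        edges[[key]] <- if (is.null(cur)) e else NA  # shared twice -> drop
      }
    }
    faces <- faces[!vis]
    for (key in ls(edges)) {
      e <- edges[[key]]
      if (length(e) == 1 && is.na(e)) next
      faces[[length(faces) + 1L]] <- c(e[1], e[2], p)
    }
  }
  # volume via divergence theorem over outward-oriented triangles
  v6 <- 0
  o <- colMeans(pts)
  for (f in faces)
    v6 <- v6 + orient(o, pts[f[1], ], pts[f[2], ], pts[f[3], ])
  abs(v6) / 6
}
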