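#' Volume of the 3D convex hull of a point set
#'
#' Incremental (beneath-beyond) convex hull. Points are added one by one;
#' faces visible from a new point are removed and the horizon is re-capped.
#' Adequate and exact (to floating point) for the point counts digitized or
#' simulated root systems produce.
#'
#' @param pts numeric matrix (n x 3), cm (or any consistent unit).
#' @param tol coplanarity tolerance relative to the cloud extent.
#' @return hull volume in the cube of the input unit; 0 (with attribute
#'   `degenerate = TRUE`) if fewer than 4 non-coplanar points exist.
#' @export
convex_hull_volume <- function(pts, tol = 1e-10) {
  pts <- unique(as.matrix(pts))
  storage.mode(pts) <- "double"
  if (nrow(pts) < 4L) return(structure(0, degenerate = TRUE))
  scale <- max(apply(pts, 2L, function(v) diff(range(v))), 1e-300)
  eps <- tol * scale^3  # signed-volume threshold

  tetra_vol6 <- function(a, b, c, d)
    sum(cross3(b - a, c - a) * (d - a))

  # initial tetrahedron: two extreme points, then max-area, then max-volume
  i1 <- which.min(pts[, 1]); i2 <- which.max(pts[, 1])
  if (i1 == i2) i2 <- which.max(rowSums(sweep(pts, 2, pts[i1, ])^2))
  if (i1 == i2) return(structure(0, degenerate = TRUE))
  ab <- pts[i2, ] - pts[i1, ]
  area2 <- apply(pts, 1L, function(p) sum(cross3(ab, p - pts[i1, ])^2))
  i3 <- which.max(area2)
  if (sqrt(area2[i3]) <= eps / scale) return(structure(0, degenerate = TRUE))
  v6 <- apply(pts, 1L, function(p)
    tetra_vol6(pts[i1, ], pts[i2, ], pts[i3, ], p))
  i4 <- which.max(abs(v6))
  if (abs(v6[i4]) <= eps) return(structure(0, degenerate = TRUE))
  init <- c(i1, i2, i3, i4)
  centroid <- colMeans(pts[init, ])
  faces <- list(init[c(1, 2, 3)], init[c(1, 4, 2)],
                init[c(2, 4, 3)], init[c(1, 3, 4)])
  faces <- lapply(faces, function(f) {  # orient normals away from centroid
    a <- pts[f[1], ]
    nrm <- cross3(pts[f[2], ] - a, pts[f[3], ] - a)
    if (sum(nrm * (centroid - a)) > 0) f[c(1, 3, 2)] else f
  })

  visible <- function(f, p) {
    a <- pts[f[1], ]; nrm <- cross3(pts[f[2], ] - a, pts[f[3], ] - a)
    sum(nrm * (p - a)) > eps
  }
  for (k in setdiff(seq_len(nrow(pts)), init)) {
    p <- pts[k, ]
    vis <- vapply(faces, visible, logical(1), p = p)
    if (!any(vis)) next
    # horizon: edges of visible faces not shared with another visible face
    edge_key <- function(a, b) paste(min(a, b), max(a, b))
    counts <- new.env(parent = emptyenv())
    edges <- list()
    for (f in faces[vis]) {
      for (e in list(f[c(1, 2)], f[c(2, 3)], f[c(3, 1)])) {
        key <- edge_key(e[1], e[2])
        cnt <- get0(key, envir = counts, ifnotfound = 0L)
        assign(key, cnt + 1L, envir = counts)
        edges[[length(edges) + 1L]] <- e
      }
    }
    horizon <- Filter(function(e)
      get(edge_key(e[1], e[2]), envir = counts) == 1L, edges)
    faces <- faces[!vis]
    for (e in horizon) {
      f <- c(e[1], e[2], k)
      # orient outward w.r.t. interior centroid
      a <- pts[f[1], ]
      nrm <- cross3(pts[f[2], ] - a, pts[f[3], ] - a)
      if (sum(nrm * (centroid - a)) > 0) f <- f[c(1, 3, 2)]
      faces[[length(faces) + 1L]] <- f
    }
  }
  vol <- sum(vapply(faces, function(f)
    tetra_vol6(centroid, pts[f[1], ], pts[f[2], ], pts[f[3], ]),
    numeric(1))) / 6
  abs(vol)
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Area of the 2D convex hull of projected points
#'
#' @param xy numeric matrix (n x 2).
#' @return hull area (unit squared); 0 if degenerate.
#' @export
convex_hull_area <- function(xy) {
  xy <- unique(as.matrix(xy))
  if (nrow(xy) < 3L) return(0)
  h <- grDevices::chull(xy)
  v <- xy[h, , drop = FALSE]
  n <- nrow(v)
  if (n < 3L) return(0)
  j <- c(2:n, 1L)
  abs(sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2])) / 2
}
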