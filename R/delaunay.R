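## Bowyer-Watson Delaunay triangulation in 2-D, used by the grid
## interpolation of projected gradient fields. Desk-scale (hundreds to a
## few thousand points); O(n^2) incremental insertion is plenty.

circumcircle <- function(a, b, c) {
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) +
            c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) {
    return(list(center = c(Inf, Inf), r2 = Inf))
  }
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  list(center = c(ux, uy), r2 = (a[1] - ux)^2 + (a[2] - uy)^2)
}

# Returns an m x 3 matrix of point indices (rows of `pts`) forming the
# Delaunay triangles. Errors if all points are collinear.
delaunayTriangulation <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3) stop("need at least 3 points to triangulate")
  span <- max(apply(pts, 2, function(x) diff(range(x))), 1e-9)
  mid <- colMeans(apply(pts, 2, range))
  # super-triangle comfortably containing all points
  sup <- rbind(mid + c(-20 * span, -10 * span),
               mid + c(20 * span, -10 * span),
               mid + c(0, 20 * span))
  P <- rbind(pts, sup)
  tris <- list(c(n + 1L, n + 2L, n + 3L))
  circ <- list(circumcircle(sup[1, ], sup[2, ], sup[3, ]))
  for (ip in seq_len(n)) {
    p <- P[ip, ]
    bad <- vapply(circ, function(cc) {
      sum((p - cc$center)^2) <= cc$r2 * (1 + 1e-10)
    }, logical(1))
    if (!any(bad)) next  # numerically degenerate; skip (duplicate point)
    # boundary polygon: edges of bad triangles that appear exactly once
    edges <- do.call(rbind, lapply(tris[bad], function(t) {
      rbind(sort(c(t[1], t[2])), sort(c(t[2], t[3])), sort(c(t[3], t[1])))
    }))
    key <- paste(edges[, 1], edges[, 2])
    keep <- key %in% names(which(table(key) == 1))
    poly <- edges[keep, , drop = FALSE]
    tris <- tris[!bad]
    circ <- circ[!bad]
    for (ie in seq_len(nrow(poly))) {
      tri <- c(poly[ie, 1], poly[ie, 2], ip)
      tris[[length(tris) + 1]] <- tri
      circ[[length(circ) + 1]] <-
        circumcircle(P[tri[1], ], P[tri[2], ], P[tri[3], ])
    }
  }
  out <- do.call(rbind, tris)
  out <- out[apply(out <= n, 1, all), , drop = FALSE]
  if (!nrow(out)) stop("all points collinear: cannot triangulate")
  out
}

# Barycentric coordinates of point p in triangle (v1, v2, v3); returns
# c(l1, l2, l3) or NULL for a degenerate triangle.
baryCoords <- function(p, v1, v2, v3) {
  det <- (v2[2] - v3[2]) * (v1[1] - v3[1]) +
    (v3[1] - v2[1]) * (v1[2] - v3[2])
  if (abs(det) < 1e-14) return(NULL)
  l1 <- ((v2[2] - v3[2]) * (p[1] - v3[1]) +
         (v3[1] - v2[1]) * (p[2] - v3[2])) / det
  l2 <- ((v3[2] - v1[2]) * (p[1] - v3[1]) +
         (v1[1] - v3[1]) * (p[2] - v3[2])) / det
  c(l1, l2, 1 - l1 - l2)
}

# Piecewise-linear interpolation of `values` (one column per component,
# rows matching `pts`) at query points; NA outside the triangulation.
baryInterpolate <- function(pts, values, queries, tris = NULL) {
  pts <- as.matrix(pts)
  values <- as.matrix(values)
  queries <- as.matrix(queries)
  if (is.null(tris)) tris <- delaunayTriangulation(pts)
  out <- matrix(NA_real_, nrow(queries), ncol(values))
  for (iq in seq_len(nrow(queries))) {
    p <- queries[iq, ]
    for (it in seq_len(nrow(tris))) {
      tri <- tris[it, ]
      l <- baryCoords(p, pts[tri[1], ], pts[tri[2], ], pts[tri[3], ])
      if (is.null(l)) next
      if (all(l >= -1e-9)) {
        out[iq, ] <- drop(l %*% values[tri, , drop = FALSE])
        break
      }
    }
  }
  out
}
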