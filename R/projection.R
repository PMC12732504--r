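## 2-D projection of gradient fields: linear (PCA, gradients map through
## the same linear operator) and nonlinear (UMAP of perturbed endpoints).

#' Project a gradient field onto its top-2 principal axes
#'
#' Fits a PCA on `fitOn` (typically the training latent embeddings) and
#' projects the field's points affinely onto the first two principal
#' axes. Gradient vectors are multiplied by the same linear map without
#' centering, so projection is exactly linear in the vectors:
#' `project(alpha * u + v) = alpha * project(u) + project(v)`. The sign of
#' each axis follows the convention that its largest-magnitude loading is
#' positive, making the projection deterministic.
#'
#' @param field A [GradientField-class].
#' @param fitOn Matrix of latent points the PCA is fitted on (>= 2 rows).
#' @return A [Projection2D-class] with `method = "pca"`.
#' @export
projectGradientsPCA <- function(field, fitOn) {
  fitOn <- as.matrix(fitOn)
  if (nrow(fitOn) < 2) stop("need at least 2 points to fit a PCA")
  pc <- prcomp(fitOn, center = TRUE, scale. = FALSE)
  if (length(pc$sdev) < 2 || pc$sdev[2] < 1e-12) {
    stop("degenerate covariance: rank < 2")
  }
  rot <- pc$rotation[, 1:2, drop = FALSE]
  for (j in 1:2) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  pts <- sweep(field@points, 2, pc$center) %*% rot
  vec <- field@vectors %*% rot
  new("Projection2D", method = "pca", points = pts, vectors = vec,
      projector = list(rotation = rot, center = pc$center))
}

#' Interpolate a projected vector field onto a regular grid
#'
#' Linear barycentric interpolation (over a Delaunay triangulation of the
#' projected points) of each vector component onto a `resolution` x
#' `resolution` lattice spanning the bounding box of the points. Lattice
#' nodes outside the convex hull are `NA`. Piecewise-linear interpolation
#' reproduces affine fields exactly on interior nodes.
#'
#' @param proj A [Projection2D-class].
#' @param resolution Lattice nodes per axis.
#' @return List with vectors `x`, `y` (lattice axes) and matrices `u`,
#'   `v` (vector components, rows indexing `x`).
#' @export
gridInterpolate <- function(proj, resolution = 20) {
  pts <- proj@points
  if (nrow(pts) < 3) stop("need at least 3 points")
  tris <- delaunayTriangulation(pts)  # errors when all collinear
  xs <- seq(min(pts[, 1]), max(pts[, 1]), length.out = resolution)
  ys <- seq(min(pts[, 2]), max(pts[, 2]), length.out = resolution)
  grid <- as.matrix(expand.grid(x = xs, y = ys))
  vals <- baryInterpolate(pts, proj@vectors, grid, tris)
  list(x = xs, y = ys,
       u = matrix(vals[, 1], resolution, resolution),
       v = matrix(vals[, 2], resolution, resolution))
}

#' Project a gradient field through a joint UMAP of perturbed endpoints
#'
#' Perturbed endpoints `z + deltaDisplay * grad` are appended to the
#' observed latents and a joint 2-D UMAP is fitted on the concatenation
#' (through the bundled python/umap-learn bridge, seeded). The displayed
#' vector of each field point is the difference between the embedded
#' endpoint and the embedded origin. `deltaDisplay` defaults to the total
#' displacement of the default knockdown flow (step size -0.001 times 400
#' steps); per-step displacements vanish visually.
#'
#' @param model An [NBVAE-class] model (unused numerically; kept so the
#'   signature mirrors the other projections and future encoders can
#'   re-encode endpoints).
#' @param latents Observed latent embeddings (rows).
#' @param field A [GradientField-class] whose points lie in the same
#'   latent space.
#' @param deltaDisplay Signed display step size; 0 yields zero vectors
#'   (with a warning).
#' @param seed Integer seed passed to UMAP.
#' @param nNeighbors,minDist UMAP hyperparameters.
#' @return A [Projection2D-class] with `method = "umap_endpoint"`; the
#'   projector records the embedded background latents.
#' @export
projectGradientsUMAP <- function(model, latents, field, deltaDisplay = -0.4,
                                 seed = 1, nNeighbors = 15,
                                 minDist = 0.1) {
  latents <- as.matrix(latents)
  origins <- field@points
  if (deltaDisplay == 0) {
    warning("deltaDisplay = 0: all displayed vectors are zero")
  }
  endpoints <- origins + deltaDisplay * field@vectors
  X <- rbind(latents, origins, endpoints)
  inFile <- tempfile("umap_in_", fileext = ".tsv")
  outFile <- tempfile("umap_out_", fileext = ".tsv")
  on.exit(unlink(c(inFile, outFile)), add = TRUE)
  write.table(X, inFile, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  runPythonScript("umap_embed.py",
                  c(inFile, outFile, seed, nNeighbors, minDist))
  emb <- as.matrix(read.delim(outFile, header = FALSE))
  nL <- nrow(latents); nF <- nrow(origins)
  embOrig <- emb[nL + seq_len(nF), , drop = FALSE]
  embEnd <- emb[nL + nF + seq_len(nF), , drop = FALSE]
  vec <- if (deltaDisplay == 0) matrix(0, nF, 2) else embEnd - embOrig
  new("Projection2D", method = "umap_endpoint", points = embOrig,
      vectors = vec,
      projector = list(background = emb[seq_len(nL), , drop = FALSE],
                       seed = seed, nNeighbors = nNeighbors,
                       minDist = minDist, deltaDisplay = deltaDisplay))
}
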