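randomField <- function(n, d, seed = 1) {
  set.seed(seed)
  new("GradientField", points = matrix(rnorm(n * d), n, d),
      vectors = matrix(rnorm(n * d), n, d), outputName = "x",
      mask = logical(0))
}

test_that("PCA projection of an axis-aligned 2-D field is the identity", {
  # exactly diagonal covariance with distinct axis variances: the
  # principal axes are the coordinate axes, and the sign convention
  # makes the rotation the identity
  pts <- rbind(c(3, 0), c(-3, 0), c(0, 1), c(0, -1))
  field <- new("GradientField", points = pts, vectors = pts * 0.5,
               outputName = "x", mask = logical(0))
  proj <- projectGradientsPCA(field, pts)
  expect_equal(proj@points, pts, tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(proj@vectors, pts * 0.5, tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("PCA projection is exactly linear in the vectors", {
  field <- randomField(30, 5, seed = 3)
  proj <- projectGradientsPCA(field, field@points)
  R <- proj@projector$rotation
  u <- rnorm(5); v <- rnorm(5); al <- 2.7
  expect_equal(drop((al * u + v) %*% R),
               al * drop(u %*% R) + drop(v %*% R), tolerance = 1e-12)
  expect_equal(proj@vectors, field@vectors %*% R)
})

test_that("gradients orthogonal to the principal plane project to zero", {
  set.seed(4)
  pts <- cbind(matrix(rnorm(100 * 2), 100, 2), 0)  # variance in dims 1-2
  field <- new("GradientField", points = pts,
               vectors = matrix(rep(c(0, 0, 1), 100), 100, 3,
                                byrow = TRUE),
               outputName = "x", mask = logical(0))
  proj <- projectGradientsPCA(field, pts)
  expect_equal(max(abs(proj@vectors)), 0, tolerance = 1e-10)
  # degenerate rank-1 cloud is rejected
  rank1 <- outer(rnorm(50), c(1, 2, 3))
  expect_error(projectGradientsPCA(field, rank1), "rank < 2")
})

test_that("projected vectors equal endpoint differences of small steps", {
  field <- randomField(40, 6, seed = 5)
  proj <- projectGradientsPCA(field, field@points)
  h <- 1e-6
  shifted <- field
  shifted@points <- field@points + h * field@vectors
  projShift <- projectGradientsPCA(shifted, field@points)
  expect_equal((projShift@points - proj@points) / h, proj@vectors,
               tolerance = 1e-6)
})

test_that("Delaunay triangulation satisfies the empty-circumcircle property", {
  set.seed(6)
  pts <- matrix(runif(60), 30, 2)
  tris <- perturbflow:::delaunayTriangulation(pts)
  for (it in seq_len(nrow(tris))) {
    cc <- perturbflow:::circumcircle(pts[tris[it, 1], ],
                                     pts[tris[it, 2], ],
                                     pts[tris[it, 3], ])
    inside <- rowSums(sweep(pts, 2, cc$center)^2) < cc$r2 * (1 - 1e-9)
    inside[tris[it, ]] <- FALSE
    expect_false(any(inside))
  }
})

test_that("grid interpolation reproduces constant and linear fields", {
  set.seed(7)
  pts <- rbind(matrix(runif(40, -1, 1), 20, 2),
               c(-1, -1), c(1, -1), c(1, 1), c(-1, 1))
  constF <- new("GradientField", points = cbind(pts, 0 * pts)[, 1:2],
                vectors = matrix(rep(c(2, -1), nrow(pts)), ncol = 2,
                                 byrow = TRUE),
                outputName = "x", mask = logical(0))
  # identity projection: latent already 2-D
  proj <- new("Projection2D", method = "pca", points = pts,
              vectors = constF@vectors, projector = list())
  grid <- gridInterpolate(proj, resolution = 8)
  inside <- !is.na(grid$u)
  expect_true(any(inside))
  expect_equal(unique(round(grid$u[inside], 9)), 2)
  expect_equal(unique(round(grid$v[inside], 9)), -1)

  A <- matrix(c(1, 2, -0.5, 0.3), 2, 2)
  linVec <- pts %*% A
  projLin <- new("Projection2D", method = "pca", points = pts,
                 vectors = linVec, projector = list())
  gridLin <- gridInterpolate(projLin, resolution = 8)
  nodes <- as.matrix(expand.grid(gridLin$x, gridLin$y))
  expected <- nodes %*% A
  ok <- !is.na(gridLin$u)
  expect_equal(gridLin$u[ok], matrix(expected[, 1], 8, 8)[ok],
               tolerance = 1e-8)
  expect_equal(gridLin$v[ok], matrix(expected[, 2], 8, 8)[ok],
               tolerance = 1e-8)
})

test_that("grid interpolation matches an independent barycentric oracle", {
  set.seed(8)
  pts <- matrix(runif(50), 25, 2)
  vecs <- matrix(rnorm(50), 25, 2)
  proj <- new("Projection2D", method = "pca", points = pts,
              vectors = vecs, projector = list())
  grid <- gridInterpolate(proj, resolution = 6)
  tris <- perturbflow:::delaunayTriangulation(pts)
  nodes <- as.matrix(expand.grid(grid$x, grid$y))
  # independent oracle: solve the 3x3 barycentric system per triangle
  oracle <- function(p) {
    for (it in seq_len(nrow(tris))) {
      V <- pts[tris[it, ], ]
      M <- rbind(t(V), c(1, 1, 1))
      l <- tryCatch(solve(M, c(p, 1)), error = function(e) NULL)
      if (!is.null(l) && all(l >= -1e-9)) {
        return(drop(l %*% vecs[tris[it, ], ]))
      }
    }
    c(NA_real_, NA_real_)
  }
  for (i in seq_len(nrow(nodes))) {
    exp_uv <- oracle(nodes[i, ])
    got <- c(grid$u[i], grid$v[i])
    if (anyNA(exp_uv)) {
      expect_true(anyNA(got))
    } else {
      expect_equal(got, exp_uv, tolerance = 1e-8)
    }
  }
  expect_error(gridInterpolate(
    new("Projection2D", method = "pca",
        points = cbind(1:5, 2 * (1:5)), vectors = matrix(0, 5, 2),
        projector = list()), 5), "collinear")
})

test_that("UMAP endpoint projection displays flows toward the target cluster", {
  set.seed(9)
  A <- matrix(rnorm(100 * 4), 100, 4)
  B <- sweep(matrix(rnorm(100 * 4), 100, 4), 2, c(6, 0, 0, 0), "+")
  lat <- rbind(A, B)
  model <- newNBVAE(c("g1", "g2"),
                    nbvaeConfig(latentDim = 4, encoderHidden = c(8),
                                seed = 1))
  field <- new("GradientField", points = A[1:30, ],
               vectors = matrix(rep(c(3, 0, 0, 0), 30), 30, 4,
                                byrow = TRUE),
               outputName = "x", mask = logical(0))
  proj <- projectGradientsUMAP(model, lat, field, deltaDisplay = 1,
                               seed = 3)
  bg <- proj@projector$background
  dirAB <- colMeans(bg[101:200, ]) - colMeans(bg[1:100, ])
  agree <- mean((proj@vectors %*% dirAB) > 0)
  expect_gt(agree, 0.5)
  expect_warning(
    proj0 <- projectGradientsUMAP(model, lat, field, deltaDisplay = 0,
                                  seed = 3),
    "zero")
  expect_equal(max(abs(proj0@vectors)), 0)
})
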