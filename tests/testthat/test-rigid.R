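test_that("identity and pure-translation transforms behave exactly", {
  pts <- matrix(rnorm(30, sd = 40), 10, 3)
  id <- rigid_body_params()
  expect_identical(rigid_body_transform(pts, id), pts)

  sh <- rigid_body_params(translation = c(1, 0, 0))
  out <- rigid_body_transform(pts, sh)
  expect_equal(out[, 1], pts[, 1] + 1)
  expect_equal(out[, 2:3], pts[, 2:3])
})

test_that("rotation matches an explicit rotation-matrix product", {
  # 90 degrees about z at the origin maps (1,0,0) -> (0,1,0)
  p <- rigid_body_params(rotation = c(0, 0, 90))
  expect_equal(rigid_body_transform(c(1, 0, 0), p), c(0, 1, 0), tolerance = 1e-12)

  # general angles against the brute-force matrix product
  set.seed(7)
  for (rep in 1:5) {
    ang <- runif(3, -180, 180)
    Rz <- matrix(c(cos(ang[3] * pi / 180), -sin(ang[3] * pi / 180), 0,
                   sin(ang[3] * pi / 180), cos(ang[3] * pi / 180), 0,
                   0, 0, 1), 3, 3, byrow = TRUE)
    Ry <- matrix(c(cos(ang[2] * pi / 180), 0, sin(ang[2] * pi / 180),
                   0, 1, 0,
                   -sin(ang[2] * pi / 180), 0, cos(ang[2] * pi / 180)), 3, 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0,
                   0, cos(ang[1] * pi / 180), -sin(ang[1] * pi / 180),
                   0, sin(ang[1] * pi / 180), cos(ang[1] * pi / 180)), 3, 3, byrow = TRUE)
    x <- rnorm(3, sd = 30)
    expect_equal(rigid_body_transform(x, rigid_body_params(rotation = ang)),
                 as.numeric(Rx %*% Ry %*% Rz %*% x), tolerance = 1e-10)
  }
})

test_that("rigid transforms are isometries and compose like homogeneous matrices", {
  set.seed(11)
  pts <- matrix(rnorm(60, sd = 50), 20, 3)
  for (rep in 1:10) {
    p1 <- rigid_body_params(rnorm(3, sd = 10), runif(3, -180, 180), rnorm(3, sd = 20))
    p2 <- rigid_body_params(rnorm(3, sd = 10), runif(3, -180, 180), rnorm(3, sd = 20))
    a <- rigid_body_transform(pts, p1)
    # pairwise distances preserved to 1e-9 relative
    expect_equal(as.numeric(dist(a)), as.numeric(dist(pts)), tolerance = 1e-9)
    # sequential transforms match the composed homogeneous matrix
    b <- rigid_body_transform(a, p2)
    M <- homogeneous_matrix(p2) %*% homogeneous_matrix(p1)
    expect_equal(b, apply_homogeneous(M, pts), tolerance = 1e-9)
  }
})

test_that("fiducial sets validate their geometry", {
  expect_error(fiducial_set(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)), "distinct")
  expect_error(fiducial_set(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "collinear")
  f <- fiducial_set(c(0, 90, 0), c(-80, 0, -10), c(80, 0, -10))
  expect_equal(ear_midpoint(f), c(0, 0, -10))
})

test_that("head transforms move mesh and fiducials rigidly together", {
  setup <- tiny_setup(120, 12, 8, 8, smoothing = 0.1)
  mesh <- setup$mesh; fids <- setup$fids

  id <- apply_head_transform(mesh, fids, rigid_body_params())
  expect_identical(id$mesh$vertices, mesh$vertices)
  expect_identical(id$mesh$normals, mesh$normals)

  set.seed(3)
  for (rep in 1:5) {
    p <- rigid_body_params(rnorm(3, sd = 10), runif(3, -30, 30))
    tr <- apply_head_transform(mesh, fids, p)
    # inter-fiducial distances unchanged to 1e-9 mm
    d0 <- sqrt(sum((fids$nasion - fids$left_ear)^2))
    d1 <- sqrt(sum((tr$fiducials$nasion - tr$fiducials$left_ear)^2))
    expect_equal(d1, d0, tolerance = 1e-9)
    # normals rotated only: still unit length, angles to vertex offsets kept
    expect_equal(rowSums(tr$mesh$normals^2), rep(1, nrow(mesh$vertices)),
                 tolerance = 1e-9)
    # triangle areas preserved
    area <- function(m) {
      a <- m$vertices[m$faces[, 1], ]; b <- m$vertices[m$faces[, 2], ]
      cc <- m$vertices[m$faces[, 3], ]
      e1 <- b - a; e2 <- cc - a
      cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                  e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                  e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
      sqrt(rowSums(cr^2)) / 2
    }
    expect_equal(area(tr$mesh), area(mesh), tolerance = 1e-9)
  }
})
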