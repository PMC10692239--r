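# Local frames, Euler/spherical codecs and rigid-transform algebra.

test_that("build_frame matches the axis-aligned case and a brute-force oracle", {
  f <- build_frame(n = c(-0.5, 1.4, 0), ca = c(0, 0, 0), c = c(1.525, 0, 0))
  expect_lt(max(abs(f$R - diag(3))), 1e-12)
  expect_equal(f$t, c(0, 0, 0))

  set.seed(11)
  for (k in 1:50) {
    ca <- runif(3, -10, 10)
    n <- ca + rnorm(3); c <- ca + rnorm(3)
    f <- build_frame(n, ca, c)
    o <- gs_oracle(n, ca, c)
    expect_lt(max(abs(f$R - o$R)), 1e-12)
    expect_lt(max(abs(crossprod(f$R) - diag(3))), 1e-9)
    expect_lt(abs(det(f$R) - 1), 1e-9)
  }
  expect_error(build_frame(c(2, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               class = "domasm_geometry_error")
})

test_that("euler_to_rotation reproduces the ZYX factor product", {
  expect_equal(euler_to_rotation(0, 0, 0), diag(3))
  expect_lt(max(abs(euler_to_rotation(0, 0, pi / 2) -
                      matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3))), 1e-12)
  Rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3)
  Ry <- function(b) matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3)
  Rz <- function(g) matrix(c(cos(g), sin(g), 0, -sin(g), cos(g), 0, 0, 0, 1), 3)
  set.seed(21)
  for (k in 1:50) {
    a <- runif(1, -pi, pi); b <- runif(1, -pi / 2, pi / 2); g <- runif(1, -pi, pi)
    expect_lt(max(abs(euler_to_rotation(a, b, g) - Rz(g) %*% Ry(b) %*% Rx(a))),
              1e-12)
  }
})

test_that("rotation_to_euler inverts the codec and handles gimbal lock", {
  expect_equal(unname(rotation_to_euler(diag(3))), c(0, 0, 0))
  set.seed(31)
  for (k in 1:100) {
    ang <- c(runif(1, -pi, pi), runif(1, -pi / 2 + 1e-3, pi / 2 - 1e-3),
             runif(1, -pi, pi))
    e <- rotation_to_euler(euler_to_rotation(ang[1], ang[2], ang[3]))
    expect_lt(max(abs(unname(e) - ang)), 1e-9)
  }
  # gimbal lock: the angle triple is not unique but must reconstruct R
  for (s in c(1, -1)) for (k in 1:10) {
    R <- euler_to_rotation(runif(1, -pi, pi), s * pi / 2, runif(1, -pi, pi))
    e <- rotation_to_euler(R)
    expect_identical(unname(e[1]), 0)
    expect_lt(max(abs(euler_to_rotation(e[1], e[2], e[3]) - R)), 1e-9)
  }
  expect_error(rotation_to_euler(matrix(1, 3, 3)),
               class = "domasm_validation_error")
})

test_that("spherical codec matches analytic cases and round-trips", {
  expect_equal(unname(translation_to_spherical(c(0, 0, 1))), c(1, 0, 0))
  expect_lt(max(abs(unname(translation_to_spherical(c(sqrt(2), sqrt(2), 0))) -
                      c(2, pi / 2, pi / 4))), 1e-12)
  expect_equal(unname(translation_to_spherical(c(0, 0, 0))), c(0, 0, 0))
  expect_equal(spherical_to_translation(0, 1.2, 0.3), c(0, 0, 0))
  expect_lt(max(abs(spherical_to_translation(1, 0, 2.2) - c(0, 0, 1))), 1e-12)
  expect_lt(max(abs(spherical_to_translation(2, pi / 2, pi / 4) -
                      c(sqrt(2), sqrt(2), 0))), 1e-12)
  expect_error(spherical_to_translation(-1, 0, 0),
               class = "domasm_validation_error")
  set.seed(41)
  for (k in 1:50) {
    t0 <- rnorm(3) * 5
    s <- translation_to_spherical(t0)
    expect_lt(max(abs(spherical_to_translation(s[1], s[2], s[3]) - t0)), 1e-12)
  }
})

test_that("relative_transform encodes A_i^-1 A_j and r equals the CA distance", {
  set.seed(51)
  f <- random_affine()
  expect_lt(max(abs(relative_transform(f, f))), 1e-12)

  fi <- random_affine()
  fj <- affine_transform(fi$R, fi$t + as.numeric(fi$R %*% c(0, 0, 5)))
  v <- relative_transform(fi, fj)
  expect_lt(abs(v[["r"]] - 5), 1e-9)
  expect_lt(abs(v[["theta"]]), 1e-9)

  for (k in 1:50) {
    fi <- random_affine(); fj <- random_affine()
    v <- relative_transform(fi, fj)
    H <- solve(hom4_of(fi)) %*% hom4_of(fj)   # homogeneous-matrix oracle
    rec <- hom4_of(affine_from_6d(v))
    expect_lt(max(abs(rec - H)), 1e-9)
    expect_lt(abs(v[["r"]] - sqrt(sum((fj$t - fi$t)^2))), 1e-9)
  }
})

test_that("affine_from_6d matches the numeric factor product and zero maps to identity", {
  z <- affine_from_6d(c(0, 0, 0, 0, 0, 0))
  expect_lt(max(abs(z$R - diag(3))), 1e-12)
  expect_equal(z$t, c(0, 0, 0))
  set.seed(61)
  for (k in 1:50) {
    v <- c(runif(1, -pi, pi), runif(1, -pi / 2, pi / 2), runif(1, -pi, pi),
           runif(1, 0, 30), runif(1, 0, pi), runif(1, -pi, pi))
    a <- affine_from_6d(v)
    expect_lt(max(abs(a$R - euler_to_rotation(v[1], v[2], v[3]))), 1e-12)
    expect_lt(max(abs(a$t - spherical_to_translation(v[4], v[5], v[6]))), 1e-12)
  }
})

test_that("compose/invert obey group laws and homogeneous-matrix action", {
  set.seed(71)
  for (k in 1:30) {
    a <- random_affine(); b <- random_affine(); c3 <- random_affine()
    ia <- affine_invert(a)
    id <- affine_compose(a, ia)
    expect_lt(max(abs(id$R - diag(3))), 1e-12)
    expect_lt(max(abs(id$t)), 1e-12)
    lhs <- affine_compose(affine_compose(a, b), c3)
    rhs <- affine_compose(a, affine_compose(b, c3))
    expect_lt(max(abs(hom4_of(lhs) - hom4_of(rhs))), 1e-12)
    x <- rnorm(3)
    expect_lt(max(abs(affine_apply(affine_compose(a, b), x) -
                        hom4_apply(hom4_of(a) %*% hom4_of(b), x))), 1e-12)
  }
})
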