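test_that("identity and single-axis coordinates compose to the expected poses", {
  p0 <- gs_compose(gs_coords())
  expect_equal(p0$rotation, diag(3), tolerance = 1e-12)
  expect_equal(p0$translation, c(0, 0, 0), tolerance = 1e-12)

  p30 <- gs_compose(gs_coords(flexion_extension = 30))
  a <- 30 * pi / 180
  expect_equal(p30$rotation,
               matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3),
               tolerance = 1e-12)
  expect_equal(p30$translation, c(0, 0, 0), tolerance = 1e-12)
})

test_that("compose/decompose round-trips over physiological ranges", {
  set.seed(11)
  worst <- 0
  for (cs in random_coords(1000)) {
    back <- gs_decompose(gs_compose(cs))
    worst <- max(worst, max(abs(unclass(back) - unclass(cs))))
  }
  expect_lt(worst, 1e-9)
})

test_that("specific coordinates survive the round trip", {
  cs <- gs_coords(15, 5, -10, 1, 4, -18)
  expect_equal(unclass(gs_decompose(gs_compose(cs))), unclass(cs),
               tolerance = 1e-12)
})

test_that("identity pose with coincident frames decomposes to zeros", {
  z <- gs_decompose(rigid_pose())
  expect_equal(max(abs(unclass(z))), 0, tolerance = 1e-12)
})

test_that("translation-only poses decompose to zero rotations and projected translations", {
  pose <- rigid_pose(diag(3), c(3, -4, 7))
  cs <- gs_decompose(pose)
  expect_equal(cs[["flexion_extension"]], 0)
  expect_equal(cs[["varus_valgus"]], 0)
  expect_equal(cs[["internal_external"]], 0)
  # at zero rotation the joint axes are the frame axes (with the documented
  # sign convention: positive coordinates displace the femur negatively)
  expect_equal(cs[["medial_lateral"]], -3)
  expect_equal(cs[["anterior_posterior"]], 4)
  expect_equal(cs[["superior_inferior"]], -7)
})

test_that("sequential single-axis motions are recovered independently", {
  for (i in 1:3) {
    vals <- c(0, 0, 0)
    vals[i] <- c(40, 12, -25)[i]
    cs <- gs_coords(vals[1], vals[2], vals[3])
    back <- gs_decompose(gs_compose(cs))
    expect_equal(unclass(back)[1:3], unclass(cs)[1:3], tolerance = 1e-12)
  }
})

test_that("composition is continuous in the coordinates", {
  set.seed(12)
  for (cs in random_coords(20)) {
    base <- transform_point(gs_compose(cs), c(10, 20, 30))
    pert <- unclass(cs) + 1e-6
    moved <- transform_point(gs_compose(do.call(gs_coords, as.list(pert))),
                             c(10, 20, 30))
    expect_lt(max(abs(moved - base)), 1e-3)
  }
})

test_that("gimbal configurations are rejected", {
  expect_error(gs_compose(gs_coords(varus_valgus = 90)), "gimbal")
  # a pose built just inside the singularity is rejected at decomposition
  R <- gs_compose(gs_coords(varus_valgus = 89.99999))$rotation
  expect_error(gs_decompose(rigid_pose(R)), "near-singular")
})

test_that("transform_point is a rigid isometry", {
  expect_equal(transform_point(rigid_pose(), c(1, 2, 3)), c(1, 2, 3))
  rot90 <- rigid_pose(matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3))
  expect_equal(transform_point(rot90, c(1, 0, 0)), c(0, 1, 0),
               tolerance = 1e-12)
  set.seed(13)
  pose <- gs_compose(random_coords(1)[[1]])
  for (i in 1:100) {
    p1 <- stats::rnorm(3, sd = 20); p2 <- stats::rnorm(3, sd = 20)
    d0 <- sqrt(sum((p1 - p2)^2))
    d1 <- sqrt(sum((transform_point(pose, p1) - transform_point(pose, p2))^2))
    expect_lt(abs(d1 - d0), 1e-9)
  }
})

test_that("mirroring negates ML, VrVl and IE and is an involution", {
  cs <- gs_coords(30, 5, -10, 2, 4, -6)
  m <- gs_mirror(cs)
  expect_equal(m[["varus_valgus"]], -5)
  expect_equal(m[["internal_external"]], 10)
  expect_equal(m[["medial_lateral"]], -2)
  expect_equal(m[["anterior_posterior"]], 4)
  expect_equal(unclass(gs_mirror(m)), unclass(cs))
})

test_that("coordinate validation rejects non-finite and out-of-range values", {
  expect_error(gs_coords(NA), "finite")
  expect_error(gs_coords(200), "-180")
  expect_error(body_frame(axes = matrix(1:9, 3)), "orthonormal")
  expect_error(rigid_pose(rotation = diag(c(1, 1, -1))), "proper")
})

test_that("kinematics series round-trip through the CSV convention", {
  series <- do.call(rbind, lapply(random_coords(3), kneelax:::coords_to_row))
  path <- withr::local_tempfile(fileext = ".csv")
  write_kinematics_csv(series, path)
  back <- utils::read.csv(path)
  expect_equal(back$AP_mm, series$AP_mm, tolerance = 1e-9)
  expect_named(back, c("step", "FE_deg", "VrVl_deg", "IE_deg", "ML_mm",
                       "AP_mm", "SI_mm"))
})
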