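test_that("total potential is zero for an inert joint and matches the compiled core", {
  inert <- inert_knee()
  set.seed(21)
  for (i in 1:10) {
    cs <- gs_coords(stats::runif(1, 0, 60), stats::runif(1, -5, 5),
                    stats::runif(1, -10, 10), stats::runif(1, -3, 3),
                    stats::runif(1, -3, 3), stats::runif(1, -3, 3))
    expect_equal(total_potential(inert, cs), 0)
  }
  knee <- clean_knee()
  fm <- kneelax:::fibers_matrix(knee)
  cm <- kneelax:::contacts_matrix(knee)
  lc <- load_case(30, force_ap = 80, torque_ie = 2, torque_vrvl = -3)
  lv <- kneelax:::loads_vector(knee, lc)
  for (i in 1:20) {
    q <- c(stats::runif(1, -0.2, 0.2), stats::runif(1, -0.5, 0.5),
           stats::runif(3, -4, 4))
    cs <- gs_coords(30, q[1] * 180 / pi, q[2] * 180 / pi, q[3], q[4], q[5])
    eR <- total_potential(knee, cs, lc)
    eC <- kneelax:::knee_energy_cpp(30 * pi / 180, q, fm, cm, lv)
    expect_equal(eC, eR, tolerance = 1e-10)
  }
})

test_that("the analytic gradient matches central finite differences of the potential", {
  knee <- clean_knee()
  fm <- kneelax:::fibers_matrix(knee)
  cm <- kneelax:::contacts_matrix(knee)
  lc <- load_case(30, force_ap = 100, torque_ie = 3, torque_vrvl = -5)
  lv <- kneelax:::loads_vector(knee, lc)
  tp <- function(q) {
    total_potential(knee, gs_coords(30, q[1] * 180 / pi, q[2] * 180 / pi,
                                    q[3], q[4], q[5]), lc)
  }
  set.seed(22)
  for (i in 1:50) {
    q <- c(stats::runif(1, -0.2, 0.2), stats::runif(1, -0.5, 0.5),
           stats::runif(3, -5, 5))
    g <- kneelax:::knee_gradient_cpp(30 * pi / 180, q, fm, cm, lv)
    gf <- numeric(5)
    h <- 1e-6
    for (j in 1:5) {
      qp <- q; qm <- q
      qp[j] <- qp[j] + h; qm[j] <- qm[j] - h
      gf[j] <- (tp(qp) - tp(qm)) / (2 * h)
    }
    expect_lt(max(abs(g - gf) / (abs(gf) + 1)), 1e-4)
  }
})

test_that("a converged equilibrium has residual below tolerance", {
  knee <- clean_knee()
  for (lc in list(load_case(0), load_case(30, force_ap = 133),
                  load_case(90, torque_ie = 5),
                  load_case(60, torque_vrvl = -8))) {
    res <- solve_equilibrium(knee, lc)
    expect_true(res$converged)
    expect_lt(res$residual_norm, 1e-3)
    expect_true(all(res$bundle_forces >= 0))
  }
})

test_that("a mirror-symmetric knee settles on the sagittal plane", {
  res <- solve_equilibrium(symmetric_knee(), load_case(0))
  expect_true(res$converged)
  expect_lt(abs(res$coords[["medial_lateral"]]), 1e-3)
  expect_lt(abs(res$coords[["internal_external"]]), 1e-3)
  expect_lt(abs(res$coords[["varus_valgus"]]), 1e-3)
})

test_that("with slack ligaments the contact carries exactly the settling compression", {
  knee <- slack_knee()
  res <- solve_equilibrium(knee, load_case(0))
  expect_true(res$converged)
  expect_equal(sum(res$bundle_forces), 0)
  expect_equal(sum(res$contact_forces), knee$settle_compression,
               tolerance = 1e-2)
})

test_that("anterior load-displacement response is monotone", {
  knee <- clean_knee()
  ap <- numeric(0)
  warm <- NULL
  for (f in seq(0, 150, by = 25)) {
    res <- solve_equilibrium(knee, load_case(30, force_ap = f), warm = warm)
    warm <- res$coords
    ap <- c(ap, res$coords[["anterior_posterior"]])
  }
  expect_true(all(diff(ap) >= 0))
})

test_that("the equilibrium is path-independent in the load ramp resolution", {
  knee <- clean_knee()
  lc <- load_case(60, force_ap = 133, torque_ie = 4)
  r10 <- solve_equilibrium(knee, lc, control = list(load_substeps = 10))
  r40 <- solve_equilibrium(knee, lc, control = list(load_substeps = 40))
  d <- abs(unclass(r10$coords) - unclass(r40$coords))
  expect_lt(max(d), 0.05)
})

test_that("mirrored knees under mirrored loads produce mirrored kinematics", {
  knee <- clean_knee()
  mk <- mirror_knee(knee)
  lc <- load_case(30, force_ap = 100, torque_ie = 4, torque_vrvl = -6)
  lm <- load_case(30, force_ap = 100, torque_ie = -4, torque_vrvl = 6)
  r1 <- solve_equilibrium(knee, lc)
  r2 <- solve_equilibrium(mk, lm)
  expect_true(r1$converged && r2$converged)
  expect_equal(unclass(gs_mirror(r2$coords)), unclass(r1$coords),
               tolerance = 1e-3)
})

test_that("AP laxity with zero magnitude reduces to the passive state", {
  knee <- clean_knee()
  ap0 <- simulate_ap_laxity(knee, angles = 30, magnitude = 0)
  passive <- solve_equilibrium(knee, load_case(30))
  expect_equal(ap0$AP_mm, rep(passive$coords[["anterior_posterior"]], 2),
               tolerance = 1e-6)
})

test_that("AP laxity is a positive range and loads the ACL most anteriorly", {
  knee <- clean_knee()
  ap <- simulate_ap_laxity(knee)
  for (ang in unique(ap$flexion_deg)) {
    a <- ap$AP_mm[ap$direction == "anterior" & ap$flexion_deg == ang]
    p <- ap$AP_mm[ap$direction == "posterior" & ap$flexion_deg == ang]
    expect_gt(a - p, 0)
  }
  groups <- names(bundle_groups())
  ant <- ap[ap$direction == "anterior", groups]
  for (i in seq_len(nrow(ant))) {
    expect_equal(names(ant)[which.max(ant[i, ])], "ACL")
  }
})

test_that("passive flexion is deterministic and starts at the settle pose", {
  knee <- clean_knee()
  pf1 <- simulate_passive_flexion(knee, max_flexion = 30)
  pf2 <- simulate_passive_flexion(knee, max_flexion = 30)
  expect_identical(pf1, pf2)
  settle <- solve_equilibrium(knee, load_case(0))
  expect_equal(pf1$AP_mm[1], settle$coords[["anterior_posterior"]],
               tolerance = 1e-6)
})

test_that("ACL removal in the pivot shift zeroes ACL forces and destabilizes anteriorly", {
  knee <- clean_knee()
  intact <- simulate_pivot_shift(knee)
  deficient <- simulate_pivot_shift(knee, acl_deficient = TRUE)
  expect_equal(deficient$bundle_forces[["ACL_AM"]], 0)
  expect_equal(deficient$bundle_forces[["ACL_PL"]], 0)
  expect_gt(bundle_group_forces(intact)[["ACL"]], 5)
  expect_gt(bundle_group_forces(deficient)[["ALS"]],
            bundle_group_forces(intact)[["ALS"]])
  expect_gt(deficient$coords[["anterior_posterior"]],
            intact$coords[["anterior_posterior"]])
})

test_that("bundle group forces partition the fiber forces", {
  knee <- clean_knee()
  res <- solve_equilibrium(knee, load_case(30, force_ap = 133))
  gf <- bundle_group_forces(res)
  expect_equal(sum(gf), sum(res$bundle_forces), tolerance = 1e-9)
  # hand-added grouping for a synthetic force vector
  bf <- stats::setNames(seq_along(bundle_names()), bundle_names())
  gf2 <- bundle_group_forces(bf)
  expect_equal(gf2[["ACL"]], 1 + 2)
  expect_equal(gf2[["MCL_S"]], 4 + 5 + 6)
  expect_equal(gf2[["PCAP"]], 13 + 14)
  expect_equal(gf2[["PCL"]], 8 + 9)
  expect_equal(sum(gf2), sum(bf))
  # an all-slack model reports zero in every group
  expect_equal(unname(bundle_group_forces(
    solve_equilibrium(slack_knee(), load_case(0)))), rep(0, 9))
})

test_that("joint-limit violations set the dislocation flag", {
  knee <- clean_knee()
  knee$joint_limits$ap <- c(-0.1, 0.1)
  res <- solve_equilibrium(knee, load_case(30, force_ap = 133))
  expect_true(res$dislocated)
})
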