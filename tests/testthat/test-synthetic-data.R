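test_that("knee generation is deterministic and carries the standard fiber counts", {
  s <- synthetic_knee_spec(seed = 9, attachment_jitter_sd = 0)
  k1 <- generate_knee(s)
  k2 <- generate_knee(s)
  expect_identical(k1, k2)
  sj <- synthetic_knee_spec(seed = 9, attachment_jitter_sd = 0.5)
  expect_identical(generate_knee(sj), generate_knee(sj))
  nf <- vapply(k1$bundles, function(b) nrow(b$origins), integer(1))
  expect_equal(sum(nf), 30)  # 2+2+3+1+1+1+3+2+2+2+3+2+3+3
  t3 <- load_paper_fixtures()$table3
  expect_equal(unname(nf[t3$abbrev]), t3$n_fibers)
})

test_that("the LCL origin sits superior-posterior to the lateral epicondyle", {
  k <- generate_knee(synthetic_knee_spec(seed = 1, attachment_jitter_sd = 0))
  lcl <- k$bundles$LCL
  central <- lcl$origins[2, ]  # middle of the three fibers
  le <- c(-30, 0, 0)           # lateral epicondyle landmark
  expect_equal(central - le, c(0, -3.1, 1.4), tolerance = 1e-9)
})

test_that("ground-truth sampling respects bounds and the uniform mean", {
  full <- generate_knee(synthetic_knee_spec(seed = 1))
  bounds <- parameter_bounds(full)
  for (s in 1:20) {
    x <- sample_ground_truth(bounds, seed = s)
    expect_true(all(x >= bounds[, 1] & x <= bounds[, 2]))
  }
  expect_identical(sample_ground_truth(bounds, seed = 3),
                   sample_ground_truth(bounds, seed = 3))
  x1 <- vapply(1:10000, function(s) sample_ground_truth(bounds, s)[["X1"]],
               numeric(1))
  expect_equal(mean(x1), 1.10, tolerance = 0.01)  # uniform mean on [0.95, 1.25]
})

test_that("noise-free measurements equal the forward simulation and are reproducible", {
  k <- reduce_bundles(generate_knee(synthetic_knee_spec(seed = 2,
                                                        attachment_jitter_sd = 0)))
  m <- generate_measurements(k, "KLA", noise = measurement_noise_spec(0, 0, seed = 1))
  expect_equal(nrow(m), 15)
  row <- m[m$group_id == "anterior@30" & m$force_ap_N == 175, ]
  res <- solve_equilibrium(k, load_case(30, force_ap = 175))
  expect_equal(row$AP_mm, res$coords[["anterior_posterior"]], tolerance = 1e-6)
  expect_equal(row$IE_deg, res$coords[["internal_external"]], tolerance = 1e-6)

  noisy1 <- generate_measurements(k, "KLA", noise = measurement_noise_spec(seed = 5))
  noisy2 <- generate_measurements(k, "KLA", noise = measurement_noise_spec(seed = 5))
  expect_identical(noisy1, noisy2)
  expect_false(identical(noisy1$AP_mm, m$AP_mm))
})

test_that("the KLA design is an information subset of the RKS design", {
  k <- reduce_bundles(generate_knee(synthetic_knee_spec(seed = 2,
                                                        attachment_jitter_sd = 0)))
  mk <- generate_measurements(k, "KLA", noise = measurement_noise_spec(0, 0, seed = 1))
  mr <- generate_measurements(k, "RKS", noise = measurement_noise_spec(0, 0, seed = 1))
  expect_equal(nrow(mr), 25)
  loaded_dof <- function(m) {
    unique(c(if (any(m$force_ap_N != 0)) "AP",
             if (any(m$torque_ie_Nm != 0)) "IE",
             if (any(m$torque_vrvl_Nm != 0)) "VrVl"))
  }
  expect_setequal(loaded_dof(mk), c("AP", "IE"))         # 2 loaded DOF
  expect_setequal(loaded_dof(mr), c("AP", "IE", "VrVl")) # 3 loaded DOF
  expect_setequal(unique(mk$flexion_deg[mk$group_id != "passive@0"]), c(30, 90))
  expect_setequal(unique(mr$flexion_deg[mr$group_id != "passive@0"]),
                  c(0, 30, 60, 90))
})

test_that("packaged fixtures match the published tables digit for digit", {
  fx <- load_paper_fixtures()
  expect_equal(nrow(fx$table3), 14)
  expect_equal(length(unique(c(fx$table3$strain_dv, fx$table3$stiffness_dv))), 26)
  expect_equal(nrow(fx$table4), 26)
  dmcl <- fx$table4[fx$table4$parameter == "reference_strain" &
                      fx$table4$ligament == "dMCL", ]
  expect_equal(unname(unlist(dmcl[, c("specimen1_kla", "specimen1_rks",
                                      "specimen2_kla", "specimen2_rks")])),
               c(0.95, 0.94, 0.79, 0.74))
  t7 <- fx$table7
  expect_equal(dim(t7), c(8, 13))
  expect_equal(t7$MCL_S[t7$specimen == 2 & t7$acl_condition == "intact" &
                          t7$model == "KLA"], 215.4)
})

test_that("knee model configurations round-trip through JSON", {
  k <- generate_knee(synthetic_knee_spec(seed = 4))
  path <- withr::local_tempfile(fileext = ".json")
  write_knee_model(k, path)
  back <- read_knee_model(path)
  expect_equal(get_parameters(back), get_parameters(k), tolerance = 1e-12)
  expect_equal(back$bundles$ACL_AM$origins, k$bundles$ACL_AM$origins,
               tolerance = 1e-12)
  expect_equal(back$contacts[[1]]$dish_radius, k$contacts[[1]]$dish_radius)
  # behavior identical after the round trip
  r1 <- solve_equilibrium(k, load_case(30, force_ap = 100))
  r2 <- solve_equilibrium(back, load_case(30, force_ap = 100))
  expect_equal(unclass(r1$coords), unclass(r2$coords), tolerance = 1e-9)
})

test_that("mirrored (right-knee) construction flips the medial-lateral axis", {
  left <- generate_knee(synthetic_knee_spec(seed = 4, attachment_jitter_sd = 0))
  right <- mirror_knee(left)
  expect_equal(right$bundles$LCL$origins[, 1], -left$bundles$LCL$origins[, 1])
  sides <- vapply(right$contacts, function(ce) ce$side, character(1))
  expect_setequal(sides, c("medial", "lateral"))
})
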