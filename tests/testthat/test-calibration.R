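# shared fixtures for the calibration tests: a reduced synthetic knee with
# known ground truth and its noise-free target tables
cal_fixture <- local({
  env <- new.env()
  function() {
    if (is.null(env$model)) {
      knee <- generate_knee(synthetic_knee_spec(seed = 5, attachment_jitter_sd = 0))
      env$model <- reduce_bundles(knee, c("ACL_AM", "LCL", "sMCL_M", "PCL_AL"))
      env$truth <- sample_ground_truth(parameter_bounds(env$model), seed = 6)
      env$truth_model <- set_parameters(env$model, env$truth)
      env$meas_rks <- generate_measurements(env$truth_model, "RKS",
                                            noise = measurement_noise_spec(0, 0, seed = 1))
      env$meas_kla <- generate_measurements(env$truth_model, "KLA",
                                            noise = measurement_noise_spec(0, 0, seed = 1))
    }
    env
  }
})

test_that("target construction produces the documented group structure", {
  fx <- cal_fixture()
  tr <- build_targets(fx$meas_rks, "RKS")
  expect_equal(nrow(tr), 25)  # 4 angles x 3 DOF x 2 extremes + passive
  expect_setequal(unique(tr$group_id),
                  c(paste0(rep(c("ap", "ie", "vrvl"), each = 4), "@",
                           c(0, 30, 60, 90)), "passive@0"))
  tk <- build_targets(fx$meas_kla, "KLA")
  expect_equal(nrow(tk), 15)  # (3 anterior + 4 IE) x 2 angles + passive
  expect_setequal(unique(tk$group_id),
                  c("anterior@30", "anterior@90", "ie@30", "ie@90", "passive@0"))
  expect_true(all(tk$force_ap_N >= 0))  # no posterior loading in KLA
})

test_that("degenerate or incomplete measurement tables are rejected by name", {
  fx <- cal_fixture()
  expect_error(build_targets(fx$meas_rks[0, ], "RKS"), "passive@0")
  partial <- fx$meas_rks[fx$meas_rks$flexion_deg != 90, ]
  expect_error(build_targets(partial, "RKS"), "ap@90")
  post <- fx$meas_kla
  post$force_ap_N[2] <- -50
  expect_error(build_targets(post, "KLA"), "posterior")
})

test_that("the 75-for-90 substitution flag is honored", {
  fx <- cal_fixture()
  m <- fx$meas_rks
  m$group_id <- sub("@90", "@75", m$group_id)
  m$flexion_deg[m$flexion_deg == 90] <- 75
  expect_error(build_targets(m, "RKS"), "@90")
  expect_s3_class(build_targets(m, "RKS", substitute_75_for_90 = TRUE),
                  "laxity_targets")
})

test_that("the grouped percentile cost reproduces the hand-computed example", {
  cfg <- cost_config(c("anterior@30:AP" = 2), ranges = c(AP = 10))
  err <- data.frame(group_id = "anterior@30", dof = "AP", error = c(1, 2, 3, 4))
  bd <- cost_breakdown(err, cfg)
  expect_equal(bd$table$percentile_error, 3.25)  # linear-interpolated 75th
  expect_equal(bd$total, 0.65)
  pen <- cost_breakdown(err, cfg, penalty = TRUE)
  expect_true(pen$penalty_applied)
  expect_equal(pen$total, 0.4225)
})

test_that("the cost is order-free, non-negative and monotone in single errors", {
  cfg <- cost_config(c("g:AP" = 1, "g:IE" = 0.5), ranges = c(AP = 10, IE = 20))
  err <- data.frame(group_id = "g", dof = rep(c("AP", "IE"), each = 4),
                    error = c(4, -1, 3, 2, 5, 6, -7, 8))
  set.seed(31)
  base <- cost_breakdown(err, cfg)$total
  for (i in 1:5) {
    shuffled <- err[sample(nrow(err)), ]
    expect_equal(cost_breakdown(shuffled, cfg)$total, base)
  }
  expect_gte(base, 0)
  grown <- err
  grown$error[1] <- 10
  expect_gte(cost_breakdown(grown, cfg)$total, base)
  zero <- err; zero$error <- 0
  expect_equal(cost_breakdown(zero, cfg)$total, 0)
})

test_that("the cost of the generating model against its own noise-free targets is zero", {
  fx <- cal_fixture()
  tr <- build_targets(fx$meas_rks, "RKS")
  bd <- evaluate_cost(fx$truth_model, tr)
  expect_true(all(attr(bd, "converged")))
  expect_equal(bd$total, 0)
})

test_that("a degenerate calibration budget returns the seeded sample deterministically", {
  fx <- cal_fixture()
  tk <- build_targets(fx$meas_kla, "KLA")
  b <- list(pso_particles = 1, pso_iterations = 0, nm_iterations = 0)
  c1 <- calibrate(fx$model, tk, budget = b, seed = 12)
  c2 <- calibrate(fx$model, tk, budget = b, seed = 12)
  expect_identical(c1$parameters, c2$parameters)
  expect_identical(c1$cost_trace, c2$cost_trace)
  bounds <- parameter_bounds(fx$model)
  expect_true(all(c1$parameters >= bounds[, 1] & c1$parameters <= bounds[, 2]))
})

test_that("the packaged design-variable bounds match the published table", {
  b <- load_table3_bounds()
  expect_equal(nrow(b), 26)
  expect_equal(unname(unlist(b[b$dv == "X1", c("lo", "hi")])), c(0.95, 1.25))
  expect_equal(unname(unlist(b[b$dv == "X17", c("lo", "hi")])), c(60, 200))
  expect_equal(sum(b$type == "reference_strain"), 14)
  expect_equal(sum(b$type == "stiffness"), 12)
  # X18 is shared by the three superficial MCL fibers
  full <- generate_knee(synthetic_knee_spec(seed = 1))
  dvt <- kneelax:::design_variable_table(full)
  expect_equal(nrow(dvt), 26)
  expect_setequal(dvt$bundles[[which(dvt$dv == "X18")]],
                  c("sMCL_A", "sMCL_M", "sMCL_P"))
})

test_that("targets round-trip through CSV", {
  fx <- cal_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_targets_csv(build_targets(fx$meas_kla, "KLA"), path)
  back <- read_targets_csv(path, "KLA")
  expect_equal(back$AP_mm, fx$meas_kla$AP_mm, tolerance = 1e-9)
})
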