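# Comparison metrics and the end-to-end KLA-vs-RKS replication experiment.

#' Root-mean-squared difference between two series
#'
#' @param a,b Equal-length numeric vectors.
#' @return `sqrt(mean((a - b)^2))`.
#' @export
#' @examples
#' rmsd(c(0, 0), c(3, 4))  # sqrt(25/2)
rmsd <- function(a, b) {
  if (length(a) != length(b)) stop("series lengths differ")
  if (length(a) < 1) stop("series must have length >= 1")
  sqrt(mean((a - b)^2))
}

#' Per-ligament summary of calibrated parameters
#'
#' Averages the four calibrated values (two specimens x two calibration
#' sources) per ligament for reference strain and stiffness and identifies
#' the ligaments with the smallest and largest averages.
#'
#' @param table4 Calibrated-parameter table (default: packaged fixture).
#' @return List with data frames `reference_strain` and `stiffness`
#'   (columns `ligament`, `mean`, `min`, `max`) and a `extremes` summary.
#' @export
#' @examples
#' s <- parameter_summary()
#' s$reference_strain[s$reference_strain$ligament == "dMCL", ]
parameter_summary <- function(table4 = load_table4()) {
  val_cols <- c("specimen1_kla", "specimen1_rks", "specimen2_kla",
                "specimen2_rks")
  one <- function(param) {
    d <- table4[table4$parameter == param, , drop = FALSE]
    vals <- as.matrix(d[, val_cols])
    data.frame(ligament = d$ligament, mean = rowMeans(vals),
               min = apply(vals, 1, min), max = apply(vals, 1, max),
               stringsAsFactors = FALSE)
  }
  rs <- one("reference_strain")
  st <- one("stiffness")
  extremes <- list(
    smallest_reference_strain = rs$ligament[which.min(rs$mean)],
    largest_reference_strain = rs$ligament[which.max(rs$mean)],
    smallest_stiffness = st$ligament[which.min(st$mean)],
    largest_stiffness = st$ligament[which.max(st$mean)]
  )
  list(reference_strain = rs, stiffness = st, extremes = extremes)
}

#' Percent differences between calibrations or specimens
#'
#' Computes per-ligament percent differences of calibrated parameters
#' either between the two calibration sources within each specimen
#' (`inter_model`) or between the two specimens within each calibration
#' source (`inter_specimen`). Two percent-difference definitions are
#' supported and the one used is recorded in the output, since published
#' summary percentages rarely state which was used: `mean_based`
#' (`|a - b| / ((a + b)/2)`) and `first_based` (`|a - b| / a`).
#'
#' @param table4 Calibrated-parameter table (default: packaged fixture).
#' @param mode `"inter_model"` or `"inter_specimen"`.
#' @param definition `"mean_based"` or `"first_based"`.
#' @return List with the per-ligament `table`, `grand_mean` per parameter
#'   type (percent), `mode` and `definition`.
#' @export
percent_difference_table <- function(table4 = load_table4(),
                                     mode = c("inter_model", "inter_specimen"),
                                     definition = c("mean_based", "first_based")) {
  mode <- match.arg(mode)
  definition <- match.arg(definition)
  pd <- function(a, b) {
    denom <- if (definition == "mean_based") (a + b) / 2 else a
    100 * abs(a - b) / denom
  }
  if (mode == "inter_model") {
    d1 <- pd(table4$specimen1_kla, table4$specimen1_rks)
    d2 <- pd(table4$specimen2_kla, table4$specimen2_rks)
    tab <- data.frame(parameter = table4$parameter, ligament = table4$ligament,
                      specimen1 = d1, specimen2 = d2,
                      mean_pct = (d1 + d2) / 2, stringsAsFactors = FALSE)
  } else {
    dk <- pd(table4$specimen1_kla, table4$specimen2_kla)
    dr <- pd(table4$specimen1_rks, table4$specimen2_rks)
    tab <- data.frame(parameter = table4$parameter, ligament = table4$ligament,
                      kla = dk, rks = dr, mean_pct = (dk + dr) / 2,
                      stringsAsFactors = FALSE)
  }
  gm <- tapply(tab$mean_pct, tab$parameter, mean)
  list(table = tab, grand_mean = gm, mode = mode, definition = definition)
}

#' Collateral-ligament load change between intact and ACL-deficient states
#'
#' Sums the chosen ligament groups in the pivot-shift load table for the
#' intact and ACL-deficient conditions of one specimen/calibration and
#' returns the decrease (intact minus deficient).
#'
#' @param table7 Pivot-shift load table (default: packaged fixture).
#' @param specimen Specimen number (1 or 2).
#' @param calibration `"KLA"` or `"RKS"`.
#' @param groups Load-table group columns to sum.
#' @return Load decrease, N.
#' @export
#' @examples
#' group_load_delta(specimen = 2, calibration = "KLA")  # 215.4 - 148.0
group_load_delta <- function(table7 = load_table7(), specimen, calibration,
                             groups = c("LCL", "MCL_S", "MCL_D")) {
  pick <- function(cond) {
    row <- table7[table7$specimen == specimen & table7$model == calibration &
                    table7$acl_condition == cond, , drop = FALSE]
    if (nrow(row) != 1) stop("missing pivot-shift load row")
    sum(as.numeric(row[, groups]))
  }
  pick("intact") - pick("no_acl")
}

#' Render a group-load vector the way published load tables do
#'
#' Loads under 5 N are shown as `"-"`.
#'
#' @param loads Named numeric vector of group loads, N.
#' @return Character vector.
#' @export
format_group_loads <- function(loads) {
  ifelse(loads < 5, "-", sprintf("%.1f", loads))
}

#' Bundles carrying appreciable load across a set of targets
#'
#' Simulates every target with the given model and returns the bundles
#' whose summed force exceeds `threshold` in at least one settled state.
#' Used to decide which reference-length ratios a calibration can be
#' expected to identify.
#'
#' @param model A [knee_model()].
#' @param targets Target table.
#' @param threshold Force threshold, N.
#' @param control Solver control list.
#' @return Character vector of bundle names.
#' @export
load_bearing_bundles <- function(model, targets, threshold = 10,
                                 control = list()) {
  mx <- stats::setNames(rep(0, length(model$bundles)), names(model$bundles))
  for (i in seq_len(nrow(targets))) {
    lc <- load_case(flexion_deg = targets$flexion_deg[i],
                    force_ap = targets$force_ap_N[i],
                    torque_ie = targets$torque_ie_Nm[i],
                    torque_vrvl = targets$torque_vrvl_Nm[i],
                    force_si = targets$force_si_N[i])
    res <- solve_equilibrium(model, lc, control = control)
    mx <- pmax(mx, res$bundle_forces[names(mx)])
  }
  names(mx)[mx > threshold]
}

#' Full KLA-vs-RKS replication experiment on a synthetic knee
#'
#' Self-contained analog of the published study design: generate a
#' synthetic knee with known ground-truth ligament parameters, produce
#' KLA-style and RKS-style laxity target tables, calibrate the model
#' separately against each, then compare the two calibrated models on AP
#' laxity (±133 N at 30/60/90 deg), passive flexion and the pivot shift
#' (intact and ACL-deficient). Uses the reduced 8-bundle model and a
#' scaled-down optimizer budget so the whole experiment runs on a desktop.
#'
#' @param seed Integer seed driving every stochastic component (geometry
#'   jitter, ground-truth draw, optimizer initialization).
#' @param budget Optimizer budget (see [calibrate()]).
#' @param knee_spec A [synthetic_knee_spec()]; defaults to the standard
#'   geometry with the given seed.
#' @param noise A [measurement_noise_spec()]; default noise-free targets.
#' @param bundles Bundle subset used for calibration (default
#'   [reduced_bundle_set()]).
#' @param control Solver control list.
#' @return An object of class `comparison_report`; key fields:
#'   `ap_laxity_rmsd_mm` (RMSD of AP translation between the two calibrated
#'   models over the six AP-laxity conditions), `pivot_rotation_max_diff_deg`,
#'   `pivot_translation_max_diff_mm`, passive-flexion RMSDs, ligament-load
#'   RMSD, parameter recovery errors, and dislocation flags.
#' @export
run_replication <- function(seed = 42,
                            budget = list(pso_particles = 15,
                                          pso_iterations = 40,
                                          nm_iterations = 100),
                            knee_spec = synthetic_knee_spec(seed = seed),
                            noise = measurement_noise_spec(0, 0, seed = seed),
                            bundles = reduced_bundle_set(),
                            control = list()) {
  model <- reduce_bundles(generate_knee(knee_spec), bundles)
  truth <- sample_ground_truth(parameter_bounds(model), seed = seed + 1L)
  truth_model <- set_parameters(model, truth)

  meas_kla <- generate_measurements(truth_model, "KLA", noise = noise,
                                    control = control)
  meas_rks <- generate_measurements(truth_model, "RKS", noise = noise,
                                    control = control)
  targets_kla <- build_targets(meas_kla, "KLA")
  targets_rks <- build_targets(meas_rks, "RKS")

  cal_kla <- calibrate(model, targets_kla, budget = budget, seed = seed + 2L,
                       control = control)
  cal_rks <- calibrate(model, targets_rks, budget = budget, seed = seed + 3L,
                       control = control)

  ap_kla <- simulate_ap_laxity(cal_kla$model, control = control)
  ap_rks <- simulate_ap_laxity(cal_rks$model, control = control)
  ap_rmsd <- rmsd(ap_kla$AP_mm, ap_rks$AP_mm)
  load_cols <- names(bundle_groups())
  lig_rmsd <- rmsd(unlist(ap_kla[, load_cols]), unlist(ap_rks[, load_cols]))

  pf_kla <- simulate_passive_flexion(cal_kla$model, control = control)
  pf_rks <- simulate_passive_flexion(cal_rks$model, control = control)
  passive_rmsd <- c(AP_mm = rmsd(pf_kla$AP_mm, pf_rks$AP_mm),
                    IE_deg = rmsd(pf_kla$IE_deg, pf_rks$IE_deg),
                    VrVl_deg = rmsd(pf_kla$VrVl_deg, pf_rks$VrVl_deg))

  ps_kla <- simulate_pivot_shift(cal_kla$model, control = control)
  ps_rks <- simulate_pivot_shift(cal_rks$model, control = control)
  psd_kla <- simulate_pivot_shift(cal_kla$model, acl_deficient = TRUE,
                                  control = control)
  psd_rks <- simulate_pivot_shift(cal_rks$model, acl_deficient = TRUE,
                                  control = control)
  rot_diff <- max(abs(ps_kla$coords[["varus_valgus"]] -
                        ps_rks$coords[["varus_valgus"]]),
                  abs(ps_kla$coords[["internal_external"]] -
                        ps_rks$coords[["internal_external"]]))
  trn_diff <- max(abs(ps_kla$coords[["medial_lateral"]] -
                        ps_rks$coords[["medial_lateral"]]),
                  abs(ps_kla$coords[["anterior_posterior"]] -
                        ps_rks$coords[["anterior_posterior"]]))

  rel_err <- function(cal) abs(cal$parameters - truth) / abs(truth)
  structure(list(
    seed = seed,
    bundles = bundles,
    budget = budget,
    truth = truth,
    calibration_kla = cal_kla,
    calibration_rks = cal_rks,
    targets_kla = targets_kla,
    targets_rks = targets_rks,
    ap_laxity_kla = ap_kla,
    ap_laxity_rks = ap_rks,
    ap_laxity_rmsd_mm = ap_rmsd,
    ligament_load_rmsd_N = lig_rmsd,
    passive_flexion_rmsd = passive_rmsd,
    pivot_shift = list(intact_kla = ps_kla, intact_rks = ps_rks,
                       deficient_kla = psd_kla, deficient_rks = psd_rks),
    pivot_rotation_max_diff_deg = rot_diff,
    pivot_translation_max_diff_mm = trn_diff,
    dislocation_flags = c(intact_kla = ps_kla$dislocated,
                          intact_rks = ps_rks$dislocated,
                          deficient_kla = psd_kla$dislocated,
                          deficient_rks = psd_rks$dislocated),
    parameter_rel_error = list(kla = rel_err(cal_kla), rks = rel_err(cal_rks))
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("KLA-vs-RKS replication on a synthetic knee (seed", x$seed, ")\n")
  cat(sprintf("  AP laxity RMSD between calibrations: %.3f mm\n",
              x$ap_laxity_rmsd_mm))
  cat(sprintf("  pivot-shift rotation max diff:       %.3f deg\n",
              x$pivot_rotation_max_diff_deg))
  cat(sprintf("  pivot-shift translation max diff:    %.3f mm\n",
              x$pivot_translation_max_diff_mm))
  cat(sprintf("  passive flexion RMSD: AP %.2f mm, IE %.2f deg, VrVl %.2f deg\n",
              x$passive_flexion_rmsd[["AP_mm"]],
              x$passive_flexion_rmsd[["IE_deg"]],
              x$passive_flexion_rmsd[["VrVl_deg"]]))
  cat(sprintf("  ligament load RMSD (AP laxity): %.1f N\n",
              x$ligament_load_rmsd_N))
  cat("  dislocations:",
      paste(names(x$dislocation_flags)[x$dislocation_flags], collapse = ", "),
      "\n")
  invisible(x)
}

#' Serialize a comparison report to JSON
#'
#' Writes the scalar comparison metrics (not the full traces) machine-
#' readably.
#'
#' @param report A `comparison_report`.
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    seed = report$seed,
    ap_laxity_rmsd_mm = report$ap_laxity_rmsd_mm,
    pivot_rotation_max_diff_deg = report$pivot_rotation_max_diff_deg,
    pivot_translation_max_diff_mm = report$pivot_translation_max_diff_mm,
    passive_flexion_rmsd = as.list(report$passive_flexion_rmsd),
    ligament_load_rmsd_N = report$ligament_load_rmsd_N,
    dislocation_flags = as.list(report$dislocation_flags),
    calibration_costs = list(kla = report$calibration_kla$cost,
                             rks = report$calibration_rks$cost)
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
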