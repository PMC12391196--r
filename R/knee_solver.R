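#' Loading condition for a quasi-static knee simulation
#'
#' Flexion is prescribed (displacement control); the remaining five DOF are
#' in load control. Torques are in N m at the interface and converted to
#' N mm internally. A positive `torque_vrvl` is varus, positive `torque_ie`
#' internal, positive `force_ap` anterior tibial load, positive `force_si`
#' compressive.
#'
#' @param flexion_deg Prescribed knee flexion, degrees, in `[0, 120]`.
#' @param force_ap Anterior(+)/posterior AP force, N.
#' @param torque_ie Internal(+)/external torque, N m.
#' @param torque_vrvl Varus(+)/valgus torque, N m.
#' @param force_si Additional superior-inferior (compressive +) force, N,
#'   applied on top of the model's settling compression.
#' @param acl_deficient If `TRUE`, both ACL bundles are removed before
#'   loading (simulated complete tear); their reported forces are zero.
#' @return An object of class `load_case`.
#' @export
load_case <- function(flexion_deg = 0, force_ap = 0, torque_ie = 0,
                      torque_vrvl = 0, force_si = 0, acl_deficient = FALSE) {
  if (flexion_deg < 0 || flexion_deg > 120) {
    stop("flexion must lie in [0, 120] degrees")
  }
  structure(list(flexion_deg = flexion_deg, force_ap = force_ap,
                 torque_ie = torque_ie, torque_vrvl = torque_vrvl,
                 force_si = force_si, acl_deficient = acl_deficient),
            class = "load_case")
}

# internal: model with ACL bundles removed (complete-tear condition)
strip_acl <- function(model) {
  keep <- setdiff(names(model$bundles), c("ACL_AM", "ACL_PL"))
  model$bundles <- model$bundles[keep]
  model
}

# internal: load vector for the compiled core:
# (f_ap N, f_si N incl. settling compression, t_ie N*mm, t_vv N*mm)
loads_vector <- function(model, loads, scale = 1) {
  c(scale * loads$force_ap,
    model$settle_compression + scale * loads$force_si,
    scale * loads$torque_ie * 1000,
    scale * loads$torque_vrvl * 1000)
}

#' Total potential energy of the joint
#'
#' Sum of ligament fiber and contact strain energies minus the work of the
#' applied loads, in N mm. This is the scalar the equilibrium solver
#' minimizes over the five free DOF; it is evaluated here in plain R from
#' the constitutive laws, independently of the compiled solver core.
#'
#' @param model A [knee_model()].
#' @param coords A [gs_coords()] state.
#' @param loads A [load_case()]; its prescribed flexion is ignored in favor
#'   of the flexion in `coords`.
#' @return Potential energy, N mm.
#' @export
total_potential <- function(model, coords, loads = load_case()) {
  coords <- as_gs_coords(coords)
  if (loads$acl_deficient) model <- strip_acl(model)
  pose <- gs_compose(coords)
  e <- 0
  for (b in model$bundles) {
    w <- transform_point(pose, b$origins) - b$insertions
    len <- sqrt(rowSums(w^2))
    e <- e + sum(fiber_energy(len, zero_load_length(b$initial_length, b$r),
                              b$k, b$eps_l))
  }
  for (ce in model$contacts) {
    e <- e + contact_energy(contact_overclosure(pose, ce), ce)
  }
  lv <- loads_vector(model, loads)
  e - lv[1] * coords[["anterior_posterior"]] -
    lv[2] * coords[["superior_inferior"]] -
    lv[3] * deg2rad(coords[["internal_external"]]) -
    lv[4] * deg2rad(coords[["varus_valgus"]])
}

#' Contact overclosure for a pose
#'
#' Interpenetration depth (mm, negative when separated) of a condylar
#' contact element at a femur pose.
#'
#' @param pose A [rigid_pose()].
#' @param element A [contact_element()].
#' @return Overclosure, mm.
#' @export
contact_overclosure <- function(pose, element) {
  cw <- transform_point(pose, element$condyle_center)
  if (is.finite(element$dish_radius)) {
    m <- element$plateau_point + element$plateau_normal * element$dish_radius
    element$condyle_radius + sqrt(sum((cw - m)^2)) - element$dish_radius
  } else {
    element$condyle_radius - sum(element$plateau_normal * (cw - element$plateau_point))
  }
}

# internal: one minimization at fixed flexion/loads via the compiled core
minimize_at <- function(fe_deg, q, fm, cm, lv, control) {
  knee_minimize_cpp(deg2rad(fe_deg), q, fm, cm, lv,
                    tol = control$tol, max_iter = control$max_iter)
}

default_solver_control <- function(control = list()) {
  utils::modifyList(list(flexion_step = 5, load_substeps = 10, tol = 1e-3,
                         max_iter = 200), control)
}

#' Solve the quasi-static equilibrium for a load case
#'
#' Two-step continuation mirroring a loaded laxity trial: the joint first
#' settles under the model's SI compression at full extension, flexion is
#' then stepped to the prescribed angle in increments of at most
#' `flexion_step` degrees, and finally the target loads are ramped linearly
#' in `load_substeps` substeps. Each stage is an energy minimization over
#' the five free DOF (VrVl, IE, ML, AP, SI) with flexion fixed. A converged
#' state has residual (gradient) norm below `tol` (N, with rotational
#' residuals expressed as force equivalents over a 100 mm moment arm).
#'
#' @param model A [knee_model()].
#' @param loads A [load_case()].
#' @param initial Optional [gs_coords()] starting state (default: neutral).
#' @param warm Optional [gs_coords()] of a previously solved nearby state;
#'   when supplied the continuation is skipped and the solver starts there
#'   directly, falling back to full continuation if that fails to converge.
#' @param control List overriding `flexion_step`, `load_substeps`, `tol`,
#'   `max_iter`.
#' @return An object of class `equilibrium_result`: coordinates, per-bundle
#'   forces (N, fibers summed), per-side contact forces, residual norm, and
#'   `converged` / `dislocated` flags.
#' @export
solve_equilibrium <- function(model, loads, initial = NULL, warm = NULL,
                              control = list()) {
  control <- default_solver_control(control)
  sim_model <- if (loads$acl_deficient) strip_acl(model) else model
  fm <- fibers_matrix(sim_model)
  cm <- contacts_matrix(sim_model)
  lv_full <- loads_vector(sim_model, loads)
  fe <- loads$flexion_deg

  fit <- NULL
  if (!is.null(warm)) {
    qw <- as_gs_coords(warm)
    q <- c(deg2rad(qw[["varus_valgus"]]), deg2rad(qw[["internal_external"]]),
           qw[["medial_lateral"]], qw[["anterior_posterior"]],
           qw[["superior_inferior"]])
    fit <- minimize_at(fe, q, fm, cm, lv_full, control)
    if (!fit$converged) fit <- NULL
  }

  if (is.null(fit)) {
    if (is.null(initial)) initial <- gs_coords()
    ci <- as_gs_coords(initial)
    q <- c(deg2rad(ci[["varus_valgus"]]), deg2rad(ci[["internal_external"]]),
           ci[["medial_lateral"]], ci[["anterior_posterior"]],
           ci[["superior_inferior"]])
    fe0 <- ci[["flexion_extension"]]
    # settle: compression only at the starting flexion
    lv0 <- loads_vector(sim_model, load_case(flexion_deg = fe0))
    fit <- minimize_at(fe0, q, fm, cm, lv0, control)
    q <- fit$q
    # flexion continuation
    n_fe <- max(1L, ceiling(abs(fe - fe0) / control$flexion_step))
    for (f in seq(fe0, fe, length.out = n_fe + 1)[-1]) {
      fit <- minimize_at(f, q, fm, cm, lv0, control)
      q <- fit$q
    }
    # load ramp
    for (s in seq_len(control$load_substeps) / control$load_substeps) {
      lv <- loads_vector(sim_model, loads, scale = s)
      fit <- minimize_at(fe, q, fm, cm, lv, control)
      q <- fit$q
    }
  }

  q <- fit$q
  coords <- gs_coords(fe, rad2deg(q[1]), rad2deg(q[2]), q[3], q[4], q[5])
  st <- knee_state_cpp(deg2rad(fe), q, fm, cm)
  bundle_forces <- stats::setNames(rep(0, length(model$bundles)),
                                   names(model$bundles))
  agg <- tapply(st$forces, attr(fm, "bundle"), sum)
  bundle_forces[names(agg)] <- agg
  contact_forces <- stats::setNames(
    st$contact_forces, vapply(sim_model$contacts, function(ce) ce$side,
                              character(1)))
  lim <- model$joint_limits
  ml <- q[3]; ap <- q[4]; si <- q[5]
  limit_hit_ml_si <- ml <= lim$ml[1] || ml >= lim$ml[2] ||
    si <= lim$si[1] || si >= lim$si[2]
  dislocated <- limit_hit_ml_si || ap <= lim$ap[1] || ap >= lim$ap[2]

  structure(list(
    coords = coords,
    bundle_forces = bundle_forces,
    contact_forces = contact_forces,
    residual_norm = fit$residual,
    energy = fit$energy,
    converged = isTRUE(fit$converged),
    dislocated = dislocated,
    limit_hit_ml_si = limit_hit_ml_si,
    loads = loads
  ), class = "equilibrium_result")
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat(sprintf("equilibrium_result: converged=%s dislocated=%s residual=%.2e\n",
              x$converged, x$dislocated, x$residual_norm))
  print(x$coords)
  loaded <- x$bundle_forces[x$bundle_forces > 0.05]
  if (length(loaded)) {
    cat("  loaded bundles (N):",
        paste(sprintf("%s=%.1f", names(loaded), loaded), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Ligament loads summed into reporting groups
#'
#' Sums per-bundle forces into the nine reporting groups (ACL, ALS, LCL,
#' MCL_S, MCL_D, POL, PCAP, PCL, PFL); see [bundle_groups()].
#'
#' @param result An [solve_equilibrium()] result (or a named per-bundle
#'   force vector).
#' @return Named numeric vector of group forces, N.
#' @export
bundle_group_forces <- function(result) {
  bf <- if (inherits(result, "equilibrium_result")) result$bundle_forces else result
  vapply(bundle_groups(), function(members) {
    sum(bf[intersect(members, names(bf))])
  }, numeric(1))
}

#' Simulate an anterior-posterior laxity protocol
#'
#' Applies `+magnitude` and `-magnitude` N AP loads at each flexion angle
#' (clinical default 133 N at 30/60/90 degrees) and records the settled
#' kinematics and ligament group loads.
#'
#' @param model A [knee_model()].
#' @param angles Flexion angles, degrees.
#' @param magnitude AP load magnitude, N.
#' @param control Solver control list (see [solve_equilibrium()]).
#' @return A data frame with one row per (direction, angle): the six joint
#'   coordinates plus group loads; the full `equilibrium_result` objects are
#'   attached as attribute `"results"`.
#' @export
simulate_ap_laxity <- function(model, angles = c(30, 60, 90), magnitude = 133,
                               control = list()) {
  cases <- expand.grid(direction = c("anterior", "posterior"),
                       flexion_deg = angles, stringsAsFactors = FALSE)
  cases <- cases[order(cases$flexion_deg, cases$direction), ]
  results <- vector("list", nrow(cases))
  rows <- vector("list", nrow(cases))
  for (i in seq_len(nrow(cases))) {
    f_ap <- if (cases$direction[i] == "anterior") magnitude else -magnitude
    lc <- load_case(flexion_deg = cases$flexion_deg[i], force_ap = f_ap)
    results[[i]] <- solve_equilibrium(model, lc, control = control)
    gf <- bundle_group_forces(results[[i]])
    rows[[i]] <- cbind(
      data.frame(direction = cases$direction[i],
                 flexion_deg = cases$flexion_deg[i], force_ap = f_ap,
                 converged = results[[i]]$converged,
                 dislocated = results[[i]]$dislocated),
      coords_to_row(results[[i]]$coords),
      as.data.frame(as.list(gf))
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}

#' Simulate passive flexion
#'
#' Prescribes flexion from 0 to `max_flexion` degrees in `step`-degree
#' increments with zero applied loads (settling compression only) and
#' records the joint coordinates at each angle.
#'
#' @param model A [knee_model()].
#' @param max_flexion Final flexion angle, degrees.
#' @param step Flexion increment, degrees.
#' @param control Solver control list.
#' @return Data frame of joint coordinates per flexion angle (columns as in
#'   [write_kinematics_csv()]).
#' @export
simulate_passive_flexion <- function(model, max_flexion = 90, step = 5,
                                     control = list()) {
  angles <- seq(0, max_flexion, by = step)
  rows <- vector("list", length(angles))
  warm <- NULL
  for (i in seq_along(angles)) {
    res <- solve_equilibrium(model, load_case(flexion_deg = angles[i]),
                             warm = warm, control = control)
    warm <- res$coords
    rows[[i]] <- cbind(coords_to_row(res$coords),
                       data.frame(converged = res$converged,
                                  dislocated = res$dislocated))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a pivot-shift test
#'
#' Clinical provocation at 30 degrees flexion: 8 N m valgus torque combined
#' with 4 N m internal torque. With `acl_deficient = TRUE` both ACL bundles
#' are removed before loading (their reported forces are exactly zero),
#' emulating a complete tear.
#'
#' @param model A [knee_model()].
#' @param acl_deficient Simulate the ACL-deficient condition.
#' @param control Solver control list.
#' @return An `equilibrium_result`.
#' @export
simulate_pivot_shift <- function(model, acl_deficient = FALSE,
                                 control = list()) {
  lc <- load_case(flexion_deg = 30, torque_vrvl = -8, torque_ie = 4,
                  acl_deficient = acl_deficient)
  solve_equilibrium(model, lc, control = control)
}
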