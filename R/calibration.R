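# Calibration targets, the grouped percentile-weighted cost, and the
# two-phase (particle swarm + simplex) parameter calibration driver.

dof_keys <- c(VrVl = "VrVl_deg", IE = "IE_deg", ML = "ML_mm",
              AP = "AP_mm", SI = "SI_mm")

#' Build calibration targets from a laxity measurement table
#'
#' Validates and groups a measurement table (the format written by
#' [generate_measurements()]) into calibration targets. KLA-style tables
#' carry anterior and internal-external groups at 30 and 90 degrees (no
#' posterior loading); RKS-style tables carry AP, IE and VrVl groups at
#' 0/30/60/90 degrees at the maximum and minimum loads. Both carry a
#' passive full-extension target. When `substitute_75_for_90 = TRUE`,
#' groups recorded at 75 degrees satisfy the 90-degree requirement.
#'
#' @param measurements Measurement data frame.
#' @param source `"KLA"` or `"RKS"`.
#' @param substitute_75_for_90 Accept 75-degree groups in place of
#'   90-degree ones.
#' @return The validated target table (class `laxity_targets`), one row per
#'   target trial.
#' @export
build_targets <- function(measurements, source = c("KLA", "RKS"),
                          substitute_75_for_90 = FALSE) {
  source <- match.arg(source)
  req_cols <- c("group_id", "flexion_deg", "force_ap_N", "torque_ie_Nm",
                "torque_vrvl_Nm", "force_si_N", unname(dof_keys))
  if (is.null(measurements) || nrow(measurements) == 0) {
    stop(sprintf("empty measurement table: no targets for groups [%s]",
                 paste(expected_groups(source), collapse = ", ")))
  }
  missing_cols <- setdiff(req_cols, names(measurements))
  if (length(missing_cols)) {
    stop("measurement table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!all(is.finite(as.matrix(measurements[, unname(dof_keys)])))) {
    stop("measured kinematics must be finite")
  }
  expected <- expected_groups(source)
  have <- unique(measurements$group_id)
  if (substitute_75_for_90) {
    have <- unique(c(have, sub("@75$", "@90", have)))
  }
  absent <- setdiff(expected, have)
  if (length(absent)) {
    stop("no targets for groups: ", paste(absent, collapse = ", "))
  }
  if (source == "KLA" && any(measurements$force_ap_N < 0)) {
    stop("KLA targets carry no posterior loading")
  }
  measurements$source <- source
  class(measurements) <- c("laxity_targets", class(measurements))
  measurements
}

expected_groups <- function(source) {
  if (source == "KLA") {
    c(paste0("anterior@", c(30, 90)), paste0("ie@", c(30, 90)), "passive@0")
  } else {
    c(paste0(rep(c("ap", "ie", "vrvl"), each = 4), "@", c(0, 30, 60, 90)),
      "passive@0")
  }
}

#' Calibration cost configuration
#'
#' The grouped cost: per (group, DOF) the chosen percentile of per-target
#' absolute errors is normalized by that DOF's observed experimental range,
#' scaled by a weight, and summed; the total is squared once if any trial
#' reached an SI or ML joint limit.
#'
#' @param weights Named numeric vector keyed `"group:DOF"` (DOF in
#'   `VrVl, IE, ML, AP, SI`), e.g. `c("anterior@30:AP" = 1)`.
#' @param percentile Percentile of per-target absolute errors per (group,
#'   DOF), in (0, 100]; default 75.
#' @param ranges Named per-DOF normalization ranges (mm / deg), > 0 for
#'   every weighted DOF.
#' @return An object of class `cost_config`.
#' @export
cost_config <- function(weights, percentile = 75, ranges) {
  stopifnot(length(weights) > 0, !is.null(names(weights)), all(weights >= 0),
            percentile > 0, percentile <= 100)
  used_dof <- unique(sub("^.*:", "", names(weights)[weights > 0]))
  if (!all(used_dof %in% names(dof_keys))) {
    stop("unknown DOF in weights: ", paste(setdiff(used_dof, names(dof_keys)),
                                           collapse = ", "))
  }
  if (!all(used_dof %in% names(ranges)) || any(ranges[used_dof] <= 0)) {
    stop("normalization range missing or non-positive for a weighted DOF")
  }
  structure(list(weights = weights, percentile = percentile,
                 ranges = ranges), class = "cost_config")
}

#' Default cost configuration for a target table
#'
#' Weights follow the primary/secondary DOF convention of the laxity
#' groups: the loaded DOF of a group gets weight 1.0 and its stated
#' secondary DOF 0.5 (IE for AP-loaded groups, AP for IE-loaded groups);
#' the passive full-extension group weights AP, IE and VrVl equally at 1.0.
#' Normalization ranges are the min-to-max span of each measured DOF across
#' all experimental targets.
#'
#' @param targets A target table from [build_targets()].
#' @return A [cost_config()].
#' @export
default_cost_config <- function(targets) {
  groups <- unique(targets$group_id)
  w <- c()
  for (g in groups) {
    kind <- sub("@.*$", "", g)
    gw <- switch(kind,
                 anterior = , ap = c(AP = 1, IE = 0.5),
                 ie = c(IE = 1, AP = 0.5),
                 vrvl = c(VrVl = 1),
                 passive = c(AP = 1, IE = 1, VrVl = 1),
                 stop("unrecognized group kind: ", kind))
    w <- c(w, stats::setNames(gw, paste0(g, ":", names(gw))))
  }
  ranges <- vapply(dof_keys, function(col) {
    r <- diff(range(targets[[col]]))
    max(r, 1e-6)
  }, numeric(1))
  names(ranges) <- names(dof_keys)
  cost_config(w, percentile = 75, ranges = ranges)
}

#' Cost breakdown from a table of per-target errors
#'
#' The arithmetic core of the calibration cost, separated from simulation:
#' given one signed error per (target, DOF), computes for each weighted
#' (group, DOF) the `percentile` (linear interpolation between order
#' statistics) of absolute errors, normalizes by the DOF range, scales by
#' the weight, and sums. If `penalty = TRUE` (a trial reached an ML or SI
#' joint limit) the summed cost is squared once.
#'
#' @param errors Data frame with columns `group_id`, `dof` (one of
#'   `VrVl, IE, ML, AP, SI`) and `error` (signed, mm / deg).
#' @param config A [cost_config()].
#' @param penalty Whether the joint-limit penalty fires.
#' @return List of class `cost_breakdown`: `table` (per group/DOF percentile,
#'   normalized and weighted errors), `penalty_applied`, `unpenalized`,
#'   `total`.
#' @export
#' @examples
#' cfg <- cost_config(c("anterior@30:AP" = 2), ranges = c(AP = 10))
#' err <- data.frame(group_id = "anterior@30", dof = "AP", error = 1:4)
#' cost_breakdown(err, cfg)$total                   # 2 * 3.25 / 10 = 0.65
#' cost_breakdown(err, cfg, penalty = TRUE)$total   # 0.65^2 = 0.4225
cost_breakdown <- function(errors, config, penalty = FALSE) {
  stopifnot(inherits(config, "cost_config"),
            all(c("group_id", "dof", "error") %in% names(errors)))
  wpos <- config$weights[config$weights > 0]
  keys <- names(wpos)
  rows <- lapply(keys, function(key) {
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    g <- parts[1]; dof <- parts[2]
    e <- abs(errors$error[errors$group_id == g & errors$dof == dof])
    if (length(e) == 0) return(NULL)
    p <- unname(stats::quantile(e, config$percentile / 100, type = 7))
    norm <- p / config$ranges[[dof]]
    data.frame(group_id = g, dof = dof, n = length(e), percentile_error = p,
               normalized_error = norm, weight = unname(wpos[[key]]),
               weighted_error = unname(wpos[[key]]) * norm,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  unpen <- if (is.null(tab)) 0 else sum(tab$weighted_error)
  total <- if (penalty) unpen^2 else unpen
  structure(list(table = tab, penalty_applied = penalty,
                 unpenalized = unpen, total = total),
            class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat(sprintf("cost_breakdown: total = %.6g (penalty %s)\n", x$total,
              if (x$penalty_applied) "applied" else "not applied"))
  if (!is.null(x$table)) print(x$table, row.names = FALSE)
  invisible(x)
}

# internal: simulate every target for a candidate model, using a warm-start
# cache (environment keyed by target row) carried across cost evaluations
simulate_targets <- function(model, targets, control = list(), cache = NULL) {
  n <- nrow(targets)
  sim <- matrix(NA_real_, n, length(dof_keys),
                dimnames = list(NULL, names(dof_keys)))
  converged <- logical(n)
  limit_hit <- logical(n)
  for (i in seq_len(n)) {
    lc <- load_case(flexion_deg = targets$flexion_deg[i],
                    force_ap = targets$force_ap_N[i],
                    torque_ie = targets$torque_ie_Nm[i],
                    torque_vrvl = targets$torque_vrvl_Nm[i],
                    force_si = targets$force_si_N[i])
    key <- as.character(i)
    warm <- if (!is.null(cache)) cache[[key]] else NULL
    res <- solve_equilibrium(model, lc, warm = warm, control = control)
    if (!is.null(cache) && res$converged) cache[[key]] <- res$coords
    co <- res$coords
    sim[i, ] <- c(co[["varus_valgus"]], co[["internal_external"]],
                  co[["medial_lateral"]], co[["anterior_posterior"]],
                  co[["superior_inferior"]])
    converged[i] <- res$converged
    limit_hit[i] <- res$limit_hit_ml_si
  }
  list(sim = sim, converged = converged, limit_hit = limit_hit)
}

#' Evaluate the calibration cost of a model against targets
#'
#' Simulates every target trial (settled equilibrium at the target's
#' prescribed flexion and loads) and scores the grouped percentile cost.
#' Targets whose simulation fails to converge contribute a worst-case error
#' equal to the DOF's normalization range. Any trial that reaches an ML or
#' SI joint limit fires the squaring penalty.
#'
#' @param model A [knee_model()].
#' @param targets A target table from [build_targets()].
#' @param config A [cost_config()]; default [default_cost_config()].
#' @param control Solver control list.
#' @param cache Optional environment carrying warm-start states across
#'   repeated evaluations (used by [calibrate()]).
#' @return A `cost_breakdown` (see [cost_breakdown()]) with the per-target
#'   error table attached as attribute `"errors"`.
#' @export
evaluate_cost <- function(model, targets, config = default_cost_config(targets),
                          control = list(), cache = NULL) {
  st <- simulate_targets(model, targets, control = control, cache = cache)
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    err <- st$sim[i, ] - c(targets$VrVl_deg[i], targets$IE_deg[i],
                           targets$ML_mm[i], targets$AP_mm[i],
                           targets$SI_mm[i])
    if (!st$converged[i]) err <- config$ranges[names(dof_keys)]
    data.frame(target = i, group_id = targets$group_id[i],
               dof = names(dof_keys), error = unname(err),
               stringsAsFactors = FALSE)
  })
  errors <- do.call(rbind, rows)
  bd <- cost_breakdown(errors, config, penalty = any(st$limit_hit))
  attr(bd, "errors") <- errors
  attr(bd, "converged") <- st$converged
  bd
}

#' Two-phase ligament parameter calibration
#'
#' Phase 1 runs a bounded particle swarm over the model's design variables
#' (reference-length ratios and stiffnesses); phase 2 polishes the swarm
#' best with a bound-projected Nelder-Mead simplex. The objective is the
#' grouped percentile cost of [evaluate_cost()]; warm-start states are
#' carried across evaluations to keep each cost evaluation a set of small
#' equilibrium corrections.
#'
#' @param model A [knee_model()] template (its current parameters are
#'   ignored; bounds come from its design-variable table).
#' @param targets A target table from [build_targets()].
#' @param config A [cost_config()].
#' @param budget List with `pso_particles`, `pso_iterations`,
#'   `nm_iterations` (scaled-down defaults 15 / 40 / 100) and optionally
#'   `nm_restarts` (default 1): additional simplex runs re-expanded around
#'   the incumbent best.
#' @param seed RNG seed (PSO initialization and updates).
#' @param control Solver control list.
#' @return An object of class `calibration_result`: `parameters` (named
#'   vector), `cost`, `cost_trace` (best-so-far, both phases), `phase_boundary`
#'   (index of the PSO-to-simplex switch in the trace), `seed`,
#'   `n_evaluations`, and the final `breakdown`.
#' @export
calibrate <- function(model, targets, config = default_cost_config(targets),
                      budget = list(pso_particles = 15, pso_iterations = 40,
                                    nm_iterations = 100),
                      seed = 1, control = list()) {
  stopifnot(nrow(targets) > 0)
  bounds <- parameter_bounds(model)
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  objective <- function(x) {
    n_eval <<- n_eval + 1L
    m <- set_parameters(model, x)
    evaluate_cost(m, targets, config, control = control, cache = cache)$total
  }
  ps <- particle_swarm(objective, bounds,
                       n_particles = budget$pso_particles,
                       n_iterations = budget$pso_iterations, seed = seed)
  restarts <- if (is.null(budget$nm_restarts)) 1L else budget$nm_restarts
  nm <- list(par = ps$par, value = ps$value, trace = numeric(0))
  if (budget$nm_iterations > 0) {
    # restarting the simplex re-expands it around the incumbent, escaping
    # the degenerate simplices a single long run can collapse into
    for (rs in seq_len(restarts)) {
      run <- nelder_mead(objective, nm$par, bounds,
                         n_iterations = budget$nm_iterations)
      run$trace <- c(nm$trace, run$trace)
      nm <- if (run$value <= nm$value) run else
        list(par = nm$par, value = nm$value, trace = run$trace)
    }
  }
  best <- if (nm$value <= ps$value) nm$par else ps$par
  final_model <- set_parameters(model, best)
  bd <- evaluate_cost(final_model, targets, config, control = control,
                      cache = cache)
  structure(list(
    parameters = best,
    model = final_model,
    cost = min(nm$value, ps$value),
    cost_trace = c(ps$trace, cummin(c(ps$value, nm$trace))[-1]),
    phase_boundary = length(ps$trace),
    seed = seed,
    n_evaluations = n_eval,
    breakdown = bd
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration_result: cost %.5g after %d evaluations (seed %d)\n",
              x$cost, x$n_evaluations, x$seed))
  print(round(x$parameters, 4))
  invisible(x)
}

#' Write a calibration target table to CSV
#'
#' @param targets Target table.
#' @param path Output path.
#' @export
write_targets_csv <- function(targets, path) {
  utils::write.csv(as.data.frame(targets), path, row.names = FALSE)
  invisible(path)
}

#' Read a calibration target table from CSV
#'
#' @param path CSV path.
#' @param source `"KLA"` or `"RKS"`.
#' @param ... Passed to [build_targets()].
#' @return Target table.
#' @export
read_targets_csv <- function(path, source, ...) {
  build_targets(utils::read.csv(path, stringsAsFactors = FALSE), source, ...)
}
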