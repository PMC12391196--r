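#' Tibiofemoral knee model
#'
#' Bundles a femur/tibia frame pair, a set of ligament bundles, two condylar
#' contact elements, per-DOF joint limits and the settling compression into
#' one quasi-static model object. The tibia is fixed; the femur pose is
#' parameterized by Grood-Suntay coordinates.
#'
#' @param bundles List of [ligament_bundle()] objects with distinct names
#'   drawn from [bundle_names()].
#' @param contacts List of two [contact_element()]s (medial and lateral).
#' @param femur_frame,tibia_frame [body_frame()] objects (default identity;
#'   all geometry is expressed in the tibia frame with coincident frames at
#'   the initial full-extension pose).
#' @param joint_limits Named list with elements `ml`, `ap`, `si`, each a
#'   length-2 numeric `(lower, upper)` in mm. Reaching a limit flags a
#'   dislocation and (for ML/SI) fires the calibration penalty.
#' @param settle_compression Settling compression, N (default 50). Applied
#'   as a positive SI load, which compresses the femur into the tibia.
#' @param side `"left"` or `"right"`; geometry is stored in the left-knee
#'   convention and right knees are mirrored at construction.
#' @return An object of class `knee_model`.
#' @export
knee_model <- function(bundles, contacts, femur_frame = body_frame(),
                       tibia_frame = body_frame(),
                       joint_limits = list(ml = c(-15, 15), ap = c(-15, 15),
                                           si = c(-5, 10)),
                       settle_compression = 50, side = "left") {
  side <- match.arg(side, c("left", "right"))
  nms <- vapply(bundles, function(b) b$name, character(1))
  if (anyDuplicated(nms)) stop("duplicate bundle names")
  if (!all(nms %in% bundle_names())) stop("unknown bundle name")
  names(bundles) <- nms
  stopifnot(length(contacts) == 2)
  sides <- vapply(contacts, function(ce) ce$side, character(1))
  if (!setequal(sides, c("medial", "lateral"))) {
    stop("need one medial and one lateral contact element")
  }
  for (nm in c("ml", "ap", "si")) {
    lim <- joint_limits[[nm]]
    if (is.null(lim) || length(lim) != 2 || lim[1] >= lim[2]) {
      stop("joint_limits must contain (lower, upper) pairs for ml, ap, si")
    }
  }
  m <- structure(list(
    femur_frame = femur_frame,
    tibia_frame = tibia_frame,
    bundles = bundles,
    contacts = contacts,
    joint_limits = joint_limits,
    settle_compression = settle_compression,
    side = side
  ), class = "knee_model")
  if (side == "right") m <- mirror_knee(m)
  m
}

#' @export
print.knee_model <- function(x, ...) {
  nf <- sum(vapply(x$bundles, function(b) nrow(b$origins), integer(1)))
  cat(sprintf("knee_model (%s): %d bundles, %d fibers, %d contact elements\n",
              x$side, length(x$bundles), nf, length(x$contacts)))
  cat("  bundles:", paste(names(x$bundles), collapse = ", "), "\n")
  cat(sprintf("  settle compression: %g N\n", x$settle_compression))
  invisible(x)
}

#' Mirror a knee model about the sagittal plane
#'
#' Negates the medial-lateral coordinate of every attachment and contact
#' point, converting a left-knee geometry to a right-knee one (and vice
#' versa). Joint coordinates of the mirrored model relate to the original by
#' [gs_mirror()].
#'
#' @param model A [knee_model()].
#' @return The mirrored model.
#' @export
mirror_knee <- function(model) {
  flipx <- function(p) { p[1] <- -p[1]; p }
  model$bundles <- lapply(model$bundles, function(b) {
    b$origins[, 1] <- -b$origins[, 1]
    b$insertions[, 1] <- -b$insertions[, 1]
    b
  })
  model$contacts <- lapply(model$contacts, function(ce) {
    ce$condyle_center <- flipx(ce$condyle_center)
    ce$plateau_point <- flipx(ce$plateau_point)
    ce$plateau_normal <- flipx(ce$plateau_normal)
    ce$side <- if (ce$side == "medial") "lateral" else "medial"
    ce
  })
  model
}

# internal: table of paper-style design variables restricted to the model's
# bundle set. Stiffness variables shared between sMCL fibers stay shared.
design_variable_table <- function(model) {
  t3 <- load_table3()
  t3 <- t3[t3$abbrev %in% names(model$bundles), , drop = FALSE]
  strain <- data.frame(
    dv = t3$strain_dv, type = "reference_strain", bundles = I(as.list(t3$abbrev)),
    lo = t3$strain_lo, hi = t3$strain_hi, stringsAsFactors = FALSE
  )
  stiff_split <- split(t3, t3$stiffness_dv)
  stiff <- do.call(rbind, lapply(stiff_split, function(d) {
    data.frame(dv = d$stiffness_dv[1], type = "stiffness",
               bundles = I(list(d$abbrev)), lo = d$stiffness_lo[1],
               hi = d$stiffness_hi[1], stringsAsFactors = FALSE)
  }))
  out <- rbind(strain, stiff)
  # order by numeric design-variable index (X1, X2, ...)
  out[order(as.integer(sub("^X", "", out$dv))), , drop = FALSE]
}

#' Current design-variable values of a model
#'
#' @param model A [knee_model()].
#' @return Named numeric vector over the model's design variables (the full
#'   14-bundle model has the 26 variables X1-X26: 14 reference-length
#'   ratios then 12 stiffnesses, the three superficial MCL fibers sharing
#'   one stiffness variable).
#' @export
get_parameters <- function(model) {
  dvt <- design_variable_table(model)
  vals <- vapply(seq_len(nrow(dvt)), function(i) {
    b <- model$bundles[[dvt$bundles[[i]][1]]]
    if (dvt$type[i] == "reference_strain") b$r else b$k
  }, numeric(1))
  stats::setNames(vals, dvt$dv)
}

#' Set design-variable values on a model
#'
#' @param model A [knee_model()].
#' @param x Numeric vector in the order of [get_parameters()] (names, if
#'   present, are checked).
#' @return The updated model.
#' @export
set_parameters <- function(model, x) {
  dvt <- design_variable_table(model)
  if (length(x) != nrow(dvt)) {
    stop(sprintf("expected %d design variables, got %d", nrow(dvt), length(x)))
  }
  if (!is.null(names(x)) && any(names(x) != "") &&
      !identical(names(x), dvt$dv)) {
    x <- x[dvt$dv]
  }
  for (i in seq_len(nrow(dvt))) {
    for (nm in dvt$bundles[[i]]) {
      if (dvt$type[i] == "reference_strain") {
        model$bundles[[nm]]$r <- unname(x[i])
      } else {
        model$bundles[[nm]]$k <- unname(x[i])
      }
    }
  }
  model
}

#' Design-variable bounds of a model
#'
#' @param model A [knee_model()].
#' @return Two-column matrix (`lo`, `hi`) with design-variable rownames.
#' @export
parameter_bounds <- function(model) {
  dvt <- design_variable_table(model)
  matrix(c(dvt$lo, dvt$hi), ncol = 2,
         dimnames = list(dvt$dv, c("lo", "hi")))
}

# internal: assemble the fiber array consumed by the compiled solver.
# columns: origin(3), insertion(3), L0, k, eps_l; attribute "bundle" maps
# rows to bundle names.
fibers_matrix <- function(model) {
  rows <- lapply(model$bundles, function(b) {
    n <- nrow(b$origins)
    cbind(b$origins, b$insertions,
          zero_load_length(b$initial_length, b$r),
          rep(b$k, n), rep(b$eps_l, n))
  })
  fm <- do.call(rbind, rows)
  attr(fm, "bundle") <- rep(names(model$bundles),
                            vapply(model$bundles, function(b) nrow(b$origins),
                                   integer(1)))
  fm
}

# internal: contact array for the compiled solver
contacts_matrix <- function(model) {
  do.call(rbind, lapply(model$contacts, function(ce) {
    c(ce$condyle_center, ce$condyle_radius, ce$plateau_point,
      ce$plateau_normal, ce$dish_radius, ce$slopes, ce$breakpoints)
  }))
}

#' Write a knee model configuration to JSON
#'
#' Round-trips geometry, material parameters, contact laws, joint limits and
#' the settling compression.
#'
#' @param model A [knee_model()].
#' @param path Output path.
#' @export
write_knee_model <- function(model, path) {
  cfg <- list(
    side = model$side,
    settle_compression = model$settle_compression,
    joint_limits = model$joint_limits,
    bundles = lapply(model$bundles, function(b) {
      list(name = b$name, origins = b$origins, insertions = b$insertions,
           r = b$r, k = b$k, eps_l = b$eps_l)
    }),
    contacts = lapply(model$contacts, function(ce) {
      list(side = ce$side, condyle_center = ce$condyle_center,
           condyle_radius = ce$condyle_radius,
           plateau_point = ce$plateau_point,
           plateau_normal = ce$plateau_normal,
           dish_radius = if (is.finite(ce$dish_radius)) ce$dish_radius else "Inf",
           slopes = ce$slopes, breakpoints = ce$breakpoints,
           friction_mu = ce$friction_mu)
    })
  )
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a knee model configuration from JSON
#'
#' @param path Path written by [write_knee_model()].
#' @return A [knee_model()].
#' @export
read_knee_model <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  bundles <- lapply(cfg$bundles, function(b) {
    ligament_bundle(b$name, b$origins, b$insertions, r = b$r, k = b$k,
                    eps_l = b$eps_l)
  })
  contacts <- lapply(cfg$contacts, function(ce) {
    dr <- if (identical(ce$dish_radius, "Inf")) Inf else as.numeric(ce$dish_radius)
    contact_element(ce$side, ce$condyle_center, ce$condyle_radius,
                    ce$plateau_point, ce$plateau_normal, dr,
                    ce$slopes, ce$breakpoints, ce$friction_mu)
  })
  knee_model(bundles, contacts,
             joint_limits = lapply(cfg$joint_limits, as.numeric),
             settle_compression = cfg$settle_compression, side = cfg$side)
}

# internal: packaged transcription of the design-variable table (bundle,
# fiber count, bounds)
load_table3 <- function() {
  path <- system.file("extdata", "table3_design_variables.csv",
                      package = "kneelax", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Design-variable bounds from the packaged parameter table
#'
#' Loads the packaged transcription of the ligament design-variable table:
#' 26 variables (14 reference-length ratios, 12 stiffnesses; the three
#' superficial MCL fibers share one stiffness variable) with their
#' calibration bounds.
#'
#' @return A data frame with columns `dv`, `type`, `ligament`, `lo`, `hi`.
#' @export
#' @examples
#' b <- load_table3_bounds()
#' b[b$dv == "X1", ]
load_table3_bounds <- function() {
  t3 <- load_table3()
  strain <- data.frame(dv = t3$strain_dv, type = "reference_strain",
                       ligament = t3$abbrev, lo = t3$strain_lo,
                       hi = t3$strain_hi, stringsAsFactors = FALSE)
  sp <- split(t3, t3$stiffness_dv)
  stiff <- do.call(rbind, lapply(sp, function(d) {
    lig <- if (nrow(d) > 1) "sMCL" else d$abbrev[1]
    data.frame(dv = d$stiffness_dv[1], type = "stiffness", ligament = lig,
               lo = d$stiffness_lo[1], hi = d$stiffness_hi[1],
               stringsAsFactors = FALSE)
  }))
  out <- rbind(strain, stiff)
  out <- out[order(as.integer(sub("^X", "", out$dv))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
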