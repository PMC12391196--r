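#' Grood-Suntay joint coordinates
#'
#' Constructs the six tibiofemoral degrees of freedom in the clinical joint
#' coordinate system: three rotations (flexion-extension about the femoral
#' transepicondylar axis, internal-external about the tibial long axis,
#' varus-valgus about the mutually perpendicular floating axis) and three
#' translations measured along the same axes. Signs follow the clinical
#' convention: flexion, varus, internal rotation, medial, anterior and
#' superior are positive. Angles are degrees, translations millimetres.
#'
#' @param flexion_extension Flexion(+)/extension angle, degrees.
#' @param varus_valgus Varus(+)/valgus angle, degrees.
#' @param internal_external Internal(+)/external tibial rotation, degrees.
#' @param medial_lateral Medial(+)/lateral translation, mm.
#' @param anterior_posterior Anterior(+)/posterior tibial translation, mm.
#' @param superior_inferior Superior(+)/inferior translation, mm (positive
#'   compresses the joint under the internal sign convention; see the
#'   methods vignette for the full sign table).
#' @return An object of class `gs_coords`: a named numeric vector of length 6.
#' @export
#' @examples
#' gs_coords(flexion_extension = 30)
gs_coords <- function(flexion_extension = 0, varus_valgus = 0,
                      internal_external = 0, medial_lateral = 0,
                      anterior_posterior = 0, superior_inferior = 0) {
  x <- c(
    flexion_extension = as.numeric(flexion_extension),
    varus_valgus = as.numeric(varus_valgus),
    internal_external = as.numeric(internal_external),
    medial_lateral = as.numeric(medial_lateral),
    anterior_posterior = as.numeric(anterior_posterior),
    superior_inferior = as.numeric(superior_inferior)
  )
  if (!all(is.finite(x))) stop("all joint coordinates must be finite")
  ang <- x[1:3]
  if (any(ang <= -180 | ang > 180)) {
    stop("angles must lie in (-180, 180] degrees")
  }
  structure(x, class = "gs_coords")
}

#' @export
print.gs_coords <- function(x, ...) {
  cat("Grood-Suntay coordinates\n")
  cat(sprintf("  FE % 8.3f deg   VrVl % 8.3f deg   IE % 8.3f deg\n",
              x[["flexion_extension"]], x[["varus_valgus"]],
              x[["internal_external"]]))
  cat(sprintf("  ML % 8.3f mm    AP   % 8.3f mm    SI % 8.3f mm\n",
              x[["medial_lateral"]], x[["anterior_posterior"]],
              x[["superior_inferior"]]))
  invisible(x)
}

#' Anatomical body frame
#'
#' A local bone coordinate system: an origin and a right-handed orthonormal
#' axis triad (columns are the medial, anterior and superior axis directions
#' for a left knee).
#'
#' @param origin 3-vector, mm.
#' @param axes 3x3 orthonormal rotation matrix, columns = anatomical axes.
#' @return An object of class `body_frame`.
#' @export
body_frame <- function(origin = c(0, 0, 0), axes = diag(3)) {
  origin <- as.numeric(origin)
  axes <- unname(as.matrix(axes))
  stopifnot(length(origin) == 3, all(dim(axes) == c(3, 3)))
  if (max(abs(crossprod(axes) - diag(3))) > 1e-9) {
    stop("frame axes must be orthonormal")
  }
  if (det(axes) < 0) stop("frame axes must be right-handed")
  structure(list(origin = origin, axes = axes), class = "body_frame")
}

#' Rigid pose
#'
#' A proper rigid transform mapping femur-local coordinates into the tibia
#' frame: `x_tibia = rotation %*% x_femur + translation`.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation 3-vector, mm.
#' @return An object of class `rigid_pose`.
#' @export
rigid_pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- unname(as.matrix(rotation))
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8 || det(rotation) < 0) {
    stop("rotation must be a proper orthonormal matrix")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_pose")
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

rot_x <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3)
}
rot_y <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3)
}
rot_z <- function(a) {
  ca <- cos(a); sa <- sin(a)
  matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3)
}

# Internal signed Cardan angles (radians) for the left-knee convention:
# R = Rz(+IE) %*% Ry(-VrVl) %*% Rx(+FE), an intrinsic z-y'-x'' sequence whose
# last axis (x, the femoral medial-lateral / flexion axis) is body-fixed in
# the femur and whose first axis (z, the tibial long axis) is fixed in the
# tibia -- the Grood-Suntay joint axes.
gs_signed_angles <- function(coords) {
  c(a = deg2rad(coords[["flexion_extension"]]),
    b = -deg2rad(coords[["varus_valgus"]]),
    c = deg2rad(coords[["internal_external"]]))
}

# Joint translation axes for a rotation matrix: e1 = femoral flexion axis
# (first column of R), e3 = tibial long axis, e2 = floating axis.
gs_axes <- function(R) {
  e1 <- R[, 1]
  e3 <- c(0, 0, 1)
  u <- c(-e1[2], e1[1], 0)  # e3 x e1
  n <- sqrt(sum(u^2))
  if (n < 1e-12) stop("gimbal configuration: |VrVl| = 90 degrees")
  list(e1 = e1, e2 = u / n, e3 = e3)
}

#' Compose a rigid pose from Grood-Suntay coordinates
#'
#' Builds the femur pose relative to the fixed tibia frame that realizes the
#' given joint coordinates, with rotations applied as the intrinsic sequence
#' internal-external (tibial long axis), varus-valgus (floating axis),
#' flexion (femoral transepicondylar axis), and translations measured along
#' the same three axes.
#'
#' @param coords A [gs_coords()] object (or coercible named vector).
#' @return A [rigid_pose()].
#' @export
#' @examples
#' p <- gs_compose(gs_coords(flexion_extension = 30))
#' gs_decompose(p)
gs_compose <- function(coords) {
  coords <- as_gs_coords(coords)
  if (abs(abs(coords[["varus_valgus"]]) - 90) < 1e-6) {
    stop("gimbal configuration: |VrVl| = 90 degrees is out of physiological range")
  }
  s <- gs_signed_angles(coords)
  R <- rot_z(s[["c"]]) %*% rot_y(s[["b"]]) %*% rot_x(s[["a"]])
  ax <- gs_axes(R)
  t <- -coords[["medial_lateral"]] * ax$e1 -
    coords[["anterior_posterior"]] * ax$e2 -
    coords[["superior_inferior"]] * ax$e3
  rigid_pose(R, t)
}

#' Decompose a rigid pose into Grood-Suntay coordinates
#'
#' Inverts [gs_compose()]. Optional body frames re-express a world pose in
#' the anatomical frames first; with the default coincident identity frames
#' the pose is taken as femur-relative-to-tibia directly.
#'
#' @param pose A [rigid_pose()].
#' @param femur_frame,tibia_frame Optional [body_frame()] objects.
#' @return A [gs_coords()] object.
#' @export
gs_decompose <- function(pose, femur_frame = body_frame(),
                         tibia_frame = body_frame()) {
  stopifnot(inherits(pose, "rigid_pose"))
  R <- t(tibia_frame$axes) %*% pose$rotation %*% femur_frame$axes
  t <- as.numeric(t(tibia_frame$axes) %*%
                    (pose$translation + pose$rotation %*% femur_frame$origin -
                       tibia_frame$origin))
  sb <- -R[3, 1]
  if (abs(abs(sb) - 1) < 1e-6) {
    stop("near-singular decomposition: |VrVl| within 1e-6 of 90 degrees")
  }
  a <- atan2(R[3, 2], R[3, 3])
  b <- asin(sb)
  cc <- atan2(R[2, 1], R[1, 1])
  ax <- gs_axes(R)
  # the joint translation axes are not mutually orthogonal (e1 . e3 = sin b),
  # so the components are recovered by solving the linear system rather than
  # by projection
  comp <- solve(cbind(ax$e1, ax$e2, ax$e3), t)
  gs_coords(
    flexion_extension = rad2deg(a),
    varus_valgus = -rad2deg(b),
    internal_external = rad2deg(cc),
    medial_lateral = -comp[1],
    anterior_posterior = -comp[2],
    superior_inferior = -comp[3]
  )
}

as_gs_coords <- function(x) {
  if (inherits(x, "gs_coords")) return(x)
  if (is.numeric(x) && length(x) == 6) {
    return(gs_coords(x[[1]], x[[2]], x[[3]], x[[4]], x[[5]], x[[6]]))
  }
  stop("cannot interpret object as gs_coords")
}

#' Apply a rigid pose to a point
#'
#' @param pose A [rigid_pose()].
#' @param point 3-vector (mm), or a 3-column matrix of points (one per row).
#' @return Transformed point(s), same shape as the input.
#' @export
transform_point <- function(pose, point) {
  stopifnot(inherits(pose, "rigid_pose"))
  if (is.matrix(point)) {
    stopifnot(ncol(point) == 3)
    return(t(pose$rotation %*% t(point) + pose$translation))
  }
  stopifnot(length(point) == 3)
  as.numeric(pose$rotation %*% point + pose$translation)
}

#' Mirror joint coordinates between left and right knees
#'
#' All internal conventions are for a left knee; a right-knee pose maps onto
#' the left-knee convention by negating the medial-lateral translation and
#' the varus-valgus and internal-external rotations.
#'
#' @param coords A [gs_coords()] object.
#' @return The mirrored [gs_coords()].
#' @export
gs_mirror <- function(coords) {
  coords <- as_gs_coords(coords)
  gs_coords(
    flexion_extension = coords[["flexion_extension"]],
    varus_valgus = -coords[["varus_valgus"]],
    internal_external = -coords[["internal_external"]],
    medial_lateral = -coords[["medial_lateral"]],
    anterior_posterior = coords[["anterior_posterior"]],
    superior_inferior = coords[["superior_inferior"]]
  )
}

# free-DOF helpers used by the solver: order (VrVl, IE, ML, AP, SI)
free_dof_names <- c("varus_valgus", "internal_external", "medial_lateral",
                    "anterior_posterior", "superior_inferior")

coords_from_free <- function(fe, q) {
  gs_coords(fe, q[1], q[2], q[3], q[4], q[5])
}

#' Serialize a kinematics series to CSV
#'
#' Writes a step-indexed series of joint coordinates with columns
#' `step, FE_deg, VrVl_deg, IE_deg, ML_mm, AP_mm, SI_mm`.
#'
#' @param series A data frame with the six coordinate columns.
#' @param path Output CSV path.
#' @export
write_kinematics_csv <- function(series, path) {
  cols <- c("FE_deg", "VrVl_deg", "IE_deg", "ML_mm", "AP_mm", "SI_mm")
  stopifnot(all(cols %in% names(series)))
  if (!"step" %in% names(series)) series <- cbind(step = seq_len(nrow(series)), series)
  utils::write.csv(series[, c("step", cols)], path, row.names = FALSE)
  invisible(path)
}

coords_to_row <- function(coords) {
  data.frame(
    FE_deg = coords[["flexion_extension"]],
    VrVl_deg = coords[["varus_valgus"]],
    IE_deg = coords[["internal_external"]],
    ML_mm = coords[["medial_lateral"]],
    AP_mm = coords[["anterior_posterior"]],
    SI_mm = coords[["superior_inferior"]]
  )
}
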