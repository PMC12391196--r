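#' Zero-load length of a ligament fiber
#'
#' The reference-length design variable `r` sets a fiber's zero-load length
#' as a ratio of its length in the initial full-extension pose:
#' `L0 = r * initial_length`. Values below 1 pretension the fiber in the
#' initial pose; values above 1 leave it slack.
#'
#' @param initial_length Fiber length in the initial pose, mm (> 0).
#' @param r Reference-length ratio (> 0), dimensionless.
#' @return Zero-load length, mm.
#' @export
#' @examples
#' zero_load_length(100, 1.25)  # 125 mm, slack
#' zero_load_length(80, 0.95)   # 76 mm, pretensioned
zero_load_length <- function(initial_length, r) {
  if (any(initial_length <= 0)) stop("initial_length must be positive")
  if (any(r <= 0)) stop("reference-length ratio must be positive")
  r * initial_length
}

#' Nonlinear tension-only ligament fiber force
#'
#' The standard piecewise force-elongation law for knee ligament springs: a
#' quadratic toe region for strains up to twice the toe strain `eps_l`,
#' then a linear region with stiffness `k`. In displacement form, with
#' `d = length - L0`:
#' \deqn{f = 0, d \le 0}
#' \deqn{f = k d^2 / (4 \epsilon_l L_0), 0 < d \le 2 \epsilon_l L_0}
#' \deqn{f = k (d - \epsilon_l L_0), d > 2 \epsilon_l L_0}
#' The curve is C1-continuous: at the toe/linear junction the force is
#' `k * eps_l * L0` and the slope is exactly `k` from both sides.
#'
#' @param length Current fiber length, mm. Vectorized.
#' @param L0 Zero-load length, mm (> 0).
#' @param k Linear-region stiffness, N/mm (>= 0).
#' @param eps_l Toe-region strain parameter (> 0), default 0.03.
#' @return Tensile force, N (never negative).
#' @export
#' @examples
#' fiber_force(110, L0 = 100, k = 100)  # linear region: 100 * (10 - 3) = 700 N
fiber_force <- function(length, L0, k, eps_l = 0.03) {
  stopifnot(all(L0 > 0), all(k >= 0), all(eps_l > 0))
  d <- length - L0
  dt <- 2 * eps_l * L0  # toe/linear junction elongation
  ifelse(d <= 0, 0,
         ifelse(d <= dt, k * d^2 / (4 * eps_l * L0),
                k * (d - eps_l * L0)))
}

#' Ligament fiber strain energy
#'
#' Closed-form integral of [fiber_force()] with respect to length, used by
#' the quasi-static equilibrium solver. `U = 0` for slack fibers and
#' `dU/dlength = fiber_force` everywhere.
#'
#' @inheritParams fiber_force
#' @return Stored energy, N mm.
#' @export
fiber_energy <- function(length, L0, k, eps_l = 0.03) {
  stopifnot(all(L0 > 0), all(k >= 0), all(eps_l > 0))
  d <- length - L0
  dt <- 2 * eps_l * L0
  # toe integral: k d^3 / (12 eps_l L0); at d = dt it equals k dt^3/(12 eps_l L0)
  u_toe_end <- k * dt^3 / (12 * eps_l * L0)
  ifelse(d <= 0, 0,
         ifelse(d <= dt, k * d^3 / (12 * eps_l * L0),
                u_toe_end + k / 2 * ((d - eps_l * L0)^2 - (dt - eps_l * L0)^2)))
}

#' Condylar contact element
#'
#' Point-contact condyle (sphere on the femur) against a tibial plateau with
#' a tri-linear force-overclosure law. The plateau is a shallow spherical
#' dish of radius `dish_radius` tangent to the plane through `plateau_point`
#' with normal `plateau_normal`; `dish_radius = Inf` gives a flat plateau.
#' The friction coefficient is recorded for completeness but not applied in
#' the quasi-static energy formulation.
#'
#' @param side `"medial"` or `"lateral"`.
#' @param condyle_center Condyle sphere center, femur frame, mm.
#' @param condyle_radius Condyle sphere radius, mm.
#' @param plateau_point Lowest point of the plateau surface, tibia frame, mm.
#' @param plateau_normal Outward (superior) plateau normal, tibia frame.
#' @param dish_radius Radius of the concave plateau dish, mm (Inf = flat).
#' @param slopes Three non-decreasing contact stiffnesses, N/mm.
#' @param breakpoints Two strictly increasing overclosure breakpoints, mm.
#' @param friction_mu Recorded friction coefficient (not applied).
#' @return An object of class `contact_element`.
#' @export
contact_element <- function(side, condyle_center, condyle_radius,
                            plateau_point, plateau_normal = c(0, 0, 1),
                            dish_radius = Inf,
                            slopes = c(200, 800, 3000),
                            breakpoints = c(0.2, 0.5),
                            friction_mu = 0.03) {
  side <- match.arg(side, c("medial", "lateral"))
  stopifnot(length(slopes) == 3, length(breakpoints) == 2)
  if (any(slopes < 0) || any(diff(slopes) < 0)) {
    stop("contact slopes must be non-negative and non-decreasing")
  }
  if (any(breakpoints <= 0) || diff(breakpoints) <= 0) {
    stop("breakpoints must be positive and strictly increasing")
  }
  if (condyle_radius <= 0) stop("condyle_radius must be positive")
  if (is.finite(dish_radius) && dish_radius <= condyle_radius) {
    stop("dish_radius must exceed condyle_radius")
  }
  n <- as.numeric(plateau_normal)
  n <- n / sqrt(sum(n^2))
  structure(list(
    side = side,
    condyle_center = as.numeric(condyle_center),
    condyle_radius = as.numeric(condyle_radius),
    plateau_point = as.numeric(plateau_point),
    plateau_normal = n,
    dish_radius = as.numeric(dish_radius),
    slopes = as.numeric(slopes),
    breakpoints = as.numeric(breakpoints),
    friction_mu = friction_mu
  ), class = "contact_element")
}

#' Tri-linear contact force
#'
#' Piecewise-linear, continuous, monotone non-decreasing normal force as a
#' function of overclosure (interpenetration depth). Zero for separation.
#'
#' @param overclosure Interpenetration depth, mm (negative = separated).
#'   Vectorized.
#' @param element A [contact_element()].
#' @return Normal contact force, N.
#' @export
#' @examples
#' el <- contact_element("medial", c(0, 0, 0), 20, c(0, 0, -20),
#'                       slopes = c(100, 500, 2000), breakpoints = c(0.1, 0.3))
#' contact_force(0.3, el)  # 100*0.1 + 500*0.2 = 110 N
contact_force <- function(overclosure, element) {
  s <- element$slopes
  b <- element$breakpoints
  f1 <- s[1] * b[1]
  f2 <- f1 + s[2] * (b[2] - b[1])
  d <- overclosure
  ifelse(d <= 0, 0,
         ifelse(d <= b[1], s[1] * d,
                ifelse(d <= b[2], f1 + s[2] * (d - b[1]),
                       f2 + s[3] * (d - b[2]))))
}

#' Tri-linear contact energy
#'
#' Integral of [contact_force()] with respect to overclosure;
#' `dU/doverclosure = contact_force` and `U = 0` at separation.
#'
#' @inheritParams contact_force
#' @return Stored energy, N mm.
#' @export
contact_energy <- function(overclosure, element) {
  s <- element$slopes
  b <- element$breakpoints
  f1 <- s[1] * b[1]
  f2 <- f1 + s[2] * (b[2] - b[1])
  u1 <- s[1] * b[1]^2 / 2
  u2 <- u1 + f1 * (b[2] - b[1]) + s[2] * (b[2] - b[1])^2 / 2
  d <- overclosure
  ifelse(d <= 0, 0,
         ifelse(d <= b[1], s[1] * d^2 / 2,
                ifelse(d <= b[2], u1 + f1 * (d - b[1]) + s[2] * (d - b[1])^2 / 2,
                       u2 + f2 * (d - b[2]) + s[3] * (d - b[2])^2 / 2)))
}

#' Ligament bundle
#'
#' A named bundle of parallel fibers sharing one reference-length ratio and
#' one linear stiffness. Fiber endpoints are stored in the femur (origin)
#' and tibia (insertion) local frames; `initial_length` is each fiber's
#' length in the initial full-extension pose.
#'
#' @param name One of the 14 modeled bundle names (see [bundle_names()]).
#' @param origins,insertions n x 3 matrices of fiber endpoints, mm.
#' @param r Reference-length ratio shared by all fibers.
#' @param k Linear stiffness shared by all fibers, N/mm.
#' @param eps_l Toe strain parameter, default 0.03.
#' @return An object of class `ligament_bundle`.
#' @export
ligament_bundle <- function(name, origins, insertions, r = 1, k = 100,
                            eps_l = 0.03) {
  name <- match.arg(name, bundle_names())
  origins <- matrix(as.numeric(origins), ncol = 3)
  insertions <- matrix(as.numeric(insertions), ncol = 3)
  stopifnot(nrow(origins) == nrow(insertions), nrow(origins) >= 1)
  init_len <- sqrt(rowSums((origins - insertions)^2))
  if (any(init_len <= 0)) stop("fiber origin and insertion must differ")
  if (r <= 0 || k < 0 || eps_l <= 0) stop("invalid bundle material parameters")
  structure(list(
    name = name,
    origins = origins,
    insertions = insertions,
    initial_length = init_len,
    r = r, k = k, eps_l = eps_l
  ), class = "ligament_bundle")
}

#' Names of the 14 modeled ligament bundles
#'
#' @return Character vector of bundle abbreviations in design-variable order.
#' @export
bundle_names <- function() {
  c("ACL_AM", "ACL_PL", "LCL", "sMCL_A", "sMCL_M", "sMCL_P", "dMCL",
    "PCL_AL", "PCL_PM", "ALS", "PFL", "POL", "PCAP_M", "PCAP_L")
}

#' Reporting groups for ligament loads
#'
#' The nine groups used when tabulating bundle forces: the two ACL bundles
#' sum into ACL, the three superficial MCL fibers into MCL_S, the two PCL
#' bundles into PCL and the two posterior-capsule bundles into PCAP.
#'
#' @return Named list mapping group name to member bundle names.
#' @export
bundle_groups <- function() {
  list(
    ACL = c("ACL_AM", "ACL_PL"),
    ALS = "ALS",
    LCL = "LCL",
    MCL_S = c("sMCL_A", "sMCL_M", "sMCL_P"),
    MCL_D = "dMCL",
    POL = "POL",
    PCAP = c("PCAP_M", "PCAP_L"),
    PCL = c("PCL_AL", "PCL_PM"),
    PFL = "PFL"
  )
}
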