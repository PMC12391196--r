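# Two-phase optimizer components: a bounded global-best particle swarm for
# the global search and a bound-projected Nelder-Mead simplex for the local
# polish.

#' Global-best particle swarm optimization
#'
#' Standard constriction-coefficient PSO (inertia 0.729, cognitive = social
#' = 1.49445) over a box-bounded domain. Positions are clamped to the
#' bounds with the corresponding velocity component zeroed. Fully
#' deterministic given `seed`.
#'
#' @param objective Function of a numeric vector returning a scalar cost.
#' @param bounds Two-column (`lo`, `hi`) matrix, one row per dimension.
#' @param n_particles Swarm size.
#' @param n_iterations Number of velocity/position updates.
#' @param seed RNG seed.
#' @return List with `par` (best vector), `value`, `trace` (best-so-far
#'   cost after initialization and after each iteration), `n_evaluations`.
#' @export
#' @examples
#' sphere <- function(x) sum(x^2)
#' b <- cbind(lo = rep(-5, 3), hi = rep(5, 3))
#' particle_swarm(sphere, b, n_particles = 20, n_iterations = 50, seed = 1)$value
particle_swarm <- function(objective, bounds, n_particles = 15,
                           n_iterations = 40, seed = 1) {
  stopifnot(is.matrix(bounds), ncol(bounds) == 2, all(is.finite(bounds)),
            all(bounds[, 2] > bounds[, 1]), n_particles >= 1)
  local_seed(seed)
  d <- nrow(bounds)
  lo <- bounds[, 1]; hi <- bounds[, 2]
  span <- hi - lo
  w <- 0.729; c1 <- 1.49445; c2 <- 1.49445

  x <- t(replicate(n_particles, stats::runif(d, lo, hi), simplify = TRUE))
  if (d == 1) x <- matrix(x, ncol = 1)
  v <- t(replicate(n_particles, stats::runif(d, -span, span) / 2))
  if (d == 1) v <- matrix(v, ncol = 1)
  cost <- apply(x, 1, objective)
  n_eval <- n_particles
  pbest <- x; pcost <- cost
  gi <- which.min(pcost)
  gbest <- pbest[gi, ]; gcost <- pcost[gi]
  trace <- gcost

  for (it in seq_len(n_iterations)) {
    for (p in seq_len(n_particles)) {
      r1 <- stats::runif(d); r2 <- stats::runif(d)
      v[p, ] <- w * v[p, ] + c1 * r1 * (pbest[p, ] - x[p, ]) +
        c2 * r2 * (gbest - x[p, ])
      xn <- x[p, ] + v[p, ]
      below <- xn < lo; above <- xn > hi
      xn[below] <- lo[below]; xn[above] <- hi[above]
      v[p, below | above] <- 0
      x[p, ] <- xn
      cst <- objective(xn)
      n_eval <- n_eval + 1
      if (cst < pcost[p]) { pcost[p] <- cst; pbest[p, ] <- xn }
      if (cst < gcost) { gcost <- cst; gbest <- xn }
    }
    trace <- c(trace, gcost)
  }
  list(par = stats::setNames(gbest, rownames(bounds)), value = gcost,
       trace = trace, n_evaluations = n_eval)
}

#' Bound-projected Nelder-Mead simplex
#'
#' Standard simplex coefficients (reflection 1, expansion 2, contraction
#' 0.5, shrink 0.5); trial points falling outside the bounds are projected
#' back onto the box before evaluation. The returned best never exceeds the
#' starting cost.
#'
#' @param objective Function of a numeric vector returning a scalar cost.
#' @param start Starting vector (within bounds).
#' @param bounds Two-column (`lo`, `hi`) matrix (may contain infinities).
#' @param n_iterations Maximum simplex iterations.
#' @param tol Relative cost-spread stopping tolerance.
#' @return List with `par`, `value`, `trace` (best-so-far per iteration),
#'   `n_evaluations`.
#' @export
nelder_mead <- function(objective, start, bounds = NULL, n_iterations = 200,
                        tol = 1e-10) {
  d <- length(start)
  if (is.null(bounds)) bounds <- cbind(rep(-Inf, d), rep(Inf, d))
  lo <- bounds[, 1]; hi <- bounds[, 2]
  clamp <- function(x) pmin(pmax(x, lo), hi)
  start <- clamp(start)
  f <- function(x) objective(clamp(x))
  n_eval <- 0L
  fc <- function(x) { n_eval <<- n_eval + 1L; f(x) }

  # initial simplex: perturb each coordinate by 5% of span (or 0.05)
  step <- ifelse(is.finite(hi - lo), 0.05 * (hi - lo), pmax(0.05 * abs(start), 0.05))
  simplex <- rbind(start, t(vapply(seq_len(d), function(i) {
    x <- start; x[i] <- x[i] + step[i]
    if (x[i] > hi[i]) x[i] <- start[i] - step[i]
    x
  }, numeric(d))))
  vals <- apply(simplex, 1, fc)
  trace <- numeric(0)

  for (it in seq_len(n_iterations)) {
    ord <- order(vals)
    simplex <- simplex[ord, , drop = FALSE]
    vals <- vals[ord]
    trace <- c(trace, vals[1])
    if (abs(vals[d + 1] - vals[1]) <= tol * (abs(vals[1]) + tol)) break
    centroid <- colMeans(simplex[seq_len(d), , drop = FALSE])
    worst <- simplex[d + 1, ]
    xr <- clamp(centroid + (centroid - worst))
    fr <- fc(xr)
    if (fr < vals[1]) {
      xe <- clamp(centroid + 2 * (centroid - worst))
      fe <- fc(xe)
      if (fe < fr) { simplex[d + 1, ] <- xe; vals[d + 1] <- fe }
      else { simplex[d + 1, ] <- xr; vals[d + 1] <- fr }
    } else if (fr < vals[d]) {
      simplex[d + 1, ] <- xr; vals[d + 1] <- fr
    } else {
      if (fr < vals[d + 1]) {  # outside contraction
        xc <- clamp(centroid + 0.5 * (xr - centroid))
      } else {                 # inside contraction
        xc <- clamp(centroid - 0.5 * (centroid - worst))
      }
      fcv <- fc(xc)
      if (fcv < min(fr, vals[d + 1])) {
        simplex[d + 1, ] <- xc; vals[d + 1] <- fcv
      } else {  # shrink toward best
        for (i in 2:(d + 1)) {
          simplex[i, ] <- clamp(simplex[1, ] + 0.5 * (simplex[i, ] - simplex[1, ]))
          vals[i] <- fc(simplex[i, ])
        }
      }
    }
  }
  best <- which.min(vals)
  list(par = stats::setNames(simplex[best, ], names(start)),
       value = vals[best], trace = cummin(trace), n_evaluations = n_eval)
}
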