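# Vector fields and region predicates of the controlled tumor model
#
#   x1' = (1 - (x1 + x2)) x1 - eps x1 - (alpha + d) u x1
#   x2' = pr (1 - (x1 + x2)) x2 + eps x1 + alpha u x1
#
# written control-affinely as x' = f(x) + u g(x).

# absolute tolerance used by all region-membership tests; absorbs integrator
# drift at the boundaries
OMEGA_TOL <- 1e-9

as_state <- function(s) {
  s <- as.numeric(s)
  if (length(s) != 2L || any(!is.finite(s)))
    stop("a state is a finite numeric vector (x1, x2)")
  s
}

#' State-space predicates and the volume output
#'
#' The model state lives in the triangle
#' \eqn{\Omega = \{x_1, x_2 \ge 0,\; x_1 + x_2 \le 1\}}; treatment is
#' considered successful while the state stays in the sub-triangle
#' \eqn{\Omega_c} where the total volume \eqn{V = x_1 + x_2} is at most the
#' critical volume `Vc`. All membership tests use an absolute tolerance of
#' `1e-9` so that trajectories skimming a boundary are not rejected.
#'
#' @param s state vector `c(x1, x2)`.
#' @param p a [params()] object.
#' @return `volume()`: the scalar `x1 + x2`; `in_omega()`/`in_omega_c()`:
#'   logical; `constraint_psi()`: the signed constraint value
#'   `x1 + x2 - Vc` (negative inside the treatment region, zero on the
#'   failure boundary `N`).
#' @export
#' @examples
#' volume(c(0.3, 0.4))
#' in_omega_c(c(0.5, 0.5), params_preset())   # FALSE: above Vc = 0.9
#' constraint_psi(c(0.9, 0), params_preset()) # 0: on the boundary N
volume <- function(s) {
  s <- as_state(s)
  s[1] + s[2]
}

#' @rdname volume
#' @export
in_omega <- function(s) {
  s <- as_state(s)
  s[1] >= -OMEGA_TOL && s[2] >= -OMEGA_TOL && s[1] + s[2] <= 1 + OMEGA_TOL
}

#' @rdname volume
#' @export
in_omega_c <- function(s, p) {
  s <- as_state(s)
  s[1] >= -OMEGA_TOL && s[2] >= -OMEGA_TOL &&
    s[1] + s[2] <= p$Vc + OMEGA_TOL
}

#' @rdname volume
#' @export
constraint_psi <- function(s, p) {
  volume(s) - p$Vc
}

#' Drift and control vector fields
#'
#' `drift_field()` evaluates the drug-free dynamics
#' \deqn{f(x) = \big((1 - V)x_1 - \epsilon x_1,\;
#'               p_r (1 - V) x_2 + \epsilon x_1\big),}
#' `control_field()` the per-unit-dose action
#' \deqn{g(x) = \big(-(\alpha + d) x_1,\; \alpha x_1\big),}
#' and `model_rhs()` their affine combination `f(x) + u g(x)`.
#'
#' @param s state vector `c(x1, x2)`; must lie in the triangle
#'   \eqn{\Omega}.
#' @param u dose, in `[0, M]`.
#' @param p a [params()] object.
#' @return A numeric 2-vector (the time derivative of the state).
#' @export
#' @examples
#' p <- params_preset()
#' drift_field(c(0.01, 0), p)
#' control_field(c(0.5, 0.2), p)
#' model_rhs(c(0.01, 0), u = 5, p)
drift_field <- function(s, p) {
  s <- as_state(s)
  if (!in_omega(s)) stop("state outside the model region Omega")
  kap <- 1 - (s[1] + s[2])
  c(kap * s[1] - p$eps * s[1],
    p$pr * kap * s[2] + p$eps * s[1])
}

#' @rdname drift_field
#' @export
control_field <- function(s, p) {
  s <- as_state(s)
  if (!in_omega(s)) stop("state outside the model region Omega")
  c(-(p$alpha + p$d) * s[1], p$alpha * s[1])
}

#' @rdname drift_field
#' @export
model_rhs <- function(s, u, p) {
  if (!is.finite(u) || u < -OMEGA_TOL || u > p$M + OMEGA_TOL)
    stop("dose u must lie in [0, M]")
  drift_field(s, p) + u * control_field(s, p)
}

# Unchecked fast path used inside integrators (thousands of calls per solve).
rhs_raw <- function(s, u, p) {
  kap <- 1 - (s[1] + s[2])
  c(kap * s[1] - p$eps * s[1] - (p$alpha + p$d) * u * s[1],
    p$pr * kap * s[2] + p$eps * s[1] + p$alpha * u * s[1])
}

# Jacobian of f + u g; used by the adjoint equation.
rhs_jacobian <- function(s, u, p) {
  x1 <- s[1]; x2 <- s[2]
  matrix(c(1 - 2 * x1 - x2 - p$eps - (p$alpha + p$d) * u, -x1,
           p$pr * (-x2) + p$eps + p$alpha * u, p$pr * (1 - x1 - 2 * x2)),
         nrow = 2, byrow = TRUE)
}
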