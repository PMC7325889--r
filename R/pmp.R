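# Pontryagin Maximum Principle diagnostics.
#
# The extremal lift (lambda0, lambda) is used as a *verifier* of candidate
# controls, not as a shooting solver: the optimal structure is already known
# in closed form, so the Hamiltonian/switching-function machinery serves as
# a test oracle for computed schedules.

#' Extremal-lift quantities
#'
#' `hamiltonian()` evaluates
#' \eqn{H = -\lambda_0 + \langle\lambda, f\rangle + u\,\Phi}, which vanishes
#' identically along an optimal lift (free terminal time);
#' `switching_value()` evaluates the switching function
#' \eqn{\Phi = \langle\lambda, g\rangle}, whose sign selects the bang dose
#' (`u = 0` where `Phi > 0`, `u = M` where `Phi < 0`);
#' `adjoint_rhs()` evaluates the adjoint equation
#' \eqn{\dot\lambda = -(D(f + ug))^\top\lambda}.
#'
#' @param lift list with `lambda0` (0 or 1) and `lam` (numeric 2-vector).
#' @param s state `c(x1, x2)`.
#' @param u dose.
#' @param p a [params()] object.
#' @return `hamiltonian`/`switching_value`: scalar; `adjoint_rhs`: 2-vector.
#' @export
hamiltonian <- function(lift, s, u, p) {
  -lift$lambda0 + sum(lift$lam * drift_field(s, p)) +
    u * switching_value(lift, s, p)
}

#' @rdname hamiltonian
#' @export
switching_value <- function(lift, s, p) {
  sum(lift$lam * control_field(s, p))
}

#' @rdname hamiltonian
#' @export
adjoint_rhs <- function(lift, s, u, p) {
  as.numeric(-t(rhs_jacobian(as_state(s), u, p)) %*% lift$lam)
}

#' Co-integrate state and adjoint along a piecewise control
#'
#' Integrates the 4-dimensional extremal-lift system (state plus adjoint,
#' normal normalization `lambda0 = 1`) along the constant-dose arcs of a
#' schedule, recording the switching function `Phi(t)` and Hamiltonian
#' `H(t)` series. Feedback arcs are not supported here: the Maximum
#' Principle applies to interior sub-arcs only, which is where verification
#' is meaningful.
#'
#' @param p a [params()] object.
#' @param ctrl a `chemopt_control` whose arcs are all clocked constant-dose
#'   arcs (`ZERO`/`MAX`/`CONST` with durations).
#' @param lam0_init initial adjoint covector `c(lambda1, lambda2)`.
#' @param n_per_arc output points per arc.
#' @return List with `times`, `states`, `lam`, `Phi`, `H`, `doses`.
#' @export
integrate_lift <- function(p, ctrl, lam0_init, n_per_arc = 200) {
  stopifnot(inherits(ctrl, "chemopt_control"))
  y <- c(unname(initial_state(p)), as.numeric(lam0_init))
  t <- 0
  times <- numeric(); states <- NULL; lam <- NULL; doses <- numeric()
  for (arc in ctrl$arcs) {
    if (!arc$mode %in% c("ZERO", "MAX", "CONST") || is.null(arc$duration))
      stop("integrate_lift supports clocked constant-dose arcs only")
    u <- arc_dose(arc, p)
    derivs <- function(tt, yy, parms) {
      s <- yy[1:2]; l <- yy[3:4]
      list(c(rhs_raw(s, u, p),
             as.numeric(-t(rhs_jacobian(s, u, p)) %*% l)))
    }
    grid <- seq(t, t + arc$duration, length.out = n_per_arc)
    out <- deSolve::lsoda(y, grid, derivs, NULL,
                          rtol = 1e-12, atol = 1e-12)
    keep <- if (length(times)) -1 else TRUE
    times <- c(times, out[keep, 1])
    states <- rbind(states, unname(out[keep, 2:3, drop = FALSE]))
    lam <- rbind(lam, unname(out[keep, 4:5, drop = FALSE]))
    doses <- c(doses, rep(u, nrow(out) - (if (identical(keep, -1)) 1 else 0)))
    y <- unname(out[nrow(out), -1])
    t <- t + arc$duration
  }
  Phi <- lam[, 2] * p$alpha * states[, 1] -
    lam[, 1] * (p$alpha + p$d) * states[, 1]
  fv <- t(apply(states, 1, drift_field, p = p))
  H <- -1 + rowSums(lam * fv) + doses * Phi
  list(times = times, states = states, lam = lam, Phi = Phi, H = H,
       doses = doses)
}

#' Construct a verified extremal lift for a bang-bang schedule
#'
#' The initial covector must satisfy `H(0) = 0` (normal normalization),
#' which leaves a one-parameter affine family
#' \eqn{\lambda(0) = v_0/\|v_0\|^2 + \tau\, v_0^\perp} with
#' \eqn{v_0 = f(x_0) + u(0) g(x_0)}. Because the adjoint equation is linear,
#' the switching value at the first switch time is affine in \eqn{\tau}, so
#' the unique lift with `Phi(t_switch) = 0` is obtained from two trial
#' integrations and one linear solve.
#'
#' @param p a [params()] object.
#' @param ctrl a clocked bang-bang `chemopt_control` with at least two arcs.
#' @param n_per_arc output points per arc in the returned series.
#' @return The output of [integrate_lift()] for the solved initial covector,
#'   plus `lam_init` and `t_switch`.
#' @export
find_extremal_lift <- function(p, ctrl, n_per_arc = 200) {
  arcs <- ctrl$arcs
  if (length(arcs) < 2) stop("need at least one switch to pin the lift")
  t_switch <- arcs[[1]]$duration
  x0 <- unname(initial_state(p))
  u0 <- arc_dose(arcs[[1]], p)
  v0 <- rhs_raw(x0, u0, p)
  v0p <- c(-v0[2], v0[1])
  lam_at_switch <- function(tau) {
    lift <- integrate_lift(p, ctrl, v0 / sum(v0^2) + tau * v0p, n_per_arc = 2)
    idx <- which.min(abs(lift$times - t_switch))
    lift$Phi[idx]
  }
  phi0 <- lam_at_switch(0)
  phi1 <- lam_at_switch(1)
  if (phi1 == phi0) stop("degenerate lift family: Phi insensitive to tau")
  tau_star <- -phi0 / (phi1 - phi0)
  lam_init <- v0 / sum(v0^2) + tau_star * v0p
  out <- integrate_lift(p, ctrl, lam_init, n_per_arc = n_per_arc)
  out$lam_init <- lam_init
  out$t_switch <- t_switch
  out
}

#' Legendre-Clebsch diagnostic on the singular segment
#'
#' Returns \eqn{L_g\gamma = (L_Y\gamma - L_X\gamma)/M}. Along the singular
#' segment this equals \eqn{\langle\lambda, [g,[f,g]]\rangle} for any
#' extremal lift of the singular arc; a positive value violates the
#' generalized Legendre-Clebsch necessary condition for the minimization
#' problem, certifying that dwelling on the singular arc is never optimal.
#'
#' @param s a state on the singular segment.
#' @param p a [params()] object.
#' @param tol allowed distance (in `a x1 + b x2 - c`) from the line.
#' @return A scalar (positive on the admissible segment).
#' @export
legendre_clebsch_value <- function(s, p, tol = 1e-6) {
  s <- as_state(s)
  L <- line_coefficients(p)
  if (abs(L$a * s[1] + L$b * s[2] - L$c) > tol)
    stop("Legendre-Clebsch diagnostic is defined on the singular segment")
  (lie_gamma_along(s, p, p$M) - lie_gamma_along(s, p, 0)) / p$M
}
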