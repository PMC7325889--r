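# Lie-algebraic phase-plane geometry of the control-affine system.
#
# Because f and g are linearly independent wherever x1 > 0, the bracket
# [f, g] decomposes as gamma f + beta g; the zero set of gamma is a straight
# line a x1 + b x2 = c which carries the only candidate singular arcs.

#' Coefficients of the singular line
#'
#' The Lie bracket coefficient \eqn{\gamma} vanishes exactly on the line
#' `a x1 + b x2 = c` with
#' \deqn{a = \alpha\big((1-p_r) + d/(\alpha+d)\big),\quad
#'       b = \alpha(1-p_r) + d p_r,\quad
#'       c = \alpha(1-p_r) + \epsilon d.}
#' For the parameter ranges of interest (`pr < 1`, `alpha, d > 0`) all three
#' are positive and the line has negative slope `-a/b`. With `alpha = 0` the
#' line is horizontal (`a = 0`).
#'
#' @param p a [params()] object.
#' @return An object of class `singular_line`: list with fields `a`, `b`, `c`.
#' @export
#' @examples
#' line_coefficients(params_preset())
line_coefficients <- function(p) {
  if (p$alpha + p$d == 0) stop("degenerate: alpha + d must be positive")
  structure(list(
    a = p$alpha * ((1 - p$pr) + p$d / (p$alpha + p$d)),
    b = p$alpha * (1 - p$pr) + p$d * p$pr,
    c = p$alpha * (1 - p$pr) + p$eps * p$d
  ), class = "singular_line")
}

#' @export
print.singular_line <- function(x, ...) {
  cat(sprintf("singular line: %.8g x1 + %.8g x2 = %.8g\n", x$a, x$b, x$c))
  invisible(x)
}

#' Determinant of the frame (f, g)
#'
#' \eqn{\det A(x) = \alpha x_1^2 \kappa + p_r(\alpha+d) x_1 x_2 \kappa
#' + \epsilon d x_1^2} with \eqn{\kappa = 1 - (x_1+x_2)}; equals the cross
#' product `f1*g2 - f2*g1` and vanishes in \eqn{\Omega} iff `x1 = 0`, which
#' is why the two fields form a frame on the region of interest.
#'
#' @inheritParams drift_field
#' @return A non-negative scalar.
#' @export
det_A <- function(s, p) {
  s <- as_state(s)
  kap <- 1 - (s[1] + s[2])
  p$alpha * s[1]^2 * kap + p$pr * (p$alpha + p$d) * s[2] * s[1] * kap +
    p$eps * p$d * s[1]^2
}

#' Bracket decomposition coefficients
#'
#' Coefficients of `[f, g] = gamma * f + beta * g`:
#' \deqn{\gamma(x) = -\frac{(\alpha+d) x_1^2}{\det A(x)}(a x_1 + b x_2 - c),}
#' \deqn{\beta(x) = \frac{x_1^2}{\det A(x)}\big(\alpha(1-p_r)\kappa(\kappa-\epsilon)
#'  + \epsilon d (x_1 + p_r x_2 + \kappa - \epsilon)\big).}
#' `gamma` is positive below the singular line (`a x1 + b x2 < c`), negative
#' above it; `beta` is positive throughout the interior of the treatment
#' region under the standing assumption `Vc < 1 - eps`.
#'
#' @inheritParams drift_field
#' @return A scalar.
#' @export
gamma_coeff <- function(s, p) {
  s <- as_state(s)
  if (s[1] <= 0) stop("gamma is defined only for x1 > 0 (det A != 0)")
  L <- line_coefficients(p)
  -(p$alpha + p$d) * s[1]^2 / det_A(s, p) *
    (L$a * s[1] + L$b * s[2] - L$c)
}

#' @rdname gamma_coeff
#' @export
beta_coeff <- function(s, p) {
  s <- as_state(s)
  if (s[1] <= 0) stop("beta is defined only for x1 > 0 (det A != 0)")
  kap <- 1 - (s[1] + s[2])
  s[1]^2 / det_A(s, p) *
    (p$alpha * (1 - p$pr) * kap * (kap - p$eps) +
       p$eps * p$d * (s[1] + p$pr * s[2] + kap - p$eps))
}

#' Lie bracket of the drift and control fields
#'
#' Exact Jacobian-based bracket `[f, g](x) = Dg(x) f(x) - Df(x) g(x)`.
#' Satisfies the frame decomposition `[f, g] = gamma f + beta g` wherever
#' `x1 > 0`.
#'
#' @inheritParams drift_field
#' @return A numeric 2-vector.
#' @export
lie_bracket_fg <- function(s, p) {
  s <- as_state(s)
  f <- drift_field(s, p)
  g <- control_field(s, p)
  Df <- rhs_jacobian(s, 0, p)
  Dg <- matrix(c(-(p$alpha + p$d), 0, p$alpha, 0), nrow = 2, byrow = TRUE)
  as.numeric(Dg %*% f - Df %*% g)
}

#' Tangency point of the maximal-dose field on the failure boundary
#'
#' The point `x* = (x1*, x2*)` on the line `N : x1 + x2 = Vc` where the
#' maximal-dose vector field `Y = f + M g` is tangent to `N`:
#' \deqn{x_1^* = \frac{p_r (1-V_c) V_c}{d M - (1-V_c)(1-p_r)},\qquad
#'       x_2^* = V_c - x_1^*.}
#' It exists when `M > (1-Vc)(1-pr)/d`, i.e. when the maximal dose is strong
#' enough to shrink the tumor anywhere on `N`. On `N` the volume decreases
#' under `Y` for `x1 > x1*` and increases for `x1 < x1*`; `x*` is also the
#' point where the boundary feedback dose saturates at `M`.
#'
#' @param p a [params()] object.
#' @return Object of class `tangency_point`: list with `x1s`, `x2s`.
#' @export
#' @examples
#' tangency_point(params_preset(d = 0.05)) # (0.1059, 0.7941)
tangency_point <- function(p) {
  thr <- (1 - p$Vc) * (1 - p$pr) / p$d
  if (p$M <= thr)
    stop("no tangency point: requires M > (1 - Vc)(1 - pr)/d = ",
         signif(thr, 6))
  x1s <- p$pr * (1 - p$Vc) * p$Vc / (p$d * p$M - (1 - p$Vc) * (1 - p$pr))
  structure(list(x1s = x1s, x2s = p$Vc - x1s), class = "tangency_point")
}

#' @export
print.tangency_point <- function(x, ...) {
  cat(sprintf("tangency point x* = (%.6g, %.6g)\n", x$x1s, x$x2s))
  invisible(x)
}

#' Directional derivative of the volume along the dosed flow
#'
#' \eqn{L_{f+ug} V = \nabla V \cdot (f + u g)
#'   = (1 - V)(x_1 + p_r x_2) - d\,u\,x_1.}
#' On the failure boundary with `u = M` this reduces to
#' `[(1-Vc)(1-pr) - dM] x1 + pr (1-Vc) Vc`, the expression whose unique zero
#' on `N` is the tangency point.
#'
#' @inheritParams model_rhs
#' @return A scalar.
#' @export
lie_V_along <- function(s, p, u) {
  s <- as_state(s)
  sum(rhs_raw(s, u, p))
}

#' Is the singular line interior to the treatment region?
#'
#' The line `a x1 + b x2 = c` lies inside the triangle `0 <= V <= Vc` iff its
#' two axis intercepts do: `c/a <= Vc` and `c/b <= Vc`. With `alpha = 0`
#' (horizontal line, `a = 0`) the condition fails whenever `eps > 0`.
#'
#' @param p a [params()] object.
#' @return Logical; `FALSE` carries a `reason` attribute when degenerate.
#' @export
line_interior <- function(p) {
  L <- line_coefficients(p)
  if (L$a == 0)
    return(structure(FALSE, reason = "alpha = 0: line horizontal, never interior"))
  L$c / L$a <= p$Vc && L$c / L$b <= p$Vc
}

#' Does the maximal dose shrink the sensitive compartment everywhere?
#'
#' True iff `M > (1 - eps)/(alpha + d)`, in which case the sensitive
#' population is strictly decreasing under the constant maximal dose.
#'
#' @param p a [params()] object.
#' @return Logical.
#' @export
max_dose_kills_sensitive <- function(p) {
  p$M > (1 - p$eps) / (p$alpha + p$d)
}

# closed-form gradient of gamma (quotient rule on the rational expression);
# cross-checked against central finite differences in the test suite.
gamma_grad <- function(s, p) {
  x1 <- s[1]; x2 <- s[2]
  if (x1 <= 0) stop("gamma gradient requires x1 > 0")
  L <- line_coefficients(p)
  kap <- 1 - (x1 + x2)
  ad <- p$alpha + p$d
  D <- det_A(s, p)
  ell <- L$a * x1 + L$b * x2 - L$c
  dD1 <- p$alpha * (2 * x1 * kap - x1^2) +
    p$pr * ad * x2 * (kap - x1) + 2 * p$eps * p$d * x1
  dD2 <- -p$alpha * x1^2 + p$pr * ad * x1 * (kap - x2)
  num <- x1^2 * ell                          # gamma = -ad * num / D
  dnum1 <- 2 * x1 * ell + x1^2 * L$a
  dnum2 <- x1^2 * L$b
  c(-ad * (dnum1 * D - num * dD1) / D^2,
    -ad * (dnum2 * D - num * dD2) / D^2)
}

#' Directional derivative of gamma along the dosed flow
#'
#' \eqn{L_{f+ug}\gamma = \nabla\gamma \cdot (f + u g)}, computed from the
#' exact closed-form gradient of \eqn{\gamma}. With `u = 0` this is
#' \eqn{L_X\gamma}, with `u = M` it is \eqn{L_Y\gamma}; their signs along the
#' singular line decide where a singular dose in `[0, M]` exists.
#'
#' @inheritParams model_rhs
#' @return A scalar.
#' @export
lie_gamma_along <- function(s, p, u) {
  s <- as_state(s)
  sum(gamma_grad(s, p) * rhs_raw(s, u, p))
}

# point on the singular line with abscissa x1
line_point <- function(x1, L) c(x1, (L$c - L$a * x1) / L$b)

#' Admissible singular segment
#'
#' The sub-segment of the singular line where a singular dose inside
#' `[0, M]` exists, i.e. where \eqn{L_Y\gamma > 0 > L_X\gamma}. Returned as
#' the `x1` interval `[s_bar, c/a]`, with `s_bar` the root of
#' \eqn{L_Y\gamma = 0} along the line (found by bisection to absolute
#' tolerance 1e-10); empty when \eqn{L_Y\gamma \le 0} already at the
#' `x2 = 0` end of the line, or when the line is not interior.
#'
#' @param p a [params()] object; requires `alpha > 0`.
#' @return A list with `empty` (logical) and, when non-empty, `x1_min`
#'   (`s_bar`), `x1_max` (`c/a`) and the line coefficients.
#' @export
singular_segment <- function(p) {
  if (p$alpha <= 0)
    return(list(empty = TRUE, reason = "alpha = 0: no singular arcs"))
  if (!isTRUE(line_interior(p)))
    return(list(empty = TRUE, reason = "singular line not interior to the treatment region"))
  L <- line_coefficients(p)
  x1_max <- L$c / L$a
  gY <- function(x1) lie_gamma_along(line_point(x1, L), p, p$M)
  if (gY(x1_max) <= 0)
    return(list(empty = TRUE,
                reason = "L_Y gamma <= 0 at the x2 = 0 end: maximal dose too small"))
  lo <- x1_max * 1e-12; hi <- x1_max
  if (gY(lo) > 0) {
    # whole line admissible down to x1 -> 0+
    return(list(empty = FALSE, x1_min = lo, x1_max = x1_max, line = L))
  }
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (gY(mid) > 0) hi <- mid else lo <- mid
  }
  list(empty = FALSE, x1_min = hi, x1_max = x1_max, line = L)
}

#' Geometric diagnostic report
#'
#' Computes every phase-plane quantity for a parameter set as a flat record:
#' line coefficients, intercepts, tangency point (if any), singular segment
#' endpoints (if any) and the admissibility booleans. Used by the
#' `check-geometry` CLI subcommand.
#'
#' @param p a [params()] object.
#' @return A named list of scalars/booleans (`NA` for undefined entries).
#' @export
geometry_report <- function(p) {
  L <- line_coefficients(p)
  tp <- tryCatch(tangency_point(p), error = function(e) NULL)
  seg <- singular_segment(p)
  list(
    a = L$a, b = L$b, c = L$c,
    x1_intercept = if (L$a > 0) L$c / L$a else NA_real_,
    x2_intercept = L$c / L$b,
    line_interior = isTRUE(line_interior(p)),
    tangency_exists = !is.null(tp),
    x1_star = if (!is.null(tp)) tp$x1s else NA_real_,
    x2_star = if (!is.null(tp)) tp$x2s else NA_real_,
    singular_segment_nonempty = !isTRUE(seg$empty),
    s_bar = if (!isTRUE(seg$empty)) seg$x1_min else NA_real_,
    s_max = if (!isTRUE(seg$empty)) seg$x1_max else NA_real_,
    max_dose_kills_sensitive = max_dose_kills_sensitive(p)
  )
}
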