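# Shared fixtures and independent numerical oracles.

p_ref <- params_preset()                       # reference parameter set
p_fig8 <- params_preset(d = 0.05, alpha = 0.005)
p_fig10 <- params_preset(d = 0.05, alpha = 0.1)

# point on the singular line at abscissa x1
on_line <- function(x1, p) {
  L <- line_coefficients(p)
  c(x1, (L$c - L$a * x1) / L$b)
}

# central finite-difference directional derivative oracle
fd_directional <- function(fun, s, v, h = 1e-6) {
  (fun(s + h * v) - fun(s - h * v)) / (2 * h)
}

# central finite-difference Lie bracket oracle: [f,g] = Dg f - Df g
fd_bracket <- function(s, p, h = 1e-6) {
  jac <- function(field) {
    cbind((field(s + c(h, 0)) - field(s - c(h, 0))) / (2 * h),
          (field(s + c(0, h)) - field(s - c(0, h))) / (2 * h))
  }
  f <- function(x) drift_field(x, p)
  g <- function(x) control_field(x, p)
  as.numeric(jac(g) %*% f(s) - jac(f) %*% g(s))
}

# dense polyline of a constant-dose flow (package integrator, no events)
dense_flow <- function(q, u, tau, p, n = 2000) {
  chemopt:::integrate_leg(q, 0, tau, function(y) u, NULL, p,
                          1e-12, 1e-12, n)$states
}

# 2-D fan quadrature of F over the region enclosed by a polyline curve from
# q1 to q2 and the straight chord back; signed triangle areas
fan_quadrature <- function(curve, q1, F) {
  tot <- 0
  for (i in seq_len(nrow(curve) - 1)) {
    P <- curve[i, ]; Q <- curve[i + 1, ]
    A <- ((P[1] - q1[1]) * (Q[2] - q1[2]) -
            (P[2] - q1[2]) * (Q[1] - q1[1])) / 2
    tot <- tot + F((q1 + P + Q) / 3) * A
  }
  tot
}

# Lie-derivative residual of the switching-function ODE along a lift series
switching_ode_residual <- function(lift, p) {
  vapply(seq_along(lift$times), function(i) {
    s <- lift$states[i, ]
    sum(lift$lam[i, ] * lie_bracket_fg(s, p)) -
      (gamma_coeff(s, p) +
         (beta_coeff(s, p) - lift$doses[i] * gamma_coeff(s, p)) *
           lift$Phi[i])
  }, numeric(1))
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(abs(x - y) / max(abs(y), 1e-300), tol)
}
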