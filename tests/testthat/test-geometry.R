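test_that("singular-line coefficients follow the closed forms", {
  p <- params(pr = 0.2, eps = 1e-6, alpha = 0.01, d = 1, M = 5, Vc = 0.9,
              x10 = 0.01)
  L <- line_coefficients(p)
  expect_equal(L$a, 0.01 * (0.8 + 1 / 1.01), tolerance = 1e-12)
  expect_equal(L$b, 0.208)
  expect_equal(L$c, 0.008001)
  # alpha = 0: horizontal line, never interior with eps > 0
  p0 <- params_preset(alpha = 0)
  L0 <- line_coefficients(p0)
  expect_equal(L0$a, 0)
  expect_equal(L0$b, p0$d * p0$pr)
  expect_equal(L0$c, p0$eps * p0$d)
  expect_false(line_interior(p0))
  # eps = 0 drops the eps*d term
  pe <- params_preset(eps = 0)
  expect_equal(line_coefficients(pe)$c, pe$alpha * (1 - pe$pr))
  # the reference set has the line interior to the treatment region
  expect_true(line_interior(p_ref))
})

test_that("det A equals the cross product of the frame and vanishes only at x1 = 0", {
  expect_equal(det_A(c(0, 0.4), p_ref), 0)
  for (s in list(c(0.5, 0.2), c(0.1, 0.7), c(0.02, 0.01))) {
    f <- drift_field(s, p_ref); g <- control_field(s, p_ref)
    expect_equal(det_A(s, p_ref), f[1] * g[2] - f[2] * g[1],
                 tolerance = 1e-12)
    expect_gt(det_A(s, p_ref), 0)   # frame independent: no abnormal lifts
  }
  # on the V = 1 edge only the eps*d term survives
  expect_equal(det_A(c(0.5, 0.5), p_ref), 2.5e-7, tolerance = 1e-12)
})

test_that("the bracket decomposition [f,g] = gamma f + beta g holds on a grid", {
  xs <- seq(0.02, 0.85, length.out = 50)
  worst <- 0
  for (x1 in xs) for (x2 in seq(0.01, 0.98 - x1, length.out = 50)) {
    s <- c(x1, x2)
    br <- lie_bracket_fg(s, p_ref)
    dec <- gamma_coeff(s, p_ref) * drift_field(s, p_ref) +
      beta_coeff(s, p_ref) * control_field(s, p_ref)
    nb <- sqrt(sum(br^2))
    if (nb > 0) worst <- max(worst, sqrt(sum((br - dec)^2)) / nb)
  }
  expect_lt(worst, 1e-9)
})

test_that("the exact bracket agrees with a finite-difference oracle", {
  for (s in list(c(0.3, 0.2), c(0.05, 0.6), c(0.6, 0.1))) {
    expect_lt(max(abs(lie_bracket_fg(s, p_ref) - fd_bracket(s, p_ref))),
              1e-5)
  }
  expect_equal(lie_bracket_fg(c(0, 0.3), p_ref), c(0, 0))
})

test_that("gamma vanishes on the line and changes sign across it", {
  L <- line_coefficients(p_ref)
  s_on <- on_line(0.2, p_ref)
  expect_equal(gamma_coeff(s_on, p_ref), 0, tolerance = 1e-12)
  s_below <- s_on - c(0, 0.01)    # a x1 + b x2 < c
  s_above <- s_on + c(0, 0.01)
  expect_gt(gamma_coeff(s_below, p_ref), 0)
  expect_lt(gamma_coeff(s_above, p_ref), 0)
  # sign(gamma) = sign(c - a x1 - b x2) on random interior points
  set.seed(11)
  for (k in 1:50) {
    s <- c(stats::runif(1, 0.01, 0.6), stats::runif(1, 0.01, 0.35))
    expect_equal(sign(gamma_coeff(s, p_ref)),
                 sign(L$c - L$a * s[1] - L$b * s[2]))
  }
  # beta positive inside the treatment region
  set.seed(12)
  for (k in 1:50) {
    s <- stats::runif(2, 0.01, 0.44)
    expect_gt(beta_coeff(s, p_ref), 0)
  }
  expect_error(gamma_coeff(c(0, 0.2), p_ref), "x1 > 0")
})

test_that("tangency point matches the closed form and its defining property", {
  p <- params_preset(d = 0.05)   # Vc = 0.9, pr = 0.2, M = 5
  tp <- tangency_point(p)
  expect_equal(round(tp$x1s, 4), 0.1059)
  expect_equal(round(tp$x2s, 4), 0.7941)
  # the maximal-dose field is tangent to N there
  expect_equal(lie_V_along(c(tp$x1s, tp$x2s), p, p$M), 0, tolerance = 1e-12)
  # volume rises under max dose below x1*, falls above it
  expect_gt(lie_V_along(c(tp$x1s - 0.05, p$Vc - tp$x1s + 0.05), p, p$M), 0)
  expect_lt(lie_V_along(c(tp$x1s + 0.05, p$Vc - tp$x1s - 0.05), p, p$M), 0)
  # no-dose flow grows the volume in the interior
  expect_gt(lie_V_along(c(0.1, 0.2), p, 0), 0)
  # pr = 0 puts the tangency point on the x2 axis
  expect_equal(tangency_point(params_preset(pr = 0, d = 0.05))$x1s, 0)
  # insufficient dose: no tangency point on N
  expect_error(tangency_point(params_preset(d = 0.05, M = 1)), "tangency")
})

test_that("gamma directional derivatives agree with finite differences", {
  for (u in c(0, 2, 5)) {
    for (x1 in c(0.1, 0.3, 0.44)) {
      s <- on_line(x1, p_ref)
      v <- model_rhs(s, u, p_ref)
      fd <- fd_directional(function(x) gamma_coeff(x, p_ref), s, v)
      expect_lt(abs(lie_gamma_along(s, p_ref, u) - fd), 1e-5)
    }
  }
})

test_that("the admissible singular segment is located correctly", {
  seg <- singular_segment(p_ref)
  expect_false(seg$empty)
  L <- seg$line
  # endpoint s_bar is the root of L_Y gamma along the line
  sb <- on_line(seg$x1_min, p_ref)
  expect_lt(abs(lie_gamma_along(sb, p_ref, p_ref$M)), 1e-8)
  # independent oracle: sign change located on a 1e4-point scan
  xs <- seq(seg$x1_max * 1e-3, seg$x1_max, length.out = 1e4)
  gY <- vapply(xs, function(x1)
    lie_gamma_along(on_line(x1, p_ref), p_ref, p_ref$M), numeric(1))
  flip <- xs[max(which(gY <= 0))]
  expect_lt(abs(flip - seg$x1_min), diff(xs[1:2]) * 1.5)
  # L_X gamma < 0 and L_Y gamma > 0 on the interior of the segment
  mid <- on_line((seg$x1_min + seg$x1_max) / 2, p_ref)
  expect_lt(lie_gamma_along(mid, p_ref, 0), 0)
  expect_gt(lie_gamma_along(mid, p_ref, p_ref$M), 0)
  # L_Y gamma > 0 at the x2 = 0 intercept, < 0 approaching the x2 axis
  expect_gt(lie_gamma_along(c(L$c / L$a, 0), p_ref, p_ref$M), 0)
  expect_lt(lie_gamma_along(on_line(1e-4, p_ref), p_ref, p_ref$M), 0)
  # no induction, or insufficient maximal dose: no singular arc
  expect_true(singular_segment(params_preset(alpha = 0))$empty)
  expect_true(singular_segment(params_preset(M = 0.5))$empty)
})

test_that("maximal-dose kill condition follows its threshold", {
  expect_true(max_dose_kills_sensitive(params_preset(alpha = 0.1, d = 1)))
  expect_false(max_dose_kills_sensitive(params_preset(alpha = 0.005,
                                                      d = 0.05)))
  # eps near 1 sends the threshold (1 - eps)/(alpha + d) toward zero
  expect_true(max_dose_kills_sensitive(
    params(pr = 0.2, eps = 0.9, alpha = 0.5, d = 0.5, M = 0.2,
           Vc = 0.05, x10 = 0.01)))
})

test_that("the geometry report is a complete flat record", {
  rep <- geometry_report(params_preset(d = 0.05))
  expect_true(rep$tangency_exists)
  expect_equal(round(rep$x1_star, 4), 0.1059)
  expect_true(is.finite(rep$a) && is.finite(rep$b) && is.finite(rep$c))
  rep0 <- geometry_report(params_preset(alpha = 0))
  expect_false(rep0$line_interior)
  expect_true(rep0$singular_segment_nonempty == FALSE)
})
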