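test_that("volume-output observables match their closed forms", {
  obs <- lie_observables(p_ref)
  expect_equal(obs$h0, 0.01)
  expect_equal(obs$Lg_h, -0.01)
  expect_equal(obs$Lg2_h, 0.0101)
  # eps = 0 reduces L_f L_g h to -d x10 (1 - x10)
  pe <- params_preset(eps = 0)
  expect_equal(lie_observables(pe)$LfLg_h, -pe$d * pe$x10 * (1 - pe$x10))
  expect_error(lie_observables(params_preset(x10 = 0.01, x20 = 0.1)),
               "x20 = 0")
})

test_that("observables agree with direct Lie differentiation of the output", {
  # numerical oracle: iterate gradient-based Lie derivatives of h = x1 + x2
  p <- params(pr = 0.37, eps = 3e-4, alpha = 0.08, d = 0.9, M = 5,
              Vc = 0.9, x10 = 0.07, x20 = 0)
  x0 <- c(p$x10, 0)
  h <- 1e-5
  num_grad <- function(fun, s) c(
    (fun(s + c(h, 0)) - fun(s - c(h, 0))) / (2 * h),
    (fun(s + c(0, h)) - fun(s - c(0, h))) / (2 * h))
  lie <- function(fun, field) function(s) sum(num_grad(fun, s) * field(s))
  # unvalidated field evaluations: the difference stencil steps just outside
  # the state triangle at x2 = 0
  f <- function(s) chemopt:::rhs_raw(s, 0, p)
  g <- function(s) chemopt:::rhs_raw(s, 1, p) - chemopt:::rhs_raw(s, 0, p)
  hfun <- function(s) s[1] + s[2]
  obs <- lie_observables(p)
  expect_equal(obs$Lg_h, lie(hfun, g)(x0), tolerance = 1e-6)
  expect_equal(obs$Lg2_h, lie(lie(hfun, g), g)(x0), tolerance = 1e-5)
  expect_equal(obs$LfLg_h, lie(lie(hfun, g), f)(x0), tolerance = 1e-5)
  expect_equal(obs$LgLf_h, lie(lie(hfun, f), g)(x0), tolerance = 1e-5)
})

test_that("parameter recovery inverts the observables exactly", {
  # the reference set round-trips
  rec <- recover_params(lie_observables(p_ref))
  expect_equal(rec$x10, p_ref$x10); expect_equal(rec$d, p_ref$d)
  expect_equal(rec$alpha, p_ref$alpha, tolerance = 1e-9)
  expect_lt(abs(rec$eps - p_ref$eps), 1e-12)
  expect_equal(rec$pr, p_ref$pr, tolerance = 1e-9)
  # a second explicit set
  p2 <- params(pr = 0.5, eps = 1e-4, alpha = 0.02, d = 0.7, M = 5,
               Vc = 0.9, x10 = 0.05, x20 = 0)
  rec2 <- recover_params(lie_observables(p2))
  for (k in c("x10", "d", "alpha", "eps", "pr"))
    expect_rel_equal(rec2[[k]], p2[[k]], 1e-9)
})

test_that("recovery round-trips over random parameter draws", {
  set.seed(20260925)
  n_fail <- 0
  for (k in seq_len(1000)) {
    p <- params(pr = stats::runif(1, 0, 0.99),
                eps = stats::runif(1, 0, 1e-2),
                alpha = stats::runif(1, 1e-4, 1),
                d = stats::runif(1, 1e-2, 2),
                M = 5, Vc = 0.9,
                x10 = stats::runif(1, 1e-3, 0.5), x20 = 0)
    rec <- recover_params(lie_observables(p))
    ok <- abs(rec$x10 - p$x10) <= 1e-9 * max(p$x10, 1) &&
      abs(rec$d - p$d) <= 1e-9 * p$d &&
      abs(rec$alpha - p$alpha) <= 1e-9 * max(p$alpha, 1e-4) &&
      abs(rec$eps - p$eps) <= 1e-9 &&
      abs(rec$pr - p$pr) <= 1e-6 * max(p$pr, 1e-3)
    if (!ok) n_fail <- n_fail + 1
  }
  expect_equal(n_fail, 0)
})

test_that("distinct parameters produce distinct observables", {
  set.seed(42)
  draw <- function() params(pr = stats::runif(1, 0, 0.99),
                            eps = stats::runif(1, 0, 1e-2),
                            alpha = stats::runif(1, 1e-4, 1),
                            d = stats::runif(1, 1e-2, 2),
                            M = 5, Vc = 0.9,
                            x10 = stats::runif(1, 1e-3, 0.5), x20 = 0)
  min_dist <- Inf
  for (k in seq_len(1e4)) {
    o1 <- unlist(unclass(lie_observables(draw())))
    o2 <- unlist(unclass(lie_observables(draw())))
    min_dist <- min(min_dist, sqrt(sum((o1 - o2)^2)))
  }
  expect_gt(min_dist, 0)
})

test_that("recovered cytotoxicity is linear in the first-order observable", {
  obs <- lie_observables(p_ref)
  d0 <- recover_params(obs)$d
  obs$Lg_h <- 1.1 * obs$Lg_h
  # rescaling Lg_h rescales d by the same factor, with Lg2_h etc. following
  expect_rel_equal(recover_params(obs)$d, 1.1 * d0, 1e-12)
})

test_that("degenerate observables are rejected or flagged", {
  obs <- lie_observables(p_ref)
  obs$Lg_h <- 0.01
  expect_error(recover_params(obs), "negative")
  # no induction: pr cannot be recovered from this observable set
  rec0 <- recover_params(lie_observables(params_preset(alpha = 0)))
  expect_true(is.na(rec0$pr))
  expect_equal(rec0$alpha, 0, tolerance = 1e-12)
})
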