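test_that("no-dose failure time matches the logistic closed form", {
  # with eps ~ 0 the volume grows logistically from x10 to Vc
  tc <- time_to_failure(p_ref, control_X())
  closed <- log(p_ref$Vc * (1 - p_ref$x10) / (p_ref$x10 * (1 - p_ref$Vc)))
  expect_rel_equal(tc, closed, 0.01)
})

test_that("starting on the boundary with no dose fails immediately", {
  p <- params(pr = 0.2, eps = 1e-6, alpha = 0.01, d = 1, M = 5, Vc = 0.9,
              x10 = 0.45, x20 = 0.45)
  tr <- integrate_trajectory(p, control_X())
  expect_equal(tr$t_c, 0)
  expect_identical(tr$events$kind[nrow(tr$events)], "FAILURE")
})

test_that("failure time is monotone in the critical volume", {
  ctrls <- list(control_X(), control_Y(), control_const(1))
  for (ctrl in ctrls) {
    tcs <- vapply(c(0.5, 0.7, 0.9), function(vc)
      time_to_failure(params_preset(Vc = vc), ctrl), numeric(1))
    expect_true(all(diff(tcs) > 0))
  }
})

test_that("a weak drug still beats no treatment when applied maximally", {
  p <- params_preset(d = 0.001, alpha = 0.001)
  expect_gt(time_to_failure(p, control_Y()),
            time_to_failure(p, control_X()))
})

test_that("sliding arcs stay on the boundary and apply the feedback dose", {
  p <- params_preset(d = 0.5, alpha = 0.001)
  tr <- integrate_trajectory(p, structured_control(1, c(2, 2), p),
                             dense = 800)
  ev <- tr$events
  t_on <- ev$time[ev$kind == "SLIDING_START"]
  t_off <- ev$time[ev$kind == "SLIDING_END"]
  expect_length(t_on, 1); expect_length(t_off, 1)
  idx <- which(tr$times > t_on & tr$times < t_off)
  expect_gt(length(idx), 100)
  V <- rowSums(tr$states[idx, ])
  expect_lt(max(abs(V - p$Vc)), 1e-7)
  up <- apply(tr$states[idx, ], 1, u_path, p = p)
  expect_lt(max(abs(tr$doses[idx] - up)), 1e-9)
  # sliding exits at the tangency point, where the feedback saturates
  tp <- tangency_point(p)
  exit <- tr$states[max(idx) + 1, ]
  expect_lt(max(abs(exit - c(tp$x1s, tp$x2s))), 1e-4)
  # failure is recorded at the exit (terminal max-dose arc adds no time)
  expect_equal(tr$t_c, t_off)
})

test_that("halving integrator tolerances leaves the failure time unchanged", {
  ctrl <- structured_control(1, c(2, 2), p_ref)
  t1 <- time_to_failure(p_ref, ctrl, rtol = 1e-10, atol = 1e-10)
  t2 <- time_to_failure(p_ref, ctrl, rtol = 5e-11, atol = 5e-11)
  expect_rel_equal(t1, t2, 1e-4)
})

test_that("the clock-form integral reproduces elapsed time on bang arcs", {
  p <- p_fig10
  for (u in c(0, p$M)) {
    ctrl <- piecewise_control(control_arc(if (u == 0) "ZERO" else "MAX",
                                          duration = 5))
    tr <- integrate_trajectory(p, ctrl, dense = 2000)
    expect_rel_equal(clock_form_time(tr, p), 5, 0.005)
  }
  # two-arc schedule
  ctrl <- piecewise_control(control_arc("MAX", duration = 3),
                            control_arc("ZERO", duration = 2))
  tr <- integrate_trajectory(p_ref, ctrl, dense = 2000)
  expect_rel_equal(clock_form_time(tr, p_ref), 5, 0.005)
  # zero-length path
  tr0 <- tr; tr0$states <- tr$states[1, , drop = FALSE]
  expect_equal(clock_form_time(tr0, p_ref), 0)
})

test_that("bang-bang transfers between singular points are slower than singular ones", {
  p <- p_ref
  seg <- singular_segment(p)
  q1 <- on_line(0.35, p); q2 <- on_line(0.30, p)
  tS <- singular_transfer_time(q1, q2, p)
  for (word in c("XY", "YX")) {
    sh <- shoot_between(q1, q2, p, word)
    expect_lt(abs(sh$miss), 1e-8)
    expect_lt(tS, sh$t_first + sh$t_second)
  }
  # trivial shooting
  triv <- shoot_between(q1, q1, p, "XY")
  expect_equal(c(triv$t_first, triv$t_second), c(0, 0))
})

test_that("the time excess of a bang-bang transfer equals the Stokes surface integral", {
  p <- p_ref
  q1 <- on_line(0.35, p); q2 <- on_line(0.30, p)
  tS <- singular_transfer_time(q1, q2, p)
  sh <- shoot_between(q1, q2, p, "XY")
  excess <- sh$t_first + sh$t_second - tS
  curve <- rbind(dense_flow(q1, 0, sh$t_first, p),
                 dense_flow(chemopt:::flow_const(q1, 0, sh$t_first, p),
                            p$M, sh$t_second, p)[-1, ])
  quad <- fan_quadrature(curve, q1,
                         function(x) -gamma_coeff(x, p) / det_A(x, p))
  expect_gt(excess, 0)
  expect_rel_equal(abs(quad), excess, 0.02)
})

test_that("trajectory export writes the standard table and event record", {
  tr <- integrate_trajectory(p_fig10, control_Y(), dense = 50)
  csv <- tempfile(fileext = ".csv"); ej <- tempfile(fileext = ".json")
  df <- write_trajectory(tr, csv, ej)
  expect_identical(names(df), c("t", "x1", "x2", "u", "V"))
  back <- utils::read.csv(csv)
  expect_equal(nrow(back), length(tr$times))
  evj <- jsonlite::fromJSON(ej)
  expect_true("FAILURE" %in% evj$events$kind)
  expect_equal(evj$t_c, tr$t_c, tolerance = 1e-8)
})
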