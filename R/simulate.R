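# Event-driven integration of (state, control) pairs.
#
# Arcs are integrated one at a time with deSolve::lsodar, whose root finding
# locates boundary contact (psi = 0), sliding saturation (u_p = M) and
# singular exit (u_s = M). Sliding is realized by applying the u_path
# feedback exactly, not by projecting onto the boundary.

DEFAULT_RTOL <- 1e-10
DEFAULT_ATOL <- 1e-10

# clamp tiny negative populations produced by the integrator; the threshold
# scales with the absolute tolerance, since overshoot of a compartment that
# truly decayed to ~0 is of that order
clip_state <- function(y, atol = DEFAULT_ATOL) {
  thr <- max(OMEGA_TOL, 1e3 * atol)
  neg <- y < 0 & y >= -thr
  y[neg] <- 0
  y
}

arc_dose <- function(arc, p) {
  switch(arc$mode, ZERO = 0, MAX = p$M, CONST = arc$value, NA_real_)
}

# one lsodar leg; returns list(times, states, troot, reached_end)
integrate_leg <- function(y0, t0, t1, ufun, rootfun, p, rtol, atol, n_out) {
  times <- if (n_out > 2) seq(t0, t1, length.out = n_out) else c(t0, t1)
  derivs <- function(t, y, parms) list(rhs_raw(y, ufun(y), p))
  out <- if (is.null(rootfun)) {
    deSolve::lsoda(y = y0, times = times, func = derivs, parms = NULL,
                   rtol = rtol, atol = atol, maxsteps = 1e5)
  } else {
    deSolve::lsodar(y = y0, times = times, func = derivs, parms = NULL,
                    rtol = rtol, atol = atol, maxsteps = 1e5,
                    rootfunc = function(t, y, parms) rootfun(y))
  }
  st <- unname(out[, 2:3, drop = FALSE])
  if (any(!is.finite(st)))
    stop("integration failure: non-finite state")
  troot <- attr(out, "troot")
  list(times = out[, 1], states = st,
       troot = if (length(troot)) troot[1] else NA_real_)
}

# dense variant for condition-terminated arcs: the end time is unknown in
# advance, so the leg is located first (endpoints only) and then re-run on a
# dense grid up to the located end
leg_with_dense <- function(y0, t0, t_cap, ufun, rootfun, p, rtol, atol,
                           n_out) {
  if (n_out <= 2 || is.null(rootfun))
    return(integrate_leg(y0, t0, t_cap, ufun, rootfun, p, rtol, atol, n_out))
  first <- integrate_leg(y0, t0, t_cap, ufun, rootfun, p, rtol, atol, 2)
  t_end <- first$times[length(first$times)]
  if (t_end <= t0) return(first)
  second <- integrate_leg(y0, t0, t_end, ufun, NULL, p, rtol, atol, n_out)
  # the root-located end state is the accurate event state; the dense re-run
  # only fills in the interior of the arc
  second$states[nrow(second$states), ] <- first$states[nrow(first$states), ]
  list(times = second$times, states = second$states, troot = first$troot)
}

#' Integrate a trajectory under a piecewise control
#'
#' Runs the model under a [piecewise_control()] schedule with event handling:
#' contact with the failure boundary `N` (volume reaching `Vc`) is located by
#' root finding; if the schedule continues with a `PATH_FEEDBACK` arc the
#' trajectory slides along `N` under the exact feedback dose until the dose
#' saturates at `M` (which happens at the tangency point), otherwise contact
#' with rising volume is treatment failure. After saturation the terminal
#' maximal-dose arc starts at the tangency point, where the volume has a
#' rising second derivative, so failure is recorded there (the extra time is
#' measure zero).
#'
#' @param p a [params()] object.
#' @param ctrl a `chemopt_control`.
#' @param t_max safety horizon; integration stops there if no failure occurs.
#' @param dense number of output points per arc (2 = endpoints only; use
#'   2000+ for clock-form work).
#' @param rtol,atol integrator tolerances.
#' @return A `chemopt_trajectory`: list with `times`, `states` (matrix),
#'   `doses`, `events` (data.frame `time`, `kind`), `t_c` (`NA` if the
#'   horizon was reached first), `p`, `ctrl`.
#' @export
#' @examples
#' p <- params_preset(d = 0.05, alpha = 0.1)
#' tr <- integrate_trajectory(p, control_Y())
#' tr$t_c   # about 24.2
integrate_trajectory <- function(p, ctrl, t_max = 1e4, dense = 200,
                                 rtol = DEFAULT_RTOL, atol = DEFAULT_ATOL) {
  stopifnot(inherits(ctrl, "chemopt_control"))
  y <- clip_state(unname(initial_state(p)), atol)
  if (!in_omega_c(y, p)) stop("initial state outside the treatment region")
  t <- 0
  times <- t; states <- matrix(y, nrow = 1); doses <- NA_real_
  events <- data.frame(time = numeric(), kind = character())
  arc_log <- data.frame(mode = character(), t0 = numeric(), t1 = numeric())
  t_c <- NA_real_
  add_event <- function(tt, kind)
    events <<- rbind(events, data.frame(time = tt, kind = kind))
  log_arc <- function(mode, t0, t1)
    arc_log <<- rbind(arc_log, data.frame(mode = mode, t0 = t0, t1 = t1))
  append_leg <- function(leg, uvals) {
    n <- length(leg$times)
    if (n > 1) {
      times <<- c(times, leg$times[-1])
      states <<- rbind(states, leg$states[-1, , drop = FALSE])
      doses <<- c(doses, uvals[-1])
    }
  }
  arcs <- ctrl$arcs
  i <- 1L
  while (i <= length(arcs) && t < t_max && is.na(t_c)) {
    arc <- arcs[[i]]
    nxt <- if (i < length(arcs)) arcs[[i + 1L]] else NULL

    if (arc$mode %in% c("ZERO", "MAX", "CONST")) {
      u <- arc_dose(arc, p)
      if (u < 0 || u > p$M + OMEGA_TOL)
        stop("constant dose outside [0, M]")
      t_end <- if (!is.null(arc$duration)) min(t + arc$duration, t_max) else t_max
      # starting on (or numerically at) the boundary
      if (constraint_psi(y, p) > -1e-12) {
        if (lie_V_along(y, p, u) > 0) {
          kind <- if (identical(arc$until, "HIT_BOUNDARY") ||
                      (!is.null(nxt) && nxt$mode == "PATH_FEEDBACK"))
            "BOUNDARY_CONTACT" else "FAILURE"
          log_arc(arc$mode, t, t)
          add_event(t, kind)
          if (kind == "FAILURE") { t_c <- t; break }
          i <- i + 1L; next
        }
        # volume falling: nudge off the root surface before enabling roots
        h <- 1e-9
        y <- clip_state(y + h * rhs_raw(y, u, p), atol)
        t <- t + h
      }
      if (t_end <= t) { i <- i + 1L; next }
      leg <- leg_with_dense(y, t, t_end, function(yy) u,
                            function(yy) yy[1] + yy[2] - p$Vc,
                            p, rtol, atol, dense)
      append_leg(leg, rep(u, length(leg$times)))
      y <- clip_state(leg$states[nrow(leg$states), ], atol)
      t0_arc <- leg$times[1]
      t <- leg$times[length(leg$times)]
      log_arc(arc$mode, t0_arc, t)
      if (!is.na(leg$troot)) {                    # boundary contact
        if (identical(arc$until, "HIT_BOUNDARY") ||
            (!is.null(nxt) && nxt$mode == "PATH_FEEDBACK")) {
          add_event(t, "BOUNDARY_CONTACT")
          i <- i + 1L
        } else {
          add_event(t, "FAILURE"); t_c <- t
        }
      } else if (t >= t_max) {
        break
      } else {
        i <- i + 1L                               # clocked arc completed
      }

    } else if (arc$mode == "PATH_FEEDBACK") {
      if (abs(constraint_psi(y, p)) > 1e-8)
        stop("PATH_FEEDBACK arc must start on the boundary N")
      add_event(t, "SLIDING_START")
      if (u_path_raw(y, p) >= p$M - 1e-12) {
        # infeasible (or exactly saturated) on entry: zero-length slide
        add_event(t, "SLIDING_END")
        log_arc("PATH_FEEDBACK", t, t)
        i <- i + 1L
      } else {
        leg <- leg_with_dense(y, t, t_max, function(yy) u_path_raw(yy, p),
                              function(yy) u_path_raw(yy, p) - p$M,
                              p, rtol, atol, dense)
        uvals <- apply(leg$states, 1,
                       function(yy) min(u_path_raw(yy, p), p$M))
        append_leg(leg, uvals)
        y <- clip_state(leg$states[nrow(leg$states), ], atol)
        t <- leg$times[length(leg$times)]
        log_arc("PATH_FEEDBACK", leg$times[1], t)
        if (is.na(leg$troot)) break               # horizon during slide
        add_event(t, "SLIDING_END")
        i <- i + 1L
      }
      # terminal maximal dose from the saturation point fails immediately:
      # psi = 0, psi' = 0 and psi'' > 0 there. Verify the sign numerically.
      if (i <= length(arcs) && arcs[[i]]$mode == "MAX" &&
          identical(arcs[[i]]$until, "FAILURE")) {
        h <- 1e-5
        yh <- y + h * rhs_raw(y, p$M, p)
        yh <- yh + h * (rhs_raw(yh, p$M, p) - rhs_raw(y, p$M, p)) / 2
        if (constraint_psi(yh, p) > constraint_psi(y, p) - 1e-14) {
          log_arc("MAX", t, t)
          add_event(t, "FAILURE"); t_c <- t
        }
      }

    } else if (arc$mode == "SINGULAR") {
      L <- line_coefficients(p)
      if (abs(L$a * y[1] + L$b * y[2] - L$c) > 1e-6)
        stop("SINGULAR arc must start on the singular line")
      t_end <- if (!is.null(arc$duration)) min(t + arc$duration, t_max) else t_max
      leg <- leg_with_dense(y, t, t_end,
                            function(yy) min(u_singular_algebraic(yy, p), p$M),
                            function(yy) u_singular_algebraic(yy, p) - p$M,
                            p, rtol, atol, dense)
      uvals <- apply(leg$states, 1,
                     function(yy) min(u_singular_algebraic(yy, p), p$M))
      append_leg(leg, uvals)
      y <- clip_state(leg$states[nrow(leg$states), ], atol)
      log_arc("SINGULAR", leg$times[1], leg$times[length(leg$times)])
      t <- leg$times[length(leg$times)]
      i <- i + 1L
    }
  }
  doses[1] <- doses[min(2, length(doses))]
  structure(list(times = times, states = states, doses = doses,
                 events = events, arc_log = arc_log, t_c = t_c,
                 p = p, ctrl = ctrl),
            class = "chemopt_trajectory")
}

#' @export
print.chemopt_trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d points over [0, %.4g], control %s\n",
              length(x$times), max(x$times), control_label(x$ctrl)))
  if (!is.na(x$t_c)) cat(sprintf("  failure time t_c = %.6g\n", x$t_c))
  else cat("  no failure before the horizon\n")
  if (nrow(x$events))
    for (k in seq_len(nrow(x$events)))
      cat(sprintf("  event %-16s at t = %.6g\n",
                  x$events$kind[k], x$events$time[k]))
  invisible(x)
}

#' @export
as.data.frame.chemopt_trajectory <- function(x, ...) {
  data.frame(t = x$times, x1 = x$states[, 1], x2 = x$states[, 2],
             u = x$doses, V = rowSums(x$states))
}

#' Time to treatment failure
#'
#' Integrates the schedule and returns the first time the tumor volume
#' reaches the critical volume `Vc`. Failure is guaranteed in finite time
#' for this model (the drug-free equilibrium lies outside the treatment
#' region), so a generous default horizon suffices.
#'
#' @inheritParams integrate_trajectory
#' @param horizon safety horizon; exceeding it raises an error.
#' @return The failure time (scalar).
#' @export
time_to_failure <- function(p, ctrl, horizon = 1e4, dense = 2,
                            rtol = DEFAULT_RTOL, atol = DEFAULT_ATOL) {
  tr <- integrate_trajectory(p, ctrl, t_max = horizon, dense = dense,
                             rtol = rtol, atol = atol)
  if (is.na(tr$t_c))
    stop("no treatment failure before the horizon (", horizon, ")")
  tr$t_c
}

#' Elapsed time via the clock form
#'
#' The one-form \eqn{\omega = (g_2\,dx_1 - g_1\,dx_2)/\det(f,g)} satisfies
#' \eqn{\omega(f) = 1}, \eqn{\omega(g) = 0}, so its line integral along any
#' admissible trajectory equals the elapsed time, independently of the dose
#' applied. Evaluated by the trapezoid rule over the stored polyline, it is
#' the basis of Stokes-type comparisons between bang-bang and singular
#' transfers.
#'
#' @param traj a `chemopt_trajectory` (use a dense output grid).
#' @param p a [params()] object.
#' @return The line integral (a time).
#' @export
clock_form_time <- function(traj, p) {
  st <- traj$states
  n <- nrow(st)
  if (n < 2) return(0)
  dets <- apply(st, 1, det_A, p = p)
  if (any(st[, 1] <= 0) || any(dets <= 0))
    stop("clock form singular: trajectory touches x1 = 0")
  g1 <- -(p$alpha + p$d) * st[, 1]
  g2 <- p$alpha * st[, 1]
  w1 <- g2 / dets
  w2 <- -g1 / dets
  dx1 <- diff(st[, 1]); dx2 <- diff(st[, 2])
  sum((w1[-n] + w1[-1]) / 2 * dx1 + (w2[-n] + w2[-1]) / 2 * dx2)
}

# flow of a constant-dose field for a fixed time (no events)
flow_const <- function(y0, u, tau, p, rtol = 1e-12, atol = 1e-12) {
  if (tau <= 0) return(y0)
  leg <- integrate_leg(y0, 0, tau, function(yy) u, NULL, p, rtol, atol, 2)
  leg$states[nrow(leg$states), ]
}

#' Two-arc shooting between points of the singular segment
#'
#' Connects two nearby points `q1`, `q2` on the singular segment by a
#' bang-bang word (`"XY"`: no dose then maximal dose, through the region
#' below the singular line; `"YX"`: the reverse order, through the region
#' above it). A one-dimensional shooting on the first-arc duration is solved
#' with [stats::uniroot()]; the second arc ends where the flow re-crosses
#' the singular line.
#'
#' By the clock-form/Stokes argument the bang-bang transfer is always slower
#' than the singular transfer between the same points, which is the
#' quantitative content of singular-arc sub-optimality.
#'
#' @param q1,q2 states on the singular segment (`q2` further along the
#'   direction of motion, i.e. smaller `x1`).
#' @param p a [params()] object.
#' @param word `"XY"` or `"YX"`.
#' @return A list with `t_first`, `t_second`, the realized endpoint `q_end`
#'   and `miss` (the terminal `x1` mismatch).
#' @export
shoot_between <- function(q1, q2, p, word = c("XY", "YX")) {
  word <- match.arg(word)
  q1 <- as_state(q1); q2 <- as_state(q2)
  if (isTRUE(all.equal(q1, q2, tolerance = 1e-14)))
    return(list(t_first = 0, t_second = 0, q_end = q2, miss = 0))
  u1 <- if (word == "XY") 0 else p$M
  u2 <- if (word == "XY") p$M else 0
  L <- line_coefficients(p)
  ell <- function(yy) L$a * yy[1] + L$b * yy[2] - L$c

  second_leg <- function(y_mid) {
    # push off the line before root-finding on the return crossing
    h <- 1e-10
    y <- y_mid + h * rhs_raw(y_mid, u2, p)
    leg <- integrate_leg(y, 0, 50, function(yy) u2,
                         function(yy) ell(yy), p, 1e-12, 1e-12, 2)
    if (is.na(leg$troot)) return(NULL)
    list(t = leg$troot + h, q = leg$states[nrow(leg$states), ])
  }
  miss <- function(tau) {
    y_mid <- flow_const(q1, u1, tau, p)
    sl <- second_leg(y_mid)
    if (is.null(sl)) stop("shooting failure: no return to the singular line")
    sl$q[1] - q2[1]
  }
  # bracket: for tau -> 0+ the return crossing approaches q1 (miss > 0);
  # exactly tau = 0 is excluded because the second field starts on the line
  # and its first crossing jumps to the far intersection
  tau_lo <- 1e-8
  m_lo <- miss(tau_lo)
  while (m_lo < 0 && tau_lo > 1e-13) {
    tau_lo <- tau_lo / 10
    m_lo <- miss(tau_lo)
  }
  if (m_lo < 0) stop("shooting failure: points too close to separate arcs")
  tau_hi <- max(1e-3, 2 * tau_lo)
  m_hi <- miss(tau_hi)
  tries <- 0
  while (m_hi > 0 && tries < 60) {
    tau_hi <- tau_hi * 2
    m_hi <- miss(tau_hi)
    tries <- tries + 1
  }
  if (m_hi > 0) stop("shooting failure: could not bracket the switch time")
  sol <- stats::uniroot(miss, c(tau_lo, tau_hi), tol = 1e-13)
  tau <- sol$root
  y_mid <- flow_const(q1, u1, tau, p)
  sl <- second_leg(y_mid)
  list(t_first = tau, t_second = sl$t, q_end = sl$q,
       miss = sl$q[1] - q2[1])
}

#' Transfer time along the singular arc
#'
#' Integrates the singular feedback flow from `q1` until the sensitive
#' fraction reaches that of `q2` (both on the singular segment) and returns
#' the elapsed time.
#'
#' @inheritParams shoot_between
#' @return The singular transfer time.
#' @export
singular_transfer_time <- function(q1, q2, p) {
  q1 <- as_state(q1); q2 <- as_state(q2)
  leg <- integrate_leg(q1, 0, 1e3,
                       function(yy) u_singular_algebraic(yy, p),
                       function(yy) yy[1] - q2[1],
                       p, 1e-12, 1e-12, 2)
  if (is.na(leg$troot)) stop("singular transfer did not reach the target x1")
  leg$troot
}

#' Export a trajectory to CSV / events to JSON
#'
#' @param traj a `chemopt_trajectory`.
#' @param csv path for the `t, x1, x2, u, V` table.
#' @param events_json optional path for the event list.
#' @return Invisibly, the data frame written.
#' @export
write_trajectory <- function(traj, csv, events_json = NULL) {
  df <- as.data.frame(traj)
  utils::write.csv(df, csv, row.names = FALSE)
  if (!is.null(events_json))
    jsonlite::write_json(list(events = traj$events, t_c = traj$t_c),
                         events_json, auto_unbox = TRUE, digits = NA,
                         na = "null")
  invisible(df)
}
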