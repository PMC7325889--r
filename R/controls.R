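# Control laws and the piecewise-control language.
#
# Admissible treatment schedules are concatenations of arcs:
#   ZERO           u = 0            ("X" arc)
#   MAX            u = M            ("Y" arc)
#   CONST          u = value in [0, M]
#   PATH_FEEDBACK  u = u_path(x)    sliding dose holding V = Vc
#   SINGULAR       u = u_singular(x) dose tangent to the singular line
# An arc ends after a fixed duration or at an end condition:
#   HIT_BOUNDARY, FEEDBACK_SATURATES, SING_EXIT, FAILURE.

ARC_MODES <- c("ZERO", "MAX", "CONST", "PATH_FEEDBACK", "SINGULAR")
ARC_UNTIL <- c("HIT_BOUNDARY", "FEEDBACK_SATURATES", "SING_EXIT", "FAILURE")

#' Boundary (sliding) feedback dose
#'
#' The dose that makes the volume derivative vanish,
#' \deqn{u_p(x) = \frac{1}{d}\,\frac{(1 - (x_1+x_2))(x_1 + p_r x_2)}{x_1},}
#' so that a trajectory on the failure boundary `N` slides along it. On `N`
#' it equals `(1-Vc)(1-pr)/d + (1-Vc) pr Vc / (d x1)`: a decreasing function
#' of `x1` that reaches the maximal dose `M` exactly at the tangency point.
#' The value is not clamped; feasibility is a separate test.
#'
#' @inheritParams drift_field
#' @return The (unclamped) feedback dose.
#' @export
u_path <- function(s, p) {
  s <- as_state(s)
  if (s[1] <= 0) stop("boundary feedback undefined at x1 <= 0")
  (1 - (s[1] + s[2])) * (s[1] + p$pr * s[2]) / (p$d * s[1])
}

# guarded variant for use inside integrator closures: trial steps of the
# solver may momentarily leave x1 <= 0 while locating the saturation root
u_path_raw <- function(s, p) {
  x1 <- max(s[1], 1e-12)
  (1 - (s[1] + s[2])) * (x1 + p$pr * s[2]) / (p$d * x1)
}

#' @describeIn u_path Is the sliding dose admissible at a boundary point?
#'   Requires `s` to lie within tolerance of `N` and returns
#'   `0 <= u_path(s) <= M` (the control set is closed, so `u_path = M`
#'   counts as feasible).
#' @export
u_path_feasible <- function(s, p) {
  s <- as_state(s)
  if (abs(constraint_psi(s, p)) > 1e-6)
    stop("feasibility of the sliding dose is defined on the boundary N only")
  up <- u_path(s, p)
  up >= -OMEGA_TOL && up <= p$M + OMEGA_TOL
}

#' Singular feedback dose
#'
#' The unique dose keeping the flow tangent to the singular line,
#' \deqn{u_s(x) = M\,\frac{L_X\gamma(x)}{L_X\gamma(x) - L_Y\gamma(x)},}
#' equivalently (from `a x1' + b x2' = 0`)
#' \deqn{u_s(x) = \frac{(1-V)(a x_1 + p_r b x_2) + \epsilon(b - a)x_1}
#'                     {2\alpha d (1-p_r) x_1}.}
#' Strictly inside `(0, M)` on the interior of the admissible segment and
#' equal to `M` at its lower endpoint `s_bar`, where the maximal-dose field
#' is parallel to the line.
#'
#' @inheritParams drift_field
#' @param tol how far (in `a x1 + b x2 - c`) the state may sit from the
#'   singular line.
#' @return The singular dose.
#' @export
u_singular <- function(s, p, tol = 1e-6) {
  s <- as_state(s)
  L <- line_coefficients(p)
  if (abs(L$a * s[1] + L$b * s[2] - L$c) > tol)
    stop("singular dose is defined on the singular line only")
  gX <- lie_gamma_along(s, p, 0)
  gY <- lie_gamma_along(s, p, p$M)
  if (gX == gY) stop("degenerate: L_X gamma = L_Y gamma")
  p$M * gX / (gX - gY)
}

# algebraically independent form of the singular dose, from a x1' + b x2' = 0
# (the a, b algebra collapses the denominator to 2 alpha d (1 - pr) x1);
# used as a cross-check oracle in tests.
u_singular_algebraic <- function(s, p) {
  L <- line_coefficients(p)
  kap <- 1 - (s[1] + s[2])
  num <- kap * (L$a * s[1] + p$pr * L$b * s[2]) + p$eps * (L$b - L$a) * s[1]
  num / (2 * p$alpha * p$d * (1 - p$pr) * s[1])
}

#' Control arcs and piecewise controls
#'
#' `control_arc()` builds one arc of a treatment schedule; a schedule is an
#' ordered list of arcs built by `piecewise_control()`. Convenience
#' constructors: `control_X()` (never dose), `control_Y()` (always maximal
#' dose), `control_const(u)` (constant dose until failure).
#'
#' @param mode one of `"ZERO"`, `"MAX"`, `"CONST"`, `"PATH_FEEDBACK"`,
#'   `"SINGULAR"`.
#' @param value constant dose (required for `CONST`, must lie in `[0, M]`;
#'   validated at simulation time against `M`).
#' @param duration arc length in time units (`>= 0`), or `NULL` when the arc
#'   is condition-terminated.
#' @param until end condition: `"HIT_BOUNDARY"`, `"FEEDBACK_SATURATES"`,
#'   `"SING_EXIT"` or `"FAILURE"`.
#' @return `control_arc()`: a `chemopt_arc`; the others: a
#'   `chemopt_control`.
#' @export
control_arc <- function(mode, value = NULL, duration = NULL, until = NULL) {
  mode <- match.arg(mode, ARC_MODES)
  if (mode == "CONST") {
    if (is.null(value) || !is.finite(value) || value < 0)
      stop("CONST arcs need a non-negative dose value")
  } else if (!is.null(value)) {
    stop("only CONST arcs carry a dose value")
  }
  if (is.null(duration) && is.null(until))
    stop("an arc needs a duration or an end condition")
  if (!is.null(duration)) {
    if (!is.finite(duration) || duration < 0)
      stop("arc duration must be finite and >= 0")
  }
  if (!is.null(until)) until <- match.arg(until, ARC_UNTIL)
  structure(list(mode = mode, value = value, duration = duration,
                 until = until), class = "chemopt_arc")
}

#' @rdname control_arc
#' @param ... `chemopt_arc` objects (or a single list of them).
#' @export
piecewise_control <- function(...) {
  arcs <- list(...)
  if (length(arcs) == 1L && !inherits(arcs[[1]], "chemopt_arc"))
    arcs <- arcs[[1]]
  if (!length(arcs)) stop("a control needs at least one arc")
  ok <- vapply(arcs, inherits, logical(1), "chemopt_arc")
  if (!all(ok)) stop("all elements must be control_arc objects")
  # drop zero-duration arcs
  keep <- vapply(arcs, function(a) is.null(a$duration) || a$duration > 0,
                 logical(1))
  arcs <- arcs[keep]
  if (!length(arcs)) stop("control collapses to zero length")
  nfb <- sum(vapply(arcs, function(a) a$mode == "PATH_FEEDBACK", logical(1)))
  if (nfb > 1) stop("at most one PATH_FEEDBACK arc is allowed")
  fail_at <- which(vapply(arcs, function(a) identical(a$until, "FAILURE"),
                          logical(1)))
  if (length(fail_at) && fail_at[1] < length(arcs))
    stop("no arcs may follow a FAILURE-terminated arc")
  structure(list(arcs = arcs), class = "chemopt_control")
}

#' @rdname control_arc
#' @export
control_X <- function() {
  piecewise_control(control_arc("ZERO", until = "FAILURE"))
}

#' @rdname control_arc
#' @export
control_Y <- function() {
  piecewise_control(control_arc("MAX", until = "FAILURE"))
}

#' @rdname control_arc
#' @param u constant dose.
#' @export
control_const <- function(u) {
  piecewise_control(control_arc("CONST", value = u, until = "FAILURE"))
}

#' @export
print.chemopt_control <- function(x, ...) {
  cat("piecewise control:", control_label(x), "\n")
  for (a in x$arcs) {
    cat(sprintf("  %-13s %s%s\n", a$mode,
                if (!is.null(a$value)) sprintf("u = %g ", a$value) else "",
                if (!is.null(a$duration)) sprintf("for %g", a$duration)
                else sprintf("until %s", a$until)))
  }
  invisible(x)
}

# compact word label, e.g. "YXupY"
control_label <- function(ctrl) {
  paste(vapply(ctrl$arcs, function(a) switch(a$mode,
    ZERO = "X", MAX = "Y", CONST = sprintf("C(%g)", a$value),
    PATH_FEEDBACK = "up", SINGULAR = "us"), character(1)), collapse = "")
}

#' Structured treatment schedule (YX)^n u_p Y
#'
#' Builds the proven-optimal control family: `n` maximal-dose / no-dose
#' alternations with prescribed switch times, then the no-dose arc runs to
#' boundary contact, then the sliding feedback holds the volume at `Vc`
#' until it saturates at the maximal dose, and a terminal maximal-dose arc
#' runs to failure. Zero-length arcs are dropped, so degenerate switch times
#' yield the sub-families `Y`, `X u_p Y`, `Y X u_p Y`, ... For `n = 0` the
#' schedule is boundary-seeking: drift to the boundary, slide, terminal
#' maximal dose.
#'
#' The sliding arc activates on boundary contact (`|psi| < 1e-8` with the
#' volume rising); the final no-dose arc therefore ends at contact rather
#' than at a clock time, and the last entry of `t_switches` is absorbed by
#' that end condition.
#'
#' @param n number of leading (Y, X) pairs (`>= 0`).
#' @param t_switches non-decreasing switch times, length `2n` (the last one
#'   is a lower bound for the final X arc; see Details).
#' @param p a [params()] object (unused for the arc list itself, kept for
#'   interface symmetry and validation).
#' @return A `chemopt_control`.
#' @export
#' @examples
#' structured_control(1, c(2, 5), params_preset())
structured_control <- function(n, t_switches = numeric(), p = NULL) {
  if (n < 0) stop("n must be >= 0")
  if (length(t_switches) != 2 * n)
    stop("t_switches must have length 2n")
  if (is.unsorted(t_switches))
    stop("switch times must be non-decreasing")
  if (length(t_switches) && t_switches[1] < 0)
    stop("switch times must be non-negative")
  arcs <- list()
  if (n > 0) {
    durs <- diff(c(0, t_switches))
    # arcs 1..2n-1 are clocked; the 2n-th (ZERO) arc runs to boundary contact
    for (i in seq_len(2 * n - 1)) {
      mode <- if (i %% 2 == 1) "MAX" else "ZERO"
      if (durs[i] > 0) arcs[[length(arcs) + 1L]] <- control_arc(mode, duration = durs[i])
    }
    arcs[[length(arcs) + 1L]] <- control_arc("ZERO", until = "HIT_BOUNDARY")
  } else {
    arcs[[1L]] <- control_arc("ZERO", until = "HIT_BOUNDARY")
  }
  arcs[[length(arcs) + 1L]] <- control_arc("PATH_FEEDBACK",
                                           until = "FEEDBACK_SATURATES")
  arcs[[length(arcs) + 1L]] <- control_arc("MAX", until = "FAILURE")
  piecewise_control(arcs)
}

#' Serialize a piecewise control to / from plain lists
#'
#' `control_to_list()` yields a JSON-ready list of
#' `{mode, value?, duration? | until}` records; `control_from_list()`
#' rebuilds the control (accepts a parsed list or a JSON file path).
#'
#' @param ctrl a `chemopt_control`.
#' @param x a list of arc records or a JSON file path.
#' @export
control_to_list <- function(ctrl) {
  lapply(ctrl$arcs, function(a)
    Filter(Negate(is.null),
           list(mode = a$mode, value = a$value, duration = a$duration,
                until = a$until)))
}

#' @rdname control_to_list
#' @export
control_from_list <- function(x) {
  if (is.character(x) && length(x) == 1L)
    x <- jsonlite::fromJSON(x, simplifyDataFrame = FALSE)
  arcs <- lapply(x, function(a)
    control_arc(a$mode, value = a$value, duration = a$duration,
                until = a$until))
  piecewise_control(arcs)
}
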