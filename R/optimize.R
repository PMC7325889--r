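# Switch-time optimization over the proven control family (YX)^n u_p Y.
#
# The family is finite-dimensional: with the final no-dose arc ending at
# boundary contact, an n-pair schedule has 2n-1 effective interior switch
# times. Each sub-family is searched on a coarse grid and polished by
# golden-section refinement; everything is deterministic (no random
# restarts), so repeated runs are byte-identical.

# label of the realized arc sequence, e.g. "YXupY"
realized_label <- function(traj) {
  al <- traj$arc_log
  if (!nrow(al)) return("")
  keep <- al$t1 > al$t0 | seq_len(nrow(al)) == nrow(al)
  modes <- al$mode[keep]
  lab <- vapply(modes, function(m) switch(m, ZERO = "X", MAX = "Y",
                                          CONST = "C", PATH_FEEDBACK = "up",
                                          SINGULAR = "us"), character(1))
  # merge adjacent duplicates (e.g. a clocked X arc followed by the
  # boundary-seeking X arc)
  lab <- lab[c(TRUE, lab[-1] != lab[-length(lab)])]
  paste(lab, collapse = "")
}

# evaluate a structured candidate; returns t_c, or -Inf if the candidate's
# integration fails (deep-kill grid points can be numerically degenerate);
# horizon-capped evaluations enlarge the horizon until failure is observed
eval_structured <- function(p, n, t_free, horizon, rtol, atol) {
  tsw <- if (n > 0) c(t_free, t_free[length(t_free)]) else numeric()
  ctrl <- structured_control(n, tsw, p)
  h <- horizon
  repeat {
    tr <- tryCatch(
      integrate_trajectory(p, ctrl, t_max = h, dense = 2,
                           rtol = rtol, atol = atol),
      error = function(e) NULL)
    if (is.null(tr)) return(-Inf)
    if (!is.na(tr$t_c)) return(tr$t_c)
    if (h > 1e6) stop("no treatment failure before an extreme horizon")
    h <- h * 4
  }
}

# non-decreasing k-tuples from a grid (the admissible region of switch times)
ordered_tuples <- function(vals, k) {
  if (k == 1) return(matrix(vals, ncol = 1))
  # combinations with repetition: strictly increasing index tuples from
  # 1..(n+k-1), shifted back to non-decreasing tuples in 1..n
  idx <- utils::combn(length(vals) + k - 1, k) - (seq_len(k) - 1)
  t(apply(idx, 2, function(j) vals[j]))
}

#' Maximize the failure time over the structured control family
#'
#' Searches the family \eqn{(YX)^n u_p Y} (with degenerate arcs allowed, so
#' it contains `X`, `Y`, `X u_p Y`, `Y X u_p Y`, `YXY`, ...) for the
#' schedule with the largest treatment-failure time. For each `n` up to
#' `n_max` the effective switch times are optimized by a coarse grid
#' (`grid_points` per dimension, restricted to non-decreasing tuples)
#' followed by coordinate-wise golden-section refinement to `refine_tol`
#' time units. Grid evaluations run at slightly relaxed integrator
#' tolerances; the refined optimum is re-simulated at the tight defaults.
#'
#' @param p a [params()] object.
#' @param n_max largest number of leading (Y, X) pairs (default 2).
#' @param grid_points coarse-grid points per dimension (>= 20 by default).
#' @param refine_tol golden-section tolerance on each switch time.
#' @param grid_rtol,grid_atol integrator tolerances for grid evaluations.
#' @param verbose print per-structure progress.
#' @return An object of class `chemopt_opt`: list with `best_control`,
#'   `t_c`, `structure` (realized arc word), `switch_times`, `n`,
#'   `candidates` (per-structure best table), `trajectory` (the re-simulated
#'   optimum) and `n_evaluations`.
#' @export
#' @examples
#' \donttest{
#' res <- optimize_dosing(params_preset(d = 0.05, alpha = 0.1), n_max = 1)
#' res$structure   # "Y": constant maximal dose is optimal here
#' }
optimize_dosing <- function(p, n_max = 2, grid_points = 20,
                            refine_tol = 1e-4, grid_rtol = 1e-8,
                            grid_atol = 1e-8, verbose = FALSE) {
  if (n_max < 0) stop("n_max must be >= 0")
  n_eval <- 0L
  tc_X <- time_to_failure(p, control_X())
  tc_Y <- time_to_failure(p, control_Y())
  horizon <- max(50, 1.5 * max(tc_X, tc_Y))
  grid_max <- horizon
  cand <- data.frame(structure = c("X", "Y"), n = c(NA, NA),
                     t_c = c(tc_X, tc_Y), times = c("", ""),
                     stringsAsFactors = FALSE)
  best <- list(n = NA_integer_, t_free = numeric(),
               t_c = max(tc_X, tc_Y),
               ctrl = if (tc_Y >= tc_X) control_Y() else control_X())

  for (n in 0:n_max) {
    k <- max(0L, 2L * n - 1L)
    if (k == 0L) {
      tc <- eval_structured(p, n, numeric(), horizon, grid_rtol, grid_atol)
      n_eval <- n_eval + 1L
      t_best <- numeric()
    } else {
      vals <- seq(0, grid_max, length.out = grid_points)
      tuples <- ordered_tuples(vals, k)
      tcs <- apply(tuples, 1, function(tv)
        eval_structured(p, n, tv, horizon, grid_rtol, grid_atol))
      n_eval <- n_eval + nrow(tuples)
      ibest <- which.max(tcs)
      t_best <- tuples[ibest, ]
      tc <- tcs[ibest]
      # coordinate-wise golden-section refinement, two sweeps
      delta <- vals[2] - vals[1]
      for (pass in 1:2) {
        for (j in seq_len(k)) {
          lo <- max(if (j > 1) t_best[j - 1] else 0, t_best[j] - delta)
          hi <- min(if (j < k) t_best[j + 1] else grid_max,
                    t_best[j] + delta)
          if (hi <= lo) next
          f <- function(tj) {
            tv <- t_best; tv[j] <- tj
            n_eval <<- n_eval + 1L
            eval_structured(p, n, tv, horizon, grid_rtol, grid_atol)
          }
          op <- stats::optimize(f, c(lo, hi), maximum = TRUE,
                                tol = refine_tol)
          if (op$objective > tc) {
            t_best[j] <- op$maximum
            tc <- op$objective
          }
        }
        delta <- delta / 4
      }
    }
    lab <- paste0(if (n > 0) strrep("YX", n) else "", "upY")
    cand <- rbind(cand, data.frame(structure = lab, n = n, t_c = tc,
                                   times = paste(signif(t_best, 8),
                                                 collapse = " "),
                                   stringsAsFactors = FALSE))
    if (verbose)
      message(sprintf("n = %d: best t_c = %.6g at (%s)", n, tc,
                      paste(signif(t_best, 6), collapse = ", ")))
    if (tc > best$t_c) {
      tsw <- if (n > 0) c(t_best, t_best[length(t_best)]) else numeric()
      best <- list(n = n, t_free = t_best, t_c = tc,
                   ctrl = structured_control(n, tsw, p))
    }
  }

  # re-simulate the winner at tight tolerances; this is the reported t_c
  traj <- integrate_trajectory(p, best$ctrl, t_max = 4 * horizon + 100,
                               dense = 2)
  if (is.na(traj$t_c))
    traj <- integrate_trajectory(p, best$ctrl, t_max = 1e4, dense = 2)
  structure(list(best_control = best$ctrl, t_c = traj$t_c,
                 structure = realized_label(traj),
                 switch_times = best$t_free, n = best$n,
                 candidates = cand, trajectory = traj,
                 n_evaluations = n_eval),
            class = "chemopt_opt")
}

#' @export
print.chemopt_opt <- function(x, ...) {
  cat(sprintf("optimal structured dosing: %s, t_c = %.6g\n",
              x$structure, x$t_c))
  if (length(x$switch_times))
    cat("  switch times:", paste(signif(x$switch_times, 8), collapse = ", "),
        "\n")
  cat(sprintf("  (%d trajectory evaluations)\n", x$n_evaluations))
  cat("per-structure candidates:\n")
  print(x$candidates, row.names = FALSE)
  invisible(x)
}

#' Regularized objective of a schedule
#'
#' Evaluates the smoothed performance index
#' \deqn{J_\eta[u] = -\int_0^{t_c}\big[1 - (1-\eta)^2 u^2(t)\big]\,dt,
#'  \qquad \eta \in [0, 1],}
#' along the simulated trajectory. `eta = 1` recovers the time-maximization
#' objective (`-t_c`); smaller `eta` penalizes dose, which is how external
#' collocation solvers are probed for accuracy on the singular limit.
#'
#' @param p a [params()] object.
#' @param ctrl a `chemopt_control`.
#' @param eta regularization weight in `[0, 1]`.
#' @param dense quadrature points per arc.
#' @return The scalar objective value.
#' @export
evaluate_regularized <- function(p, ctrl, eta, dense = 2000) {
  if (eta < 0 || eta > 1) stop("eta must lie in [0, 1]")
  tr <- integrate_trajectory(p, ctrl, t_max = 1e4, dense = dense)
  if (is.na(tr$t_c)) stop("no treatment failure before the horizon")
  keep <- tr$times <= tr$t_c
  tt <- tr$times[keep]; uu <- tr$doses[keep]
  if (length(tt) < 2) return(0)
  integrand <- 1 - (1 - eta)^2 * uu^2
  -sum((integrand[-1] + integrand[-length(tt)]) / 2 * diff(tt))
}

#' Optimize over a (d, alpha) parameter grid
#'
#' Runs [optimize_dosing()] for every combination of cytotoxicity and
#' induction-rate values, holding the remaining parameters fixed. Cell
#' failures are recorded in the `error` column and do not stop the sweep.
#'
#' @param p_base a [params()] object providing the fixed parameters.
#' @param d_values,alpha_values grids for the cytotoxicity `d` and the
#'   induced transition rate `alpha`.
#' @param ... passed to [optimize_dosing()].
#' @return A data.frame with one row per cell: `d`, `alpha`, `structure`,
#'   `t_c`, `switch_times`, `error`.
#' @export
sweep_grid <- function(p_base, d_values, alpha_values, ...) {
  rows <- list()
  for (d in d_values) for (a in alpha_values) {
    pc <- params(pr = p_base$pr, eps = p_base$eps, alpha = a, d = d,
                 M = p_base$M, Vc = p_base$Vc, x10 = p_base$x10,
                 x20 = p_base$x20)
    res <- tryCatch(optimize_dosing(pc, ...), error = identity)
    rows[[length(rows) + 1L]] <- if (inherits(res, "error")) {
      data.frame(d = d, alpha = a, structure = NA_character_,
                 t_c = NA_real_, switch_times = NA_character_,
                 error = conditionMessage(res), stringsAsFactors = FALSE)
    } else {
      data.frame(d = d, alpha = a, structure = res$structure,
                 t_c = res$t_c,
                 switch_times = paste(signif(res$switch_times, 8),
                                      collapse = " "),
                 error = NA_character_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
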