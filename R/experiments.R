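# Reproduction of the quantitative experiments: the (d, alpha) optimal-time
# grid and the alpha-sweep response curves, with versioned CSV output for
# the command-line interface.

CSV_SCHEMA <- "# chemopt result schema v1"

write_versioned_csv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(CSV_SCHEMA, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(df)
}

#' Optimal failure times over the reference (d, alpha) grid
#'
#' Optimizes the structured schedule over the grid
#' `d in {0.001, 0.01, 0.1, 0.5, 1}` times `alpha in {0.001, 0.01, 0.1}`
#' with the remaining parameters at the built-in preset, and additionally
#' reports the no-treatment baseline per cell. For drugs with low
#' cytotoxicity the optimal time increases with the induction rate (the
#' induced transitions push mass into the slower-growing compartment);
#' for highly cytotoxic drugs the trend reverses.
#'
#' @param d_values,alpha_values grid values.
#' @param p_base fixed parameters (defaults to [params_preset()]).
#' @param out_csv optional path; writes the long table with a schema header.
#' @param ... passed to [optimize_dosing()].
#' @return List with `long` (per-cell data.frame, including `baseline_tc`)
#'   and `wide` (d rows by alpha columns matrix of optimal times).
#' @export
run_table2 <- function(d_values = c(0.001, 0.01, 0.1, 0.5, 1),
                       alpha_values = c(0.001, 0.01, 0.1),
                       p_base = params_preset(), out_csv = NULL, ...) {
  long <- sweep_grid(p_base, d_values, alpha_values, ...)
  long$baseline_tc <- NA_real_
  for (r in seq_len(nrow(long))) {
    pc <- params(pr = p_base$pr, eps = p_base$eps, alpha = long$alpha[r],
                 d = long$d[r], M = p_base$M, Vc = p_base$Vc,
                 x10 = p_base$x10, x20 = p_base$x20)
    long$baseline_tc[r] <- time_to_failure(pc, control_X())
  }
  wide <- matrix(long$t_c, nrow = length(d_values), byrow = TRUE,
                 dimnames = list(d = as.character(d_values),
                                 alpha = as.character(alpha_values)))
  if (!is.null(out_csv)) write_versioned_csv(long, out_csv)
  list(long = long, wide = wide)
}

#' Optimal failure time as a function of the induction rate
#'
#' Sweeps a fine `alpha` grid at one or more fixed cytotoxicities and flags
#' the direction of the response: for small `d` the failure time increases
#' with `alpha`, for large `d` it decreases.
#'
#' @param d_values fixed cytotoxicities (one curve each).
#' @param alpha_grid induction-rate grid.
#' @param p_base fixed parameters.
#' @param out_csv optional path for the long table.
#' @param ... passed to [optimize_dosing()].
#' @return List with `curves` (data.frame `d`, `alpha`, `t_c`, `structure`)
#'   and `monotonicity` (per-`d` label: "increasing", "decreasing",
#'   "non-monotone").
#' @export
run_alpha_sweep <- function(d_values = c(0.001, 0.5),
                            alpha_grid = c(0.001, 0.005, 0.01, 0.05, 0.1),
                            p_base = params_preset(), out_csv = NULL, ...) {
  curves <- sweep_grid(p_base, d_values, alpha_grid, ...)
  mono <- vapply(d_values, function(d) {
    tc <- curves$t_c[curves$d == d]
    dt <- diff(tc)
    if (all(dt > 0)) "increasing"
    else if (all(dt < 0)) "decreasing"
    else "non-monotone"
  }, character(1))
  names(mono) <- as.character(d_values)
  if (!is.null(out_csv)) write_versioned_csv(curves, out_csv)
  list(curves = curves, monotonicity = mono)
}
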