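# Structural identifiability of the model from the volume output.
#
# With an entirely sensitive initial population, a handful of iterated Lie
# derivatives of the volume output h = x1 + x2 at t = 0 determine all five
# unknowns (x10, d, alpha, eps, pr) in closed form.

#' Iterated Lie derivatives of the volume output
#'
#' For the initial condition `x0 = (x10, 0)` (treatment starts on an
#' entirely sensitive population) the observable quantities are
#' \deqn{h_0 = x_{10},\quad L_g h = -d\,x_{10},\quad
#'       L_g^2 h = d(\alpha+d)\,x_{10},}
#' \deqn{L_f L_g h = -d\,x_{10}(1 - x_{10} - \epsilon),}
#' \deqn{L_g L_f h = x_{10}\big[-(\alpha+d)(1-2x_{10})
#'       + \alpha p_r (1-x_{10}) - \alpha x_{10}\big].}
#' All five are reachable from volume measurements under suitably chosen
#' dosing schedules, and together they determine the parameter vector.
#'
#' @param p a [params()] object with `x20 = 0`.
#' @return An object of class `chemopt_observables`: list with `h0`,
#'   `Lg_h`, `Lg2_h`, `LfLg_h`, `LgLf_h`.
#' @export
#' @examples
#' lie_observables(params_preset())
lie_observables <- function(p) {
  if (p$x20 != 0)
    stop("closed-form observables require an entirely sensitive initial ",
         "population (x20 = 0)")
  x10 <- p$x10
  structure(list(
    h0 = x10,
    Lg_h = -p$d * x10,
    Lg2_h = p$d * (p$alpha + p$d) * x10,
    LfLg_h = -p$d * x10 * (1 - x10 - p$eps),
    LgLf_h = x10 * (-(p$alpha + p$d) * (1 - 2 * x10) +
                      p$alpha * p$pr * (1 - x10) - p$alpha * x10)
  ), class = "chemopt_observables")
}

#' @export
print.chemopt_observables <- function(x, ...) {
  cat("volume-output Lie derivatives at t = 0:\n")
  for (k in names(unclass(x)))
    cat(sprintf("  %-7s = %.10g\n", k, x[[k]]))
  invisible(x)
}

#' Recover model parameters from the observables
#'
#' Inverts the closed forms of [lie_observables()] recursively:
#' \deqn{x_{10} = h_0,\quad d = -L_g h/x_{10},\quad
#'       \alpha = L_g^2 h/(d\,x_{10}) - d,}
#' \deqn{\epsilon = L_f L_g h/(d\,x_{10}) + 1 - x_{10},}
#' \deqn{p_r = \frac{L_g L_f h/x_{10} + (\alpha+d)(1-2x_{10})
#'       + \alpha x_{10}}{\alpha(1-x_{10})}.}
#' Recovery is exact on noiseless observables; when `alpha = 0` the
#' resistant compartment is never populated by dosing, `pr` does not enter
#' this observable set and is flagged non-recoverable (`NA`).
#'
#' @param obs a `chemopt_observables` (or compatible named list).
#' @return An object of class `chemopt_recovered`: list with `x10`, `d`,
#'   `alpha`, `eps`, `pr`.
#' @export
#' @examples
#' p <- params_preset()
#' recover_params(lie_observables(p))   # returns the generating values
recover_params <- function(obs) {
  h0 <- obs$h0
  if (!is.finite(h0) || h0 <= 0 || h0 >= 1)
    stop("h0 must lie in (0, 1)")
  if (obs$Lg_h >= 0)
    stop("inconsistent observables: Lg_h must be negative (d, x10 > 0)")
  x10 <- h0
  d <- -obs$Lg_h / x10
  if (d <= 0) stop("inconsistent observables: recovered d <= 0")
  alpha <- obs$Lg2_h / (d * x10) - d
  eps <- obs$LfLg_h / (d * x10) + 1 - x10
  pr <- if (abs(alpha) < 1e-14) {
    NA_real_   # pr does not enter the observables when the drug induces nothing
  } else {
    (obs$LgLf_h / x10 + (alpha + d) * (1 - 2 * x10) + alpha * x10) /
      (alpha * (1 - x10))
  }
  structure(list(x10 = x10, d = d, alpha = alpha, eps = eps, pr = pr),
            class = "chemopt_recovered")
}

#' @export
print.chemopt_recovered <- function(x, ...) {
  cat("recovered parameters:\n")
  cat(sprintf("  x10 = %.10g, d = %.10g, alpha = %.10g, eps = %.10g, pr = %s\n",
              x$x10, x$d, x$alpha, x$eps,
              if (is.na(x$pr)) "non-recoverable (alpha = 0)"
              else sprintf("%.10g", x$pr)))
  invisible(x)
}
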