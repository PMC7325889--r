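#' Model and problem parameters
#'
#' Bundles the constants of the sensitive/resistant tumor model and of the
#' treatment-failure problem into a validated parameter object. The model
#' tracks two tumor fractions (of a joint carrying capacity scaled to 1):
#' a drug-sensitive compartment `x1` and a fully resistant compartment `x2`.
#' The drug kills sensitive cells at rate `d*u*x1` (log-kill) and induces
#' sensitive-to-resistant transitions at rate `alpha*u*x1`, on top of the
#' spontaneous transition rate `eps*x1`.
#'
#' @param pr relative growth rate of the resistant compartment
#'   (dimensionless, `0 <= pr < 1`; resistant cells divide more slowly).
#' @param eps spontaneous (drug-independent) transition rate (per unit time).
#' @param alpha drug-induced transition rate (per unit dose-time).
#' @param d drug cytotoxicity (per unit dose-time); must be positive, since
#'   both the boundary feedback dose and the identifiability recovery divide
#'   by `d`.
#' @param M maximal tolerated dose (dimensionless dose units).
#' @param Vc critical tumor volume as a fraction of carrying capacity;
#'   treatment fails once `x1 + x2` exceeds `Vc`. Must satisfy
#'   `0 < Vc < 1 - eps`.
#' @param x10,x20 initial sensitive and resistant fractions; the initial state
#'   must lie in the treatment region (`x10 + x20 <= Vc`, both non-negative)
#'   with `x10 > 0`.
#'
#' @return An object of class `chemopt_params` (a named list).
#' @seealso [params_preset()] for the built-in reference parameter set.
#' @export
#' @examples
#' p <- params(pr = 0.2, eps = 1e-6, alpha = 0.01, d = 1, M = 5, Vc = 0.9,
#'             x10 = 0.01, x20 = 0)
#' p
params <- function(pr, eps, alpha, d, M, Vc, x10, x20 = 0) {
  vals <- c(pr = pr, eps = eps, alpha = alpha, d = d, M = M, Vc = Vc,
            x10 = x10, x20 = x20)
  if (any(!is.finite(vals)))
    stop("all parameters must be finite numbers")
  if (pr < 0 || pr >= 1)
    stop("pr must satisfy 0 <= pr < 1")
  if (eps < 0 || alpha < 0)
    stop("eps and alpha must be non-negative")
  if (d <= 0)
    stop("d must be strictly positive (the boundary feedback and the ",
         "identifiability recovery divide by d)")
  if (M <= 0)
    stop("M must be strictly positive")
  if (Vc <= 0 || Vc >= 1 - eps)
    stop("Vc must lie in (0, 1 - eps)")
  if (x10 <= 0)
    stop("x10 must be strictly positive")
  if (x20 < 0 || x10 + x20 > Vc + 1e-9)
    stop("initial state must lie in the treatment region: x20 >= 0 and ",
         "x10 + x20 <= Vc")
  structure(as.list(vals), class = "chemopt_params")
}

#' Built-in reference parameter preset
#'
#' The parameter set used throughout the numerical experiments:
#' `x10 = 0.01`, `x20 = 0`, `alpha = 0.01`, `d = 1`, `eps = 1e-6`,
#' `pr = 0.2`, `M = 5`, `Vc = 0.9`. Individual values can be overridden,
#' which is how the dose-response grids are built.
#'
#' @param ... named overrides of individual fields (e.g. `d = 0.05`).
#' @return A `chemopt_params` object.
#' @export
#' @examples
#' params_preset()              # the reference set
#' params_preset(d = 0.05, alpha = 0.1)
params_preset <- function(...) {
  base <- list(pr = 0.2, eps = 1e-6, alpha = 0.01, d = 1, M = 5, Vc = 0.9,
               x10 = 0.01, x20 = 0)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(base))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    base[names(over)] <- over
  }
  do.call(params, base)
}

#' @export
print.chemopt_params <- function(x, ...) {
  cat("Tumor resistance model parameters\n")
  cat(sprintf("  pr = %g, eps = %g, alpha = %g, d = %g\n",
              x$pr, x$eps, x$alpha, x$d))
  cat(sprintf("  M = %g, Vc = %g, x0 = (%g, %g)\n", x$M, x$Vc, x$x10, x$x20))
  invisible(x)
}

#' Serialize parameters to / from a flat key-value list
#'
#' `params_to_list()` returns a plain named list (suitable for
#' `jsonlite::toJSON` or `yaml::as.yaml`); `params_from_list()` rebuilds and
#' revalidates a `chemopt_params` object from such a list, e.g. one read from
#' a JSON/YAML config file.
#'
#' @param p a `chemopt_params` object.
#' @param x a named list (or the path of a JSON file when `x` is a string)
#'   with keys `pr, eps, alpha, d, M, Vc, x10, x20`.
#' @return `params_to_list()`: a named list; `params_from_list()`: a
#'   `chemopt_params` object.
#' @export
params_to_list <- function(p) {
  stopifnot(inherits(p, "chemopt_params"))
  unclass(p)
}

#' @rdname params_to_list
#' @export
params_from_list <- function(x) {
  if (is.character(x) && length(x) == 1L)
    x <- jsonlite::fromJSON(x)
  need <- c("pr", "eps", "alpha", "d", "M", "Vc", "x10")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing parameter key(s): ", paste(miss, collapse = ", "))
  if (is.null(x$x20)) x$x20 <- 0
  params(pr = x$pr, eps = x$eps, alpha = x$alpha, d = x$d, M = x$M,
         Vc = x$Vc, x10 = x$x10, x20 = x$x20)
}

# initial state of a parameter set as a bare (x1, x2) vector
initial_state <- function(p) c(x1 = p$x10, x2 = p$x20)
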