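#' Quadratic fit of a potential energy scan
#'
#' Ordinary least-squares fit of `y = a*i^2 + b*i + c` to one state's
#' scan. `a` is the curvature of the fitted parabola (eV per i^2), `b`
#' governs the horizontal vertex shift (eV per i) and `c` the vertical
#' offset (eV). The fit RMSD, `sqrt(mean(residual^2))` over all n
#' points, is the working measure of anharmonicity: energies that a
#' parabola cannot follow leave residuals.
#'
#' @param factors Numeric grid of scaling factors i (at least 3 distinct
#'   values).
#' @param energies Numeric energies (eV), same length as `factors`.
#' @return An object of class `quad_fit`: a list with `a`, `b`, `c`,
#'   `r2`, `rmsd`, `n`, plus `factors`, `energies`, `fitted`. When all
#'   energies are equal, `r2` is reported as 1 if the residuals are also
#'   zero (a constant is fit exactly) and is an error otherwise.
#' @examples
#' g <- displacement_grid()
#' f <- fit_quadratic(g, 2 * g^2 + 3 * g + 1)
#' f$a; f$rmsd
#' @export
fit_quadratic <- function(factors, energies) {
  x <- as.numeric(factors); y <- as.numeric(energies)
  if (length(x) != length(y)) stop("factors and energies must have equal length", call. = FALSE)
  if (length(unique(x)) < 3L) {
    stop("quadratic fit needs at least 3 distinct grid points", call. = FALSE)
  }
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- stats::coef(fit)
  res <- stats::residuals(fit)
  n <- length(y)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) {
    if (ss_res < 1e-20) 1 else stop("undefined R^2: zero total variance with nonzero residuals",
                                    call. = FALSE)
  } else 1 - ss_res / ss_tot
  structure(
    list(a = unname(cf[["I(x^2)"]]), b = unname(cf[["x"]]), c = unname(cf[["(Intercept)"]]),
         r2 = r2, rmsd = sqrt(ss_res / n), n = n,
         factors = x, energies = y, fitted = unname(stats::fitted(fit))),
    class = "quad_fit"
  )
}

#' @export
print.quad_fit <- function(x, ...) {
  cat(sprintf("<quad_fit> y = %.6g i^2 + %.6g i + %.6g  (n = %d, RMSD = %.3g eV, R^2 = %.6g)\n",
              x$a, x$b, x$c, x$n, x$rmsd, x$r2))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a quadratic scan fit
#' @param x A `quad_fit`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`term`, `estimate`).
#' @method tidy quad_fit
#' @export
tidy.quad_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c"), estimate = c(x$a, x$b, x$c))
}

#' One-row summary of a quadratic scan fit
#' @param x A `quad_fit`.
#' @param ... Unused.
#' @return A tibble with `a`, `b`, `c`, `r2`, `rmsd`, `n`.
#' @method glance quad_fit
#' @export
glance.quad_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, c = x$c, r2 = x$r2, rmsd = x$rmsd, n = x$n)
}

#' Evaluate a quadratic scan fit
#' @param object A `quad_fit`.
#' @param newdata Optional numeric vector of scaling factors.
#' @param ... Unused.
#' @return Fitted energies at `newdata` (or at the fit grid).
#' @export
predict.quad_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$factors else as.numeric(newdata)
  object$a * x^2 + object$b * x + object$c
}

# Minimum of the fitted parabola over a closed interval.
# Returns list(value, at, interior) where interior marks a vertex minimum.
parabola_min_on <- function(fit, lo, hi) {
  if (fit$a > 0) {
    vertex <- -fit$b / (2 * fit$a)
    if (vertex >= lo && vertex <= hi) {
      return(list(value = fit$c - fit$b^2 / (4 * fit$a), at = vertex, interior = TRUE))
    }
  }
  ends <- c(lo, hi)
  vals <- predict(fit, ends)
  k <- which.min(vals)
  list(value = vals[k], at = ends[k], interior = FALSE)
}
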