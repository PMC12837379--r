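#' Convert percent viability to fraction affected
#'
#' The fraction affected (fa) is the fraction of cells inhibited relative to
#' control: `fa = 1 - viability/100`, clamped to `[0, 1]` so that apparent
#' stimulation (viability above 100%) maps to zero inhibition.
#'
#' @param viability Percent viability, non-negative; vectorised.
#' @return Fractions in `[0, 1]`.
#' @examples
#' inhibition_fraction(c(100, 42, 110))  # 0, 0.58, 0
#' @export
inhibition_fraction <- function(viability) {
  if (any(is.na(viability)) || any(viability < 0)) {
    stop("viability must be non-negative", call. = FALSE)
  }
  pmin(1, pmax(0, 1 - viability / 100))
}

# defined at dose 0 with value top (the untreated asymptote)
fourpl_curve <- function(dose, top, bottom, hill, ec50) {
  f <- ifelse(dose == 0, 0, (dose / ec50)^hill)
  bottom + (top - bottom) / (1 + f)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of the 4PL model
#' `V(D) = bottom + (top - bottom) / (1 + (D / ec50)^hill)`
#' to the per-dose mean viabilities of a series. The dose-0 anchor is
#' included as-is (the model equals `top` at `D = 0`). Fitting uses
#' Levenberg-Marquardt with box bounds and a multi-start over Hill slopes
#' `{0.5, 1, 2, 4}`; the start with the lowest residual sum of squares wins.
#'
#' Bounds: `bottom` in `[0, min mean]`, `top` in
#' `[0.9 * max mean, 1.1 * max mean + 5]`, `hill` in `(0.1, 10]`,
#' `ec50` in `[min positive dose / 10, 10 * max dose]`.
#'
#' @param series A `dose_response_series`, or a data frame with columns
#'   `total_dose` and `mean_viability`.
#' @return An object of class `fourpl_fit` with fields `top`, `bottom`,
#'   `hill`, `ec50`, `rss`, `converged`, plus the data used.
#' @seealso [absolute_ic50()], [predict.fourpl_fit()]
#' @export
fit_four_pl <- function(series) {
  dat <- if (inherits(series, "dose_response_series")) series$data else series
  dose <- dat$total_dose
  v <- dat$mean_viability
  if (length(unique(dose)) < 4) {
    stop("insufficient data: 4PL fit needs at least 4 distinct doses",
         call. = FALSE)
  }
  vmax <- max(v); vmin <- min(v)
  pos <- dose[dose > 0]
  lower <- c(top = 0.9 * vmax, bottom = 0, hill = 0.1,
             ec50 = min(pos) / 10)
  upper <- c(top = 1.1 * vmax + 5, bottom = max(vmin, 0), hill = 10,
             ec50 = 10 * max(dose))
  # ec50 start: dose nearest the half-range response, by linear interpolation
  half <- (vmax + vmin) / 2
  ec50_0 <- tryCatch(stats::approx(v, dose, xout = half, ties = mean)$y,
                     error = function(e) NA_real_)
  if (is.na(ec50_0) || ec50_0 <= 0) ec50_0 <- stats::median(pos)
  ec50_0 <- min(max(ec50_0, lower["ec50"]), upper["ec50"])

  resid_fn <- function(p) {
    v - fourpl_curve(dose, p["top"], p["bottom"], p["hill"], p["ec50"])
  }
  sse_fn <- function(p) sum(resid_fn(p)^2)
  # starts sit strictly inside the box: both optimizers handle interior
  # starts much better than starts pinned on a bound
  nudge <- function(x, lo, hi) {
    if (hi <= lo) return(lo)
    min(max(x, lo + 1e-3 * (hi - lo)), hi - 1e-3 * (hi - lo))
  }
  starts <- expand.grid(hill = c(0.5, 1, 2, 4),
                        bottom = unique(c(0, vmin)))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    start <- c(top = nudge(vmax, lower["top"], upper["top"]),
               bottom = nudge(starts$bottom[k], lower["bottom"],
                              upper["bottom"]),
               hill = starts$hill[k],
               ec50 = nudge(ec50_0, lower["ec50"], upper["ec50"]))
    names(start) <- c("top", "bottom", "hill", "ec50")
    fit <- tryCatch(
      stats::optim(start, sse_fn, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = 10, maxit = 2000)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("4PL fit failed from every start", call. = FALSE)
  }
  # Levenberg-Marquardt polish from the located basin: quadratic
  # convergence to machine precision when the optimum is interior
  p <- best$par
  converged <- best$convergence == 0
  polish <- tryCatch(
    minpack.lm::nls.lm(
      par = vapply(names(p), function(nm)
        nudge(p[[nm]], lower[[nm]], upper[[nm]]), 0),
      lower = lower, upper = upper, fn = resid_fn,
      control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                           maxiter = 1000)),
    error = function(e) NULL)
  if (!is.null(polish) && sum(polish$fvec^2) <= best$value) {
    p <- polish$par
    converged <- polish$info %in% 1:4
  }
  rss <- sse_fn(p)
  structure(
    list(top = unname(p["top"]), bottom = unname(p["bottom"]),
         hill = unname(p["hill"]), ec50 = unname(p["ec50"]),
         rss = rss,
         converged = converged,
         label = if (inherits(series, "dose_response_series")) series$label else NA_character_,
         data = data.frame(total_dose = dose, mean_viability = v)),
    class = "fourpl_fit"
  )
}

#' @export
print.fourpl_fit <- function(x, digits = 4, ...) {
  cat("Four-parameter logistic fit",
      if (!is.na(x$label)) paste0(" [", x$label, "]"), "\n", sep = "")
  print(signif(c(top = x$top, bottom = x$bottom, hill = x$hill,
                 ec50 = x$ec50), digits))
  cat("RSS:", signif(x$rss, digits),
      if (!x$converged) " (NOT converged)", "\n")
  invisible(x)
}

#' @export
coef.fourpl_fit <- function(object, ...) {
  c(top = object$top, bottom = object$bottom, hill = object$hill,
    ec50 = object$ec50)
}

#' Predicted viability from a 4PL fit
#'
#' @param object A `fourpl_fit`.
#' @param newdata Optional numeric vector of doses (µM); defaults to the
#'   doses used in the fit.
#' @param ... Unused.
#' @return Percent viabilities.
#' @export
predict.fourpl_fit <- function(object, newdata = NULL, ...) {
  dose <- if (is.null(newdata)) object$data$total_dose else newdata
  fourpl_curve(dose, object$top, object$bottom, object$hill, object$ec50)
}

#' @export
residuals.fourpl_fit <- function(object, ...) {
  object$data$mean_viability - predict(object)
}

#' @export
plot.fourpl_fit <- function(x, n_grid = 200, ...) {
  d <- x$data$total_dose
  pos <- d[d > 0]
  grid <- c(0, exp(seq(log(min(pos) / 2), log(max(pos) * 1.5),
                       length.out = n_grid)))
  graphics::plot(d, x$data$mean_viability, xlab = "dose (µM)",
                 ylab = "viability (%)",
                 main = if (!is.na(x$label)) x$label else "4PL fit", ...)
  graphics::lines(grid, predict(x, grid), col = "steelblue")
  graphics::abline(h = 50, lty = 3, col = "grey50")
  invisible(x)
}

#' Absolute IC50 from a fitted 4PL curve
#'
#' The dose at which the fitted viability curve crosses 50% of control:
#' `D = ec50 * ((top - 50) / (50 - bottom))^(1/hill)`. Undefined (returned
#' as `NA` with a warning) when the curve never crosses 50, i.e. when
#' `bottom >= 50` or `top <= 50`. For `top = 100`, `bottom = 0` the absolute
#' IC50 coincides with `ec50` for any Hill slope.
#'
#' @param fit A converged `fourpl_fit`.
#' @return The absolute IC50 in µM, or `NA_real_`.
#' @export
absolute_ic50 <- function(fit) {
  stopifnot(inherits(fit, "fourpl_fit"))
  if (fit$bottom >= 50 || fit$top <= 50) {
    warning("fitted curve does not cross 50% viability; absolute IC50 ",
            "undefined", call. = FALSE)
    return(NA_real_)
  }
  fit$ec50 * ((fit$top - 50) / (50 - fit$bottom))^(1 / fit$hill)
}
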