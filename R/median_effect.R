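#' Linearize dose-effect data under the median-effect model
#'
#' The mass-action median-effect equation `fa/fu = (D/Dm)^m` (with
#' `fu = 1 - fa`) is log-linear:
#' `log10(fa/(1 - fa)) = m * log10(D) - m * log10(Dm)`.
#' This helper maps observations to that plane, excluding points outside
#' the inclusion window (`fa_min <= fa <= fa_max`, default `[0.01, 0.99]`)
#' and any dose-0 point, where the logarithm is undefined. Log-odds explode
#' at the extremes, so trimming them is standard median-effect practice.
#'
#' @param doses Positive doses (µM).
#' @param fa Fractions affected in `[0, 1]`, same length.
#' @param fa_min,fa_max Inclusion window on fa.
#' @return A data frame with columns `log_dose`, `log_odds`, `dose`, `fa`
#'   for the retained points; excluded points are reported in the
#'   `"excluded"` attribute with a reason each.
#' @export
linearize_median_effect <- function(doses, fa, fa_min = 0.01, fa_max = 0.99) {
  stopifnot(length(doses) == length(fa))
  reason <- rep(NA_character_, length(doses))
  reason[doses <= 0] <- "dose <= 0"
  reason[is.na(reason) & fa < fa_min] <- "fa below window"
  reason[is.na(reason) & fa > fa_max] <- "fa above window"
  keep <- is.na(reason)
  if (sum(keep) < 2) {
    stop("insufficient data: fewer than 2 points inside the median-effect ",
         "inclusion window", call. = FALSE)
  }
  out <- data.frame(log_dose = log10(doses[keep]),
                    log_odds = log10(fa[keep] / (1 - fa[keep])),
                    dose = doses[keep], fa = fa[keep])
  attr(out, "excluded") <- data.frame(dose = doses[!keep], fa = fa[!keep],
                                      reason = reason[!keep])
  out
}

#' Fit the median-effect (mass-action) model
#'
#' Ordinary least squares on the linearized median-effect plane gives the
#' slope `m` (sigmoidicity) and the median-effect dose
#' `Dm = 10^(-intercept/m)`, the dose producing 50% effect. The linear
#' correlation coefficient `r` of the regression is reported as the usual
#' conformity check. For inhibition data `m` should be positive; a fit with
#' `m <= 0` is returned but marked unreliable.
#'
#' @param x Either a numeric vector of positive doses (µM), or a
#'   `dose_response_series` (fa is then computed from mean viability per
#'   dose and the dose-0 anchor drops out of the inclusion window).
#' @param fa Fractions affected, when `x` is a dose vector.
#' @param fa_min,fa_max Inclusion window passed to
#'   [linearize_median_effect()].
#' @param ... Unused.
#' @return An object of class `median_effect_fit` with fields `dm`, `m`,
#'   `r`, `n_points`, `reliable`, and the retained points.
#' @examples
#' fit <- fit_median_effect(c(2, 5, 10, 20, 50),
#'                          c(2, 5, 10, 20, 50)^2 / (100 + c(2, 5, 10, 20, 50)^2))
#' coef(fit)  # dm = 10, m = 2
#' @export
fit_median_effect <- function(x, ...) UseMethod("fit_median_effect")

#' @rdname fit_median_effect
#' @export
fit_median_effect.default <- function(x, fa, fa_min = 0.01, fa_max = 0.99,
                                      ...) {
  pts <- linearize_median_effect(x, fa, fa_min = fa_min, fa_max = fa_max)
  ols <- stats::lm(log_odds ~ log_dose, data = pts)
  m <- unname(stats::coef(ols)[2])
  b <- unname(stats::coef(ols)[1])
  if (m == 0) stop("degenerate median-effect fit: zero slope", call. = FALSE)
  fit <- structure(
    list(dm = 10^(-b / m), m = m,
         r = stats::cor(pts$log_dose, pts$log_odds),
         n_points = nrow(pts), reliable = m > 0,
         points = pts, excluded = attr(pts, "excluded"),
         label = NA_character_),
    class = "median_effect_fit"
  )
  if (!fit$reliable) {
    warning("median-effect slope m <= 0: fit flagged unreliable",
            call. = FALSE)
  }
  fit
}

#' @rdname fit_median_effect
#' @export
fit_median_effect.dose_response_series <- function(x, fa_min = 0.01,
                                                   fa_max = 0.99, ...) {
  fa <- inhibition_fraction(x$data$mean_viability)
  fit <- fit_median_effect(x$data$total_dose, fa,
                           fa_min = fa_min, fa_max = fa_max)
  fit$label <- x$label
  fit
}

#' @export
print.median_effect_fit <- function(x, digits = 4, ...) {
  cat("Median-effect fit",
      if (!is.na(x$label)) paste0(" [", x$label, "]"), "\n", sep = "")
  cat(sprintf("  Dm = %.*g uM, m = %.*g, r = %.*g (n = %d)\n",
              digits, x$dm, digits, x$m, digits, x$r, x$n_points))
  if (!x$reliable) cat("  WARNING: m <= 0, unreliable for inhibition data\n")
  if (nrow(x$excluded) > 0) {
    cat("  excluded points:", nrow(x$excluded), "\n")
  }
  invisible(x)
}

#' @export
coef.median_effect_fit <- function(object, ...) {
  c(dm = object$dm, m = object$m)
}

#' Predicted fraction affected from a median-effect fit
#'
#' @param object A `median_effect_fit`.
#' @param newdata Optional positive doses (µM); defaults to the fitted ones.
#' @param ... Unused.
#' @return Fractions affected in `(0, 1)`.
#' @export
predict.median_effect_fit <- function(object, newdata = NULL, ...) {
  dose <- if (is.null(newdata)) object$points$dose else newdata
  effect_at_dose(object, dose)
}

#' @export
plot.median_effect_fit <- function(x, ...) {
  graphics::plot(x$points$log_dose, x$points$log_odds,
                 xlab = "log10 dose", ylab = "log10(fa/fu)",
                 main = if (!is.na(x$label)) x$label else "median-effect plot",
                 ...)
  graphics::abline(a = -x$m * log10(x$dm), b = x$m, col = "steelblue")
  invisible(x)
}

#' Dose producing a given effect level
#'
#' Inverts the median-effect equation: `Dx = Dm * (fa/(1 - fa))^(1/m)`, the
#' single-agent dose producing fraction affected `fa`. Strictly increasing
#' in `fa` for `m > 0`.
#'
#' @param fit A `median_effect_fit`.
#' @param fa Effect levels strictly inside `(0, 1)`; vectorised.
#' @return Doses in µM.
#' @export
dose_for_effect <- function(fit, fa) {
  stopifnot(inherits(fit, "median_effect_fit"))
  if (any(fa <= 0) || any(fa >= 1)) {
    stop("fa must lie strictly inside (0, 1)", call. = FALSE)
  }
  fit$dm * (fa / (1 - fa))^(1 / fit$m)
}

#' Effect at a given dose
#'
#' The median-effect equation `fa = (D/Dm)^m / (1 + (D/Dm)^m)`; monotone
#' increasing in dose for `m > 0`, with `fa = 0.5` exactly at `D = Dm`.
#'
#' @param fit A `median_effect_fit`.
#' @param dose Positive doses (µM); vectorised.
#' @return Fractions affected in `(0, 1)`.
#' @export
effect_at_dose <- function(fit, dose) {
  stopifnot(inherits(fit, "median_effect_fit"))
  if (any(dose <= 0)) stop("dose must be positive", call. = FALSE)
  q <- (dose / fit$dm)^fit$m
  q / (1 + q)
}

# internal constructor for synthetic/known-parameter fits
median_effect_pars <- function(dm, m, label = NA_character_) {
  stopifnot(dm > 0)
  structure(list(dm = dm, m = m, r = 1, n_points = 0L, reliable = m > 0,
                 points = data.frame(), excluded = data.frame(),
                 label = label),
            class = "median_effect_fit")
}

#' Construct a median-effect model from known parameters
#'
#' Builds a `median_effect_fit` directly from `(Dm, m)`, e.g. for
#' simulation ground truth or literature parameters, without fitting.
#'
#' @param dm Median-effect dose (µM), positive.
#' @param m Slope (sigmoidicity).
#' @param label Optional label.
#' @return A `median_effect_fit`.
#' @export
median_effect_model <- function(dm, m, label = NA_character_) {
  median_effect_pars(dm, m, label)
}

#' Combination Index at an observed combination point
#'
#' The Chou-Talalay Combination Index for a combination delivering doses
#' `(d1, d2)` and producing fraction affected `fa_obs`:
#' `CI = d1/Dx1 + d2/Dx2 + alpha * (d1*d2)/(Dx1*Dx2)`,
#' where `Dx1`, `Dx2` are the single-agent doses giving the same effect,
#' from each agent's median-effect fit. `alpha = 0` treats the drugs as
#' mutually exclusive (classical Loewe-consistent form), `alpha = 1` as
#' mutually non-exclusive. CI < 1 indicates synergy, CI = 1 additivity,
#' CI > 1 antagonism.
#'
#' @param fit_a,fit_b `median_effect_fit` objects for the two agents.
#' @param d1,d2 Component doses in the combination (µM), non-negative.
#' @param fa_obs Observed fraction affected, strictly inside `(0, 1)`.
#' @param alpha 0 or 1.
#' @param tolerance Half-width of the additive band for classification.
#' @return An object of class `ci_result`: a list with `fa`, `d1`, `d2`,
#'   `dx1`, `dx2`, `alpha`, `ci`, `classification`.
#' @export
combination_index <- function(fit_a, fit_b, d1, d2, fa_obs, alpha = 0,
                              tolerance = 0.05) {
  if (length(fa_obs) != 1 || is.na(fa_obs) || fa_obs <= 0 || fa_obs >= 1) {
    stop("fa_obs must be a single value strictly inside (0, 1)",
         call. = FALSE)
  }
  stopifnot(alpha %in% c(0, 1), d1 >= 0, d2 >= 0)
  dx1 <- dose_for_effect(fit_a, fa_obs)
  dx2 <- dose_for_effect(fit_b, fa_obs)
  ci <- d1 / dx1 + d2 / dx2 + alpha * (d1 * d2) / (dx1 * dx2)
  structure(
    list(fa = fa_obs, d1 = d1, d2 = d2, dx1 = dx1, dx2 = dx2,
         alpha = alpha, ci = ci,
         classification = classify_ci(ci, tolerance = tolerance)),
    class = "ci_result"
  )
}

#' @export
print.ci_result <- function(x, digits = 4, ...) {
  cat(sprintf("CI = %.*g at fa = %.*g (%s)\n", digits, x$ci, digits, x$fa,
              x$classification))
  cat(sprintf("  d1 = %.4g / Dx1 = %.4g; d2 = %.4g / Dx2 = %.4g; alpha = %d\n",
              x$d1, x$dx1, x$d2, x$dx2, x$alpha))
  invisible(x)
}

#' Fa-CI curve for a fixed-ratio combination
#'
#' For each effect level fa on the grid, the total combination dose
#' producing that effect is read off the combination's own median-effect
#' fit (the fixed-ratio mixture treated as a single agent at total dose
#' `d1 + d2`), split into components by the mixing weights, and the
#' Combination Index evaluated against the single-agent fits.
#'
#' @param fit_a,fit_b Single-agent `median_effect_fit` objects.
#' @param fit_combo `median_effect_fit` of the combination on total dose.
#' @param ratio Mixing weights (length 2, positive); normalised to sum 1.
#' @param grid Effect levels; default 0.25 to 0.90 in steps of 0.05
#'   (14 points).
#' @param alpha 0 or 1, as in [combination_index()].
#' @param tolerance Additive band half-width for classification.
#' @return An object of class `fa_ci_curve`: a data frame with columns
#'   `fa`, `total_dose`, `d1`, `d2`, `dx1`, `dx2`, `ci`, `classification`.
#' @export
fa_ci_curve <- function(fit_a, fit_b, fit_combo, ratio,
                        grid = seq(0.25, 0.90, by = 0.05), alpha = 0,
                        tolerance = 0.05) {
  if (length(grid) == 0) stop("empty fa grid", call. = FALSE)
  if (any(grid <= 0) || any(grid >= 1)) {
    stop("fa grid must lie strictly inside (0, 1)", call. = FALSE)
  }
  grid <- sort(grid)
  stopifnot(length(ratio) == 2, all(ratio > 0))
  w <- ratio / sum(ratio)
  dc <- dose_for_effect(fit_combo, grid)
  dx1 <- dose_for_effect(fit_a, grid)
  dx2 <- dose_for_effect(fit_b, grid)
  d1 <- dc * w[1]
  d2 <- dc * w[2]
  ci <- d1 / dx1 + d2 / dx2 + alpha * (d1 * d2) / (dx1 * dx2)
  out <- data.frame(fa = grid, total_dose = dc, d1 = d1, d2 = d2,
                    dx1 = dx1, dx2 = dx2, ci = ci,
                    classification = vapply(ci, classify_ci, "",
                                            tolerance = tolerance))
  structure(out, class = c("fa_ci_curve", "data.frame"),
            alpha = alpha, ratio = w)
}

#' @export
print.fa_ci_curve <- function(x, digits = 4, ...) {
  cat("Fa-CI curve (alpha =", attr(x, "alpha"), ", ratio =",
      paste(signif(attr(x, "ratio"), 4), collapse = ":"), ")\n")
  print.data.frame(format(as.data.frame(x), digits = digits),
                   row.names = FALSE)
  invisible(x)
}

#' @export
plot.fa_ci_curve <- function(x, ...) {
  graphics::plot(x$fa, x$ci, type = "b", xlab = "fraction affected (fa)",
                 ylab = "Combination Index", ylim = range(c(x$ci, 0, 1.5)),
                 ...)
  graphics::abline(h = 1, lty = 2, col = "grey40")
  invisible(x)
}

#' Dose-Reduction Index
#'
#' The fold by which the combination lowers each agent's dose relative to
#' the single-agent dose needed for the same effect:
#' `DRI_i = Dx_i / d_i`. A component dose of zero makes that component's
#' DRI undefined (`NA`).
#'
#' @param fit_a,fit_b Single-agent `median_effect_fit` objects.
#' @param d1,d2 Component doses in the combination (µM).
#' @param fa_obs Observed fraction affected, strictly inside `(0, 1)`.
#' @return A list with `dri_a` and `dri_b` (both positive, or `NA`).
#' @export
dose_reduction_index <- function(fit_a, fit_b, d1, d2, fa_obs) {
  if (fa_obs <= 0 || fa_obs >= 1) {
    stop("fa_obs must lie strictly inside (0, 1)", call. = FALSE)
  }
  dri <- function(fit, d) {
    if (d == 0) return(NA_real_)
    dose_for_effect(fit, fa_obs) / d
  }
  list(dri_a = dri(fit_a, d1), dri_b = dri(fit_b, d2))
}
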