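# Independent oracles used to freeze expected values. These deliberately
# avoid the package's own fitting/rootfinding code paths.

# 4PL by brute force: grid over (hill, ec50); for each node the optimal
# (top, bottom) is a bound-clipped linear least-squares solve, since the
# model is linear in (top, bottom) given the shape. Two refinement passes.
oracle_fourpl_grid <- function(dose, v) {
  vmax <- max(v); vmin <- min(v)
  pos <- dose[dose > 0]
  bounds <- list(top = c(0.9 * vmax, 1.1 * vmax + 5),
                 bottom = c(0, vmin),
                 hill = c(0.1, 10),
                 ec50 = c(min(pos) / 10, 10 * max(dose)))
  profile_sse <- function(hill, ec50) {
    f <- ifelse(dose == 0, 0, (dose / ec50)^hill)
    w <- 1 / (1 + f)                      # V = bottom + (top - bottom) * w
    X <- cbind(top = w, bottom = 1 - w)
    ab <- tryCatch(solve(crossprod(X), crossprod(X, v)),
                   error = function(e) NULL)
    if (is.null(ab)) return(list(sse = Inf))
    top <- min(max(ab[1], bounds$top[1]), bounds$top[2])
    bottom <- min(max(ab[2], bounds$bottom[1]), bounds$bottom[2])
    r <- v - (bottom + (top - bottom) * w)
    list(sse = sum(r^2), top = top, bottom = bottom)
  }
  h_grid <- exp(seq(log(0.1), log(10), length.out = 80))
  e_grid <- exp(seq(log(bounds$ec50[1]), log(bounds$ec50[2]),
                    length.out = 120))
  for (pass in 1:3) {
    best <- list(sse = Inf)
    for (h in h_grid) for (e in e_grid) {
      cand <- profile_sse(h, e)
      if (cand$sse < best$sse) {
        best <- c(cand, list(hill = h, ec50 = e))
      }
    }
    h_grid <- seq(best$hill * 0.8, best$hill * 1.25, length.out = 60)
    e_grid <- seq(best$ec50 * 0.8, best$ec50 * 1.25, length.out = 60)
  }
  best
}

# absolute IC50 by bisection on a given 4PL curve (no closed form used)
oracle_ic50_bisect <- function(top, bottom, hill, ec50, lo = 1e-8,
                               hi = 1e8) {
  f <- function(d) bottom + (top - bottom) / (1 + (d / ec50)^hill) - 50
  if (f(lo) < 0 || f(hi) > 0) return(NA_real_)
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

# median-effect fit by explicit closed-form OLS sums
oracle_median_effect_ols <- function(doses, fa) {
  x <- log10(doses); y <- log10(fa / (1 - fa))
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  m <- sxy / sxx
  b <- mean(y) - m * mean(x)
  syy <- sum(y^2) - sum(y)^2 / n
  list(m = m, dm = 10^(-b / m), r = sxy / sqrt(sxx * syy))
}

# Loewe-additive fa by dense grid scan of the additivity residual
oracle_loewe_grid <- function(dm1, m1, dm2, m2, d1, d2, n = 2e6) {
  fa <- seq(1e-7, 1 - 1e-7, length.out = n)
  dx1 <- dm1 * (fa / (1 - fa))^(1 / m1)
  dx2 <- dm2 * (fa / (1 - fa))^(1 / m2)
  resid <- d1 / dx1 + d2 / dx2 - 1
  fa[which.min(abs(resid))]
}

# shared fixture accessors
fixture_series <- function() {
  build_series(read_well_table(example_data_path("viability")))
}

fixture_combo_label <- function(series) {
  grep("@", names(series), value = TRUE)[1]
}
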