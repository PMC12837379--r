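#' Bliss Independence expected effect
#'
#' Expected combined inhibition of two independently acting agents:
#' `Eexp = EA + EB - EA * EB`. Symmetric in its arguments and bounded by
#' `max(EA, EB) <= Eexp <= min(1, EA + EB)`.
#'
#' @param e_a,e_b Single-agent inhibition fractions in `[0, 1]`; vectorised.
#' @return Expected inhibition fractions.
#' @examples
#' bliss_expected(0.58, 0.72)  # 0.8824
#' @export
bliss_expected <- function(e_a, e_b) {
  check_fraction(e_a, "e_a")
  check_fraction(e_b, "e_b")
  e_a + e_b - e_a * e_b
}

check_fraction <- function(x, name) {
  if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop(name, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

#' Bliss deviation and interaction call
#'
#' `delta = Eobs - Eexp`; a combination is called synergistic when the
#' observed effect exceeds the independence expectation by more than the
#' tolerance, antagonistic when it falls short by more, additive otherwise.
#' The default tolerance 0.01 gives the "approximately equal" additive
#' class a non-empty width.
#'
#' @param e_obs Observed combined inhibition fraction in `[0, 1]`.
#' @param e_exp Expected inhibition fraction in `[0, 1]` (e.g. from
#'   [bliss_expected()]).
#' @param tolerance Half-width of the additive band.
#' @return A list with `delta` and `classification`.
#' @export
delta_bliss <- function(e_obs, e_exp, tolerance = 0.01) {
  check_fraction(e_obs, "e_obs")
  check_fraction(e_exp, "e_exp")
  delta <- e_obs - e_exp
  cls <- ifelse(delta > tolerance, "synergistic",
                ifelse(delta < -tolerance, "antagonistic", "additive"))
  list(delta = delta, classification = cls)
}

#' Highest Single Agent expected effect
#'
#' The HSA reference: the expected combined effect is the larger of the two
#' single-agent effects, `Eexp = max(EA, EB)`. Always at most the Bliss
#' expectation, with equality iff `min(EA, EB) = 0`.
#'
#' @inheritParams bliss_expected
#' @return Expected inhibition fractions.
#' @export
hsa_expected <- function(e_a, e_b) {
  check_fraction(e_a, "e_a")
  check_fraction(e_b, "e_b")
  pmax(e_a, e_b)
}

#' Classify a Combination Index value
#'
#' CI < 1 is synergistic, CI > 1 antagonistic, CI = 1 additive; a band
#' `|CI - 1| <= tolerance` absorbs floating-point noise around exact
#' additivity.
#'
#' @param ci Positive Combination Index.
#' @param tolerance Half-width of the additive band (default 0.05).
#' @return `"synergistic"`, `"additive"` or `"antagonistic"`.
#' @examples
#' classify_ci(0.78)  # synergistic
#' classify_ci(1.32)  # antagonistic
#' @export
classify_ci <- function(ci, tolerance = 0.05) {
  if (any(is.na(ci)) || any(ci <= 0)) {
    stop("CI must be positive", call. = FALSE)
  }
  ifelse(abs(ci - 1) <= tolerance, "additive",
         ifelse(ci < 1, "synergistic", "antagonistic"))
}

#' Per-pair Bliss and HSA table for a fixed-ratio design
#'
#' For each dose of the combination series, splits the total dose into
#' component doses by the stored mixing ratio, looks up each agent's
#' single-agent inhibition at exactly the matching component dose, and
#' tabulates observed vs Bliss- and HSA-expected inhibition. Effects are
#' inhibition fractions throughout. By default a component dose absent
#' from the single-agent series yields `NA` for that pair; with
#' `interpolate = TRUE`, single-agent fa is interpolated linearly in dose.
#'
#' @param series_a,series_b Single-agent `dose_response_series`.
#' @param series_combo Combination `dose_response_series` (must carry a
#'   mixing `ratio`; component order follows `ratio` names against the
#'   single-agent series labels).
#' @param tolerance Additive band half-width for the Bliss and HSA calls.
#' @param interpolate Interpolate single-agent effects at unmatched
#'   component doses (default `FALSE`).
#' @return A data frame of class `synergy_table`, one row per combination
#'   dose pair: `d1`, `d2`, `e_a`, `e_b`, `e_obs`, `e_exp_bliss`,
#'   `delta_bliss`, `class_bliss`, `e_exp_hsa`, `delta_hsa`, `class_hsa`.
#' @export
synergy_table <- function(series_a, series_b, series_combo,
                          tolerance = 0.01, interpolate = FALSE) {
  stopifnot(inherits(series_combo, "dose_response_series"),
            !is.null(series_combo$ratio))
  w <- series_combo$ratio / sum(series_combo$ratio)
  # align ratio components to the two single-agent series by label
  if (!is.null(names(w)) && series_a$label %in% names(w)) {
    w <- w[c(series_a$label, series_b$label)]
  }
  lookup <- function(series, dose) {
    dat <- series$data
    hit <- which(abs(dat$total_dose - dose) <= 1e-9 * max(1, dose))
    if (length(hit) == 1) return(inhibition_fraction(dat$mean_viability[hit]))
    if (!interpolate) return(NA_real_)
    fa <- inhibition_fraction(dat$mean_viability)
    stats::approx(dat$total_dose, fa, xout = dose, rule = 2)$y
  }
  combo <- series_combo$data[series_combo$data$total_dose > 0, ]
  rows <- lapply(seq_len(nrow(combo)), function(i) {
    total <- combo$total_dose[i]
    d1 <- total * w[[1]]; d2 <- total * w[[2]]
    e_a <- lookup(series_a, d1)
    e_b <- lookup(series_b, d2)
    e_obs <- inhibition_fraction(combo$mean_viability[i])
    if (is.na(e_a) || is.na(e_b)) {
      return(data.frame(total_dose = total, d1 = d1, d2 = d2,
                        e_a = e_a, e_b = e_b, e_obs = e_obs,
                        e_exp_bliss = NA_real_, delta_bliss = NA_real_,
                        class_bliss = NA_character_, e_exp_hsa = NA_real_,
                        delta_hsa = NA_real_, class_hsa = NA_character_))
    }
    eb <- bliss_expected(e_a, e_b)
    db <- delta_bliss(e_obs, eb, tolerance)
    eh <- hsa_expected(e_a, e_b)
    dh <- delta_bliss(e_obs, eh, tolerance)
    data.frame(total_dose = total, d1 = d1, d2 = d2,
               e_a = e_a, e_b = e_b, e_obs = e_obs,
               e_exp_bliss = eb, delta_bliss = db$delta,
               class_bliss = db$classification,
               e_exp_hsa = eh, delta_hsa = dh$delta,
               class_hsa = dh$classification)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("synergy_table", "data.frame"))
}

#' @export
print.synergy_table <- function(x, digits = 4, ...) {
  cat("Bliss / HSA reference-model table (effects are inhibition fractions)\n")
  print.data.frame(format(as.data.frame(x), digits = digits),
                   row.names = FALSE)
  invisible(x)
}
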