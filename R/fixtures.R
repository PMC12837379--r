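#' Packaged MDA-MB-231 quercetin + gemcitabine example data
#'
#' Paths to the example tables installed with the package. The viability
#' table holds the published group-mean viabilities for the quercetin (Q)
#' and gemcitabine (GEM) single-agent series, the fixed-ratio (10:1)
#' combinations, and the untreated control (stored as printed, 98%,
#' without re-normalisation), each mean repeated over n = 3 replicates.
#' Three of the five combination conditions (Q10+GEM1, Q20+GEM2, Q40+GEM4)
#' have no published viability value; the file carries synthetic stand-ins
#' for them (64, 48 and 30%), chosen to show a mild positive Bliss
#' deviation consistent with the qualitative description of the screen —
#' hence the `_synthetic` suffix on the filename. The marker table holds
#' the published group summaries as single values.
#'
#' @param which `"viability"` or `"markers"`.
#' @return A file path.
#' @export
example_data_path <- function(which = c("viability", "markers")) {
  which <- match.arg(which)
  file <- switch(which,
                 viability = "mda_mb231_viability_synthetic.csv",
                 markers = "mda_mb231_markers.csv")
  system.file("extdata", file, package = "synergyci", mustWork = TRUE)
}

#' Published summary values of the worked example
#'
#' The headline numbers of the quercetin + gemcitabine MDA-MB-231 study,
#' as published, for side-by-side comparison with what the package computes
#' from the packaged tables (see [reproduce_published_example()]). Several published
#' values are mutually inconsistent with the published dose-response
#' series; the package reports both sides and never overwrites either.
#'
#' @return A nested list: `ic50` (µM, per agent, and the published potency
#'   ratio), `ci` (published CI values at fa 0.7 and 0.9), `combo_inhibition`
#'   (published combination reductions), `ros_fold`, `apoptosis_percent`,
#'   `correlation` (published ROS-apoptosis bound) and `qpcr_fold`.
#' @export
reported_values <- function() {
  list(
    ic50 = list(Q = 82.4, GEM = 17.2, potency_ratio = 4.8),
    ci = list(fa_0.70 = 1.32, fa_0.90 = 0.78),
    combo_inhibition = list(Q80_GEM8 = 0.62, Q100_GEM10 = 0.76),
    single_inhibition = list(Q100 = 0.58, GEM10 = 0.72, Q80 = 0.44,
                             GEM8 = 0.54),
    ros_fold = c(control = 1, Q = 1.6, GEM = 2.4, Q_GEM = 2.8),
    apoptosis_percent = c(control = 2.8, Q = 24.6, GEM = 38.4, Q_GEM = 44.2),
    correlation = list(ros_vs_apoptosis_r = 0.9),
    qpcr_fold = list(
      HIF1A = c(control = 1, Q = 0.6, GEM = 0.4, Q_GEM = 0.2),
      VEGF = c(control = 1, Q = 0.8, GEM = 0.6, Q_GEM = 0.4),
      BAX = c(control = 1, Q = 1.6, GEM = 2.3, Q_GEM = 2.5),
      BCL2 = c(control = 1, Q = 0.6, GEM = 0.4, Q_GEM = 0.3),
      CASP3 = c(control = 1, Q = 2.4, GEM = 2.8, Q_GEM = 3.2)
    )
  )
}
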