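#' Configuration for the combination-screen simulator
#'
#' Bundles and validates everything the simulator needs: median-effect
#' parameters for the two drugs, the fixed mixing ratio, dose grids,
#' the interaction ground truth, the noise level and the seed. Defaults
#' mirror the packaged quercetin (Q) + gemcitabine (GEM) MDA-MB-231 screen:
#' median-effect parameters fitted from the packaged single-agent series,
#' Q:GEM ratio 10:1, dose grids 0-100 µM (Q), 0-10 µM (GEM) and their
#' fixed-ratio totals, and biological triplicates.
#'
#' @param drug_a,drug_b Lists with `name`, `dm` (µM) and `m` (slope).
#' @param ratio Length-2 positive mixing weights (drug_a : drug_b).
#' @param dose_grid_a,dose_grid_b,dose_grid_combo Positive increasing dose
#'   grids (µM); the combo grid is in total dose.
#' @param interaction_mode `"loewe"`, `"bliss"` or `"potency_shift"` ground
#'   truth for the combination.
#' @param interaction_strength Positive; 1 means no interaction. Under
#'   `potency_shift`, effects are computed at component doses scaled by
#'   this factor, so the true Combination Index equals
#'   `1/interaction_strength` at every effect level.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   viability noise, in `[0, 0.5)`.
#' @param n_replicates Wells per condition.
#' @param seed Integer seed; all simulator outputs are deterministic given
#'   the config (Mersenne-Twister, recorded in the config's `rng` field).
#' @param marker_spec Named list: marker -> list(units, means (named per
#'   group), cv).
#' @param qpcr_spec List with `reference_ct`, `target_ct_control`,
#'   `noise_sd` (cycles) and `genes`, a named list gene -> named fold
#'   changes per group (control fold 1).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(
    drug_a = list(name = "Q", dm = 96.3494588, m = 0.9224870),
    drug_b = list(name = "GEM", dm = 4.7872312, m = 0.8382195),
    ratio = c(10, 1),
    dose_grid_a = c(10, 20, 40, 80, 100),
    dose_grid_b = c(1, 2, 4, 8, 10),
    dose_grid_combo = c(11, 22, 44, 88, 110),
    interaction_mode = c("loewe", "bliss", "potency_shift"),
    interaction_strength = 1,
    noise_cv = 0.05,
    n_replicates = 3,
    seed = 1L,
    marker_spec = default_marker_spec(),
    qpcr_spec = default_qpcr_spec()) {
  interaction_mode <- match.arg(interaction_mode)
  for (d in list(drug_a, drug_b)) {
    stopifnot(is.character(d$name), d$dm > 0, d$m > 0)
  }
  stopifnot(length(ratio) == 2, all(ratio > 0))
  for (g in list(dose_grid_a, dose_grid_b, dose_grid_combo)) {
    if (any(g <= 0) || any(diff(g) <= 0)) {
      stop("dose grids must be positive and strictly increasing",
           call. = FALSE)
    }
  }
  if (interaction_strength <= 0) {
    stop("interaction_strength must be positive", call. = FALSE)
  }
  if (noise_cv < 0 || noise_cv >= 0.5) {
    stop("noise_cv must lie in [0, 0.5)", call. = FALSE)
  }
  stopifnot(n_replicates >= 1)
  if (!is.null(marker_spec)) {
    for (mk in marker_spec) {
      if (any(mk$means < 0)) stop("marker means must be non-negative",
                                  call. = FALSE)
    }
  }
  structure(
    list(drug_a = drug_a, drug_b = drug_b, ratio = ratio / sum(ratio),
         dose_grid_a = dose_grid_a, dose_grid_b = dose_grid_b,
         dose_grid_combo = dose_grid_combo,
         interaction_mode = interaction_mode,
         interaction_strength = interaction_strength,
         noise_cv = noise_cv, n_replicates = as.integer(n_replicates),
         seed = as.integer(seed), rng = "Mersenne-Twister",
         marker_spec = marker_spec, qpcr_spec = qpcr_spec),
    class = "synthetic_config"
  )
}

#' Default marker panel specification
#'
#' Group means mirror the packaged MDA-MB-231 readouts: ROS fold changes
#' 1 / 1.6 / 2.4 / 2.8, caspase-3 folds 1 / 2.1 / 3.0 / 3.6 and apoptosis
#' percentages 2.8 / 24.6 / 38.4 / 44.2 across control / Q / GEM / Q_GEM,
#' each with a 5% CV.
#'
#' @return A named list usable as `marker_spec` in [synthetic_config()].
#' @export
default_marker_spec <- function() {
  g <- c("control", "Q", "GEM", "Q_GEM")
  list(
    ROS = list(units = "fold_of_control",
               means = stats::setNames(c(1, 1.6, 2.4, 2.8), g), cv = 0.05),
    caspase3 = list(units = "fold_of_control",
                    means = stats::setNames(c(1, 2.1, 3.0, 3.6), g),
                    cv = 0.05),
    apoptosis = list(units = "percent_cells",
                     means = stats::setNames(c(2.8, 24.6, 38.4, 44.2), g),
                     cv = 0.05)
  )
}

#' Default qPCR specification
#'
#' Fold changes mirror the packaged RT-qPCR panel (control / Q / GEM /
#' Q_GEM): HIF-1A 1/0.6/0.4/0.2, VEGF 1/0.8/0.6/0.4, BAX 1/1.6/2.3/2.5,
#' BCL2 1/0.6/0.4/0.3, CASP3 1/2.4/2.8/3.2, against a beta-actin-like
#' reference at Ct 15 and control target Ct 25.
#'
#' @return A list usable as `qpcr_spec` in [synthetic_config()].
#' @export
default_qpcr_spec <- function() {
  g <- c("control", "Q", "GEM", "Q_GEM")
  list(
    reference_ct = 15, target_ct_control = 25, noise_sd = 0,
    genes = list(
      HIF1A = stats::setNames(c(1, 0.6, 0.4, 0.2), g),
      VEGF = stats::setNames(c(1, 0.8, 0.6, 0.4), g),
      BAX = stats::setNames(c(1, 1.6, 2.3, 2.5), g),
      BCL2 = stats::setNames(c(1, 0.6, 0.4, 0.3), g),
      CASP3 = stats::setNames(c(1, 2.4, 2.8, 3.2), g)
    )
  )
}

me_fit_of <- function(drug) median_effect_pars(drug$dm, drug$m, drug$name)

#' Loewe-additive effect of a dose pair
#'
#' Solves the Loewe additivity equation
#' `d1/Dx1(fa) + d2/Dx2(fa) = 1` for the fraction affected `fa`, where
#' `Dx_i(fa)` comes from each agent's median-effect model. For positive
#' slopes the left side is strictly decreasing in `fa`, so the root is
#' unique; it is found by bisection on `fa` in `[1e-9, 1 - 1e-9]` to a
#' bracket width of 1e-12 (at most 200 iterations). When one dose is zero
#' the result reduces to the other agent's [effect_at_dose()].
#'
#' @param fit_a,fit_b `median_effect_fit` objects with positive slopes.
#' @param d1,d2 Non-negative doses (µM), not both zero.
#' @return The additive fraction affected in `(0, 1)`.
#' @export
loewe_effect <- function(fit_a, fit_b, d1, d2) {
  if (fit_a$m <= 0 || fit_b$m <= 0) {
    stop("Loewe effect requires positive median-effect slopes",
         call. = FALSE)
  }
  stopifnot(d1 >= 0, d2 >= 0, d1 + d2 > 0)
  if (d2 == 0) return(effect_at_dose(fit_a, d1))
  if (d1 == 0) return(effect_at_dose(fit_b, d2))
  g <- function(fa) {
    d1 / dose_for_effect(fit_a, fa) + d2 / dose_for_effect(fit_b, fa) - 1
  }
  lo <- 1e-9; hi <- 1 - 1e-9
  glo <- g(lo)
  if (glo < 0) return(lo)  # effect below resolvable range
  if (g(hi) > 0) return(hi)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
    if (hi - lo < 1e-12) break
  }
  (lo + hi) / 2
}

# multiplicative lognormal-style noise; sigma = log(1 + CV) keeps viability
# positive and the CV interpretable
noise_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  exp(stats::rnorm(n, 0, log(1 + cv)))
}

sim_wells <- function(agent_a, dose_a, agent_b, dose_b, fa_true, config) {
  n <- config$n_replicates
  rows <- lapply(seq_along(fa_true), function(i) {
    v <- 100 * (1 - fa_true[i]) * noise_factor(n, config$noise_cv)
    data.frame(agent_a = agent_a, dose_a = dose_a[i],
               agent_b = agent_b, dose_b = dose_b[i],
               replicate = seq_len(n), response = v,
               response_kind = "percent_viability",
               stringsAsFactors = FALSE)
  })
  validate_well_table(do.call(rbind, rows))
}

control_wells <- function(config) {
  v <- 100 * noise_factor(config$n_replicates, config$noise_cv)
  validate_well_table(data.frame(
    agent_a = "control", dose_a = 0, agent_b = "", dose_b = 0,
    replicate = seq_len(config$n_replicates), response = v,
    response_kind = "percent_viability", stringsAsFactors = FALSE))
}

#' Simulate a single-agent dose-response plate
#'
#' Generates wells at the configured dose grid with true effects from the
#' drug's median-effect model, viability `100 * (1 - fa)` under
#' multiplicative noise, plus untreated control wells. Deterministic given
#' the config (each simulator stream derives its own seed from
#' `config$seed`).
#'
#' @param config A [synthetic_config()].
#' @param drug `"a"` or `"b"`.
#' @return A `well_table` with `percent_viability` responses.
#' @export
simulate_single_agent <- function(config, drug = c("a", "b")) {
  stopifnot(inherits(config, "synthetic_config"))
  drug <- match.arg(drug)
  set.seed(config$seed + if (drug == "a") 11L else 12L)
  spec <- if (drug == "a") config$drug_a else config$drug_b
  grid <- if (drug == "a") config$dose_grid_a else config$dose_grid_b
  fa <- effect_at_dose(me_fit_of(spec), grid)
  rbind(control_wells(config),
        sim_wells(spec$name, grid, "", rep(0, length(grid)), fa, config))
}

#' Simulate a fixed-ratio combination plate
#'
#' Each total dose on the combo grid is split into component doses by the
#' mixing ratio and the true combined effect computed per the configured
#' ground truth: `loewe` solves the additivity equation; `bliss` combines
#' the single-agent effects as `EA + EB - EA*EB`; `potency_shift` evaluates
#' the Loewe effect at component doses scaled by `interaction_strength`
#' (so CI = 1/strength at every effect level). Untreated controls are
#' appended as for single agents.
#'
#' @param config A [synthetic_config()].
#' @return A `well_table` with `percent_viability` responses.
#' @export
simulate_combination <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed + 13L)
  fit_a <- me_fit_of(config$drug_a)
  fit_b <- me_fit_of(config$drug_b)
  w <- config$ratio
  d1 <- config$dose_grid_combo * w[1]
  d2 <- config$dose_grid_combo * w[2]
  s <- config$interaction_strength
  fa <- switch(
    config$interaction_mode,
    loewe = mapply(function(x, y) loewe_effect(fit_a, fit_b, x, y), d1, d2),
    bliss = bliss_expected(effect_at_dose(fit_a, d1),
                           effect_at_dose(fit_b, d2)),
    potency_shift = mapply(function(x, y) loewe_effect(fit_a, fit_b, x, y),
                           s * d1, s * d2),
    stop("unknown interaction mode", call. = FALSE)
  )
  rbind(control_wells(config),
        sim_wells(config$drug_a$name, d1, config$drug_b$name, d2, fa,
                  config))
}

#' Simulate the full combination screen
#'
#' Single-agent plates for both drugs plus the fixed-ratio combination
#' plate, in one `well_table` ready for [build_series()].
#'
#' @param config A [synthetic_config()].
#' @return A `well_table`.
#' @export
simulate_screen <- function(config) {
  a <- simulate_single_agent(config, "a")
  b <- simulate_single_agent(config, "b")
  ab <- simulate_combination(config)
  # keep a single set of control wells (from the first plate)
  drop_ctrl <- function(x) x[!(x$dose_a == 0 & x$dose_b == 0), ]
  validate_well_table(rbind(a, drop_ctrl(b), drop_ctrl(ab)))
}

#' Simulate marker panels with known group means
#'
#' Replicate values are drawn around the configured group means with the
#' configured CV (multiplicative noise, as for viability). With zero noise,
#' [fold_change()] on the output reproduces the configured mean ratios
#' exactly.
#'
#' @param config A [synthetic_config()] with a `marker_spec`.
#' @return A tidy data frame `marker, units, group, replicate, value`.
#' @export
simulate_markers <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (is.null(config$marker_spec)) stop("no marker_spec in config",
                                        call. = FALSE)
  set.seed(config$seed + 14L)
  n <- config$n_replicates
  rows <- list()
  for (mk in names(config$marker_spec)) {
    spec <- config$marker_spec[[mk]]
    for (g in names(spec$means)) {
      v <- spec$means[[g]] * noise_factor(n, spec$cv)
      rows[[length(rows) + 1]] <- data.frame(
        marker = mk, units = spec$units, group = g, replicate = seq_len(n),
        value = v, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate qPCR Ct tables encoding known fold changes
#'
#' Builds Ct values so that the 2^-ddCt method recovers the configured
#' fold changes: the reference gene sits at `reference_ct`, the control
#' group's target at `target_ct_control`, and each treated group's target
#' Ct is shifted by `-log2(fold)`. Optional Gaussian noise (`noise_sd`,
#' cycles) is added per well; with zero noise recovery is exact.
#'
#' @param config A [synthetic_config()] with a `qpcr_spec`.
#' @return A tidy data frame `group, target, replicate, ct_target,
#'   ct_reference`.
#' @export
simulate_qpcr <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  spec <- config$qpcr_spec
  if (is.null(spec)) stop("no qpcr_spec in config", call. = FALSE)
  set.seed(config$seed + 15L)
  n <- config$n_replicates
  rows <- list()
  for (gene in names(spec$genes)) {
    folds <- spec$genes[[gene]]
    for (g in names(folds)) {
      ct_t <- spec$target_ct_control - log2(folds[[g]]) +
        stats::rnorm(n, 0, spec$noise_sd)
      ct_r <- spec$reference_ct + stats::rnorm(n, 0, spec$noise_sd)
      rows[[length(rows) + 1]] <- data.frame(
        group = g, target = gene, replicate = seq_len(n),
        ct_target = ct_t, ct_reference = ct_r, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
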