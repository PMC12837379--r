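#' Run the full combination-screen analysis pipeline
#'
#' Orchestrates ingest (or simulation), series building, 4PL and
#' median-effect fitting, Fa-CI synergy analysis, Bliss/HSA reference
#' tables and marker summaries into one report. Stages run in order; any
#' stage failure is re-signalled with the stage name. Re-running with the
#' same config (and seed, when simulating) yields an identical report.
#'
#' @param config A configuration list as returned by [default_config()] /
#'   [load_config()]. Either `config$io$wells` points at a well CSV, or
#'   `config$simulate` holds a [synthetic_config()] (or argument list for
#'   one). Optional `config$io$markers` / `config$io$qpcr` add marker and
#'   qPCR summaries; `config$io$out` writes the JSON report.
#' @param quiet Suppress the one-line-per-stage log.
#' @return An object of class `run_report`: a nested list with `metadata`,
#'   `series`, `fourpl`, `ic50`, `median_effect`, `synergy` (Fa-CI grid,
#'   DRI, Bliss/HSA table), `markers`, `qpcr` and `warnings`.
#' @export
run_pipeline <- function(config = default_config(), quiet = FALSE) {
  warnings <- character()
  note <- function(...) {
    if (!quiet) message(sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  collect <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  # --- ingest -------------------------------------------------------------
  if (!is.null(config$simulate) &&
      !inherits(config$simulate, "synthetic_config")) {
    config$simulate <- do.call(synthetic_config, config$simulate)
  }
  wells <- stage("ingest", {
    if (!is.null(config$simulate)) {
      note("stage ingest: simulated screen, seed %d", config$simulate$seed)
      simulate_screen(config$simulate)
    } else {
      if (is.null(config$io$wells)) {
        stop("config has neither io$wells nor a simulate block")
      }
      note("stage ingest: %s", config$io$wells)
      read_well_table(config$io$wells)
    }
  })

  series <- stage("build_series", build_series(wells))
  singles <- Filter(function(s) is.null(s$ratio) && s$label != ".control",
                    series)
  combos <- Filter(function(s) !is.null(s$ratio), series)
  note("stage series: %d single-agent, %d combination series",
       length(singles), length(combos))

  # --- dose-response fits -------------------------------------------------
  fourpl <- stage("fourpl", lapply(series, function(s) {
    if (length(unique(s$data$total_dose)) < 4) return(NULL)
    collect(fit_four_pl(s))
  }))
  ic50 <- lapply(fourpl, function(f) {
    if (is.null(f)) return(NA_real_)
    collect(absolute_ic50(f))
  })
  mefits <- stage("median_effect", lapply(series, function(s) {
    if (s$label == ".control") return(NULL)
    collect(fit_median_effect(s))
  }))
  note("stage fits: %d 4PL, %d median-effect",
       sum(!vapply(fourpl, is.null, TRUE)),
       sum(!vapply(mefits, is.null, TRUE)))

  # --- synergy ------------------------------------------------------------
  synergy <- NULL
  if (length(singles) == 2 && length(combos) >= 1) {
    synergy <- stage("synergy", lapply(combos, function(cmb) {
      a <- singles[[1]]; b <- singles[[2]]
      w <- cmb$ratio
      if (!is.null(names(w)) && all(c(a$label, b$label) %in% names(w))) {
        w <- w[c(a$label, b$label)]
      }
      grid <- seq(config$synergy$fa_min, config$synergy$fa_max,
                  by = config$synergy$fa_step)
      curve <- collect(fa_ci_curve(
        mefits[[a$label]], mefits[[b$label]], mefits[[cmb$label]],
        ratio = as.numeric(w), grid = grid, alpha = config$synergy$alpha,
        tolerance = config$synergy$ci_tolerance))
      tab <- collect(synergy_table(
        a, b, cmb, tolerance = config$synergy$bliss_tolerance,
        interpolate = config$synergy$interpolate_singles))
      # CI and DRI at each observed combination point
      obs <- lapply(seq_len(nrow(tab)), function(i) {
        fa <- tab$e_obs[i]
        if (fa <= 0 || fa >= 1) return(NULL)
        ci <- combination_index(mefits[[a$label]], mefits[[b$label]],
                                tab$d1[i], tab$d2[i], fa,
                                alpha = config$synergy$alpha,
                                tolerance = config$synergy$ci_tolerance)
        dri <- dose_reduction_index(mefits[[a$label]], mefits[[b$label]],
                                    tab$d1[i], tab$d2[i], fa)
        list(d1 = tab$d1[i], d2 = tab$d2[i], fa_obs = fa, ci = ci$ci,
             classification = ci$classification, dri_a = dri$dri_a,
             dri_b = dri$dri_b)
      })
      list(combination = cmb$label, fa_ci = as.data.frame(curve),
           reference_models = as.data.frame(tab),
           observed_points = Filter(Negate(is.null), obs))
    }))
    note("stage synergy: %d combination(s) analysed", length(synergy))
  }

  # --- markers ------------------------------------------------------------
  markers <- NULL
  if (!is.null(config$io$markers)) {
    markers <- stage("markers", {
      panels <- read_marker_table(config$io$markers)
      do.call(rbind, lapply(panels, summarise_marker,
                            control_group = config$markers$control_group))
    })
    note("stage markers: %d panel rows", nrow(markers))
  }
  qpcr <- NULL
  if (!is.null(config$io$qpcr)) {
    qpcr <- stage("qpcr", {
      tab <- read_qpcr_table(config$io$qpcr)
      summarise_qpcr(tab, control_group = config$markers$control_group)
    })
    note("stage qpcr: %d gene-group RQs", nrow(qpcr))
  }

  report <- structure(
    list(
      metadata = list(package = "synergyci",
                      version = as.character(utils::packageVersion("synergyci")),
                      seed = if (!is.null(config$simulate))
                        config$simulate$seed else NULL),
      series = lapply(series, function(s)
        list(label = s$label, ratio = s$ratio, data = s$data)),
      fourpl = lapply(fourpl, function(f) {
        if (is.null(f)) return(NULL)
        list(top = f$top, bottom = f$bottom, hill = f$hill, ec50 = f$ec50,
             rss = f$rss, converged = f$converged)
      }),
      ic50 = ic50,
      median_effect = lapply(mefits, function(f) {
        if (is.null(f)) return(NULL)
        list(dm = f$dm, m = f$m, r = f$r, n_points = f$n_points,
             reliable = f$reliable)
      }),
      synergy = synergy,
      markers = markers,
      qpcr = qpcr,
      warnings = warnings
    ),
    class = "run_report"
  )
  if (!is.null(config$io$out)) {
    write_report(report, config$io$out)
    note("stage report: wrote %s", config$io$out)
  }
  report
}

#' Relative expression summary for a qPCR table
#'
#' 2^-ddCt relative quantity of every gene in every non-control group,
#' against the control group.
#'
#' @param tab A qPCR data frame as from [read_qpcr_table()] or
#'   [simulate_qpcr()].
#' @param control_group Control group label.
#' @return A data frame `target, group, rq`.
#' @export
summarise_qpcr <- function(tab, control_group = "control") {
  rows <- list()
  for (gene in unique(tab$target)) {
    sub <- tab[tab$target == gene, ]
    ctl <- sub[sub$group == control_group, ]
    if (nrow(ctl) == 0) {
      stop("qPCR control group '", control_group, "' absent for target ",
           gene, call. = FALSE)
    }
    for (g in setdiff(unique(sub$group), control_group)) {
      rows[[length(rows) + 1]] <- data.frame(
        target = gene, group = g,
        rq = relative_quantity(ctl, sub[sub$group == g, ]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("synergyci run report\n")
  cat("  series:", paste(names(x$series), collapse = ", "), "\n")
  ic <- unlist(x$ic50)
  ic <- ic[!is.na(ic)]
  if (length(ic) > 0) {
    cat("  absolute IC50 (µM):",
        paste(sprintf("%s = %.3g", names(ic), ic), collapse = ", "), "\n")
  }
  if (!is.null(x$synergy)) {
    for (s in x$synergy) {
      cat("  combination", s$combination, ": CI range [",
          sprintf("%.3g", min(s$fa_ci$ci)), ",",
          sprintf("%.3g", max(s$fa_ci$ci)), "] over fa grid\n")
    }
  }
  if (length(x$warnings) > 0) {
    cat("  warnings:", length(x$warnings), "\n")
  }
  invisible(x)
}

#' Recompute the worked example and compare with the published numbers
#'
#' Runs the packaged MDA-MB-231 quercetin + gemcitabine tables through the
#' pipeline and reports, side by side with the published values: single-
#' agent inhibition fractions, 4PL fits and absolute IC50s, the published
#' IC50 potency ratio, the Bliss/HSA table for the two fully published
#' combination pairs, the Combination Index at the observed Q80+GEM8
#' point, the ROS-apoptosis Pearson correlation, and marker fold/percent
#' summaries. qPCR Ct tables are synthesised to encode the published fold
#' changes (see [simulate_qpcr()]). Where the computed value disagrees
#' with the published one — several published numbers are mutually
#' inconsistent — both are reported; nothing is overwritten.
#'
#' @param alpha CI interaction constant, 0 (default) or 1.
#' @return An object of class `published_comparison` (a nested list; see Details).
#' @export
reproduce_published_example <- function(alpha = 0) {
  printed <- reported_values()
  wells <- read_well_table(example_data_path("viability"))
  series <- build_series(wells)
  q <- series[["Q"]]; gem <- series[["GEM"]]
  combo_name <- grep("^GEM\\+Q@|^Q\\+GEM@", names(series), value = TRUE)
  combo <- series[[combo_name[1]]]

  # (a) inhibition fractions from the published viabilities
  inhibition <- lapply(list(Q = q, GEM = gem, combination = combo),
                       function(s) data.frame(
                         total_dose = s$data$total_dose,
                         fa = inhibition_fraction(s$data$mean_viability)))

  # (b) 4PL fits and absolute IC50s computed from the published series
  fit_q <- fit_four_pl(q); fit_g <- fit_four_pl(gem)
  ic50 <- list(
    Q = list(computed = suppressWarnings(absolute_ic50(fit_q)),
             printed = printed$ic50$Q),
    GEM = list(computed = suppressWarnings(absolute_ic50(fit_g)),
               printed = printed$ic50$GEM))

  # (c) published IC50 potency ratio
  potency <- list(
    computed_from_printed_ic50s = round(printed$ic50$Q / printed$ic50$GEM, 1),
    printed = printed$ic50$potency_ratio)

  # median-effect fits on the published single-agent series
  me_q <- fit_median_effect(q); me_g <- fit_median_effect(gem)
  me_c <- fit_median_effect(combo)

  # (d) Bliss/HSA table (published pairs are Q80+GEM8 and Q100+GEM10)
  bliss <- synergy_table(q, gem, combo)

  # (e) CI and DRI at the observed Q80+GEM8 point (fa_obs = 0.62)
  fa_obs <- printed$combo_inhibition$Q80_GEM8
  ci_obs <- combination_index(me_q, me_g, d1 = 80, d2 = 8, fa_obs = fa_obs,
                              alpha = alpha)
  dri_obs <- dose_reduction_index(me_q, me_g, d1 = 80, d2 = 8,
                                  fa_obs = fa_obs)

  # Fa-CI curve from the packaged series, next to the published CI values
  curve <- fa_ci_curve(me_q, me_g, me_c, ratio = combo$ratio, alpha = alpha)
  ci_compare <- list(
    fa_0.70 = list(computed = curve$ci[abs(curve$fa - 0.70) < 1e-9],
                   printed = printed$ci$fa_0.70),
    fa_0.90 = list(computed = curve$ci[abs(curve$fa - 0.90) < 1e-9],
                   printed = printed$ci$fa_0.90))

  # (f) ROS-apoptosis correlation over the four group summaries
  panels <- read_marker_table(example_data_path("markers"))
  grp <- c("control", "Q", "GEM", "Q_GEM")
  ros <- vapply(grp, function(g) panels$ROS$groups[[g]][1], 0)
  apo <- vapply(grp, function(g) panels$apoptosis$groups[[g]][1], 0)
  correlation <- list(
    computed = pearson_r(ros, apo),
    printed_bound = printed$correlation$ros_vs_apoptosis_r)

  # (g) marker fold / percent summaries
  marker_summary <- do.call(rbind, lapply(panels, summarise_marker))

  # qPCR: synthetic Ct tables encoding the published folds, then 2^-ddCt
  cfg <- synthetic_config(noise_cv = 0, seed = 1L)
  qpcr <- summarise_qpcr(simulate_qpcr(cfg))
  qpcr$printed_fold <- mapply(function(t, g) printed$qpcr_fold[[t]][[g]],
                              qpcr$target, qpcr$group)

  structure(
    list(inhibition = inhibition,
         fourpl = list(Q = fit_q, GEM = fit_g),
         ic50 = ic50, potency_ratio = potency,
         median_effect = list(Q = me_q, GEM = me_g, combination = me_c),
         reference_models = bliss,
         ci_at_Q80_GEM8 = ci_obs, dri_at_Q80_GEM8 = dri_obs,
         fa_ci = curve, ci_vs_printed = ci_compare,
         correlation = correlation,
         markers = marker_summary, qpcr = qpcr),
    class = "published_comparison")
}

#' @export
print.published_comparison <- function(x, ...) {
  cat("Worked example: quercetin + gemcitabine, MDA-MB-231 (computed vs published)\n\n")
  cat(sprintf("IC50 Q:   computed %.4g µM | published %.4g µM\n",
              x$ic50$Q$computed, x$ic50$Q$printed))
  cat(sprintf("IC50 GEM: computed %.4g µM | published %.4g µM\n",
              x$ic50$GEM$computed, x$ic50$GEM$printed))
  cat(sprintf("Potency ratio (published IC50s): %.1f | published %.1f\n",
              x$potency_ratio$computed_from_printed_ic50s,
              x$potency_ratio$printed))
  cat(sprintf("\nMedian-effect: Q Dm = %.4g, m = %.4g (r = %.3f); GEM Dm = %.4g, m = %.4g (r = %.3f)\n",
              x$median_effect$Q$dm, x$median_effect$Q$m, x$median_effect$Q$r,
              x$median_effect$GEM$dm, x$median_effect$GEM$m,
              x$median_effect$GEM$r))
  cat(sprintf("CI at Q80+GEM8 (fa = %.2f): %.4g (%s); DRI Q = %.3g, GEM = %.3g\n",
              x$ci_at_Q80_GEM8$fa, x$ci_at_Q80_GEM8$ci,
              x$ci_at_Q80_GEM8$classification,
              x$dri_at_Q80_GEM8$dri_a, x$dri_at_Q80_GEM8$dri_b))
  cat(sprintf("CI at fa 0.70: computed %.4g | published %.4g\n",
              x$ci_vs_printed$fa_0.70$computed, x$ci_vs_printed$fa_0.70$printed))
  cat(sprintf("CI at fa 0.90: computed %.4g | published %.4g\n",
              x$ci_vs_printed$fa_0.90$computed, x$ci_vs_printed$fa_0.90$printed))
  cat(sprintf("\nROS-apoptosis Pearson r: computed %.4f | published bound %.2f\n",
              x$correlation$computed, x$correlation$printed_bound))
  cat("\nBliss/HSA table (inhibition fractions):\n")
  print(x$reference_models)
  invisible(x)
}
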