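#' Fold change of a treated group over control
#'
#' Ratio of group means, the convention used for ROS (DCFDA fluorescence)
#' and caspase-3 activity readouts.
#'
#' @param treated,control Numeric replicate values; control mean must be
#'   positive.
#' @return `mean(treated) / mean(control)`.
#' @export
fold_change <- function(treated, control) {
  if (length(control) == 0 || length(treated) == 0) {
    stop("fold change needs non-empty treated and control groups",
         call. = FALSE)
  }
  mc <- mean(control)
  if (is.na(mc) || mc <= 0) {
    stop("control mean must be positive", call. = FALSE)
  }
  mean(treated) / mc
}

#' Signed percent change relative to control
#'
#' `(mean(treated)/mean(control) - 1) * 100`; the percent-of-control
#' convention used for the antioxidant/oxidative-stress panel (SOD, CAT,
#' GSH, MDA). Exactly `(fold_change - 1) * 100`.
#'
#' @inheritParams fold_change
#' @return Signed percent.
#' @export
percent_change <- function(treated, control) {
  (fold_change(treated, control) - 1) * 100
}

#' Annexin/PI quadrant percentages
#'
#' Constructor validating a flow-cytometry quadrant breakdown. Convention
#' (Annexin V-FITC / PI): Q1 Annexin-/PI+ necrotic; Q2 Annexin+/PI+ late
#' apoptotic; Q3 Annexin-/PI- viable; Q4 Annexin+/PI- early apoptotic.
#' (Some figure legends swap Q3/Q4; this package follows the gating
#' definition above.)
#'
#' @param q1,q2,q3,q4 Percentages in `[0, 100]`, summing to 100 within
#'   rounding (`[99, 101]`).
#' @return A named numeric vector of class `quadrant_counts`.
#' @export
quadrant_counts <- function(q1, q2, q3, q4) {
  q <- c(q1 = q1, q2 = q2, q3 = q3, q4 = q4)
  if (any(is.na(q)) || any(q < 0) || any(q > 100)) {
    stop("quadrant percentages must lie in [0, 100]", call. = FALSE)
  }
  s <- sum(q)
  if (s < 99 || s > 101) {
    stop("quadrant percentages must sum to 100 within rounding (got ",
         format(s), ")", call. = FALSE)
  }
  structure(q, class = "quadrant_counts")
}

#' Total apoptosis from quadrant percentages
#'
#' The sum of the early (Q4, Annexin+/PI-) and late (Q2, Annexin+/PI+)
#' apoptotic populations, as a percent of total cells.
#'
#' @param q A `quadrant_counts` object (see [quadrant_counts()]).
#' @return Percent apoptotic cells, `q2 + q4`.
#' @export
total_apoptosis <- function(q) {
  stopifnot(inherits(q, "quadrant_counts"))
  unname(q["q2"] + q["q4"])
}

#' Relative expression by the 2^-ddCt method
#'
#' Per group, `dCt` is the mean of per-replicate `ct_target - ct_reference`
#' (paired within wells, the standard ddCt bookkeeping); then
#' `ddCt = dCt_treated - dCt_control` and the relative quantity is
#' `RQ = 2^(-ddCt)`, the fold expression of the target in the treated group
#' relative to control, normalised to the reference gene.
#'
#' @param control,treated Data frames with columns `target`, `ct_target`,
#'   `ct_reference` (one row per replicate), both for the same target gene.
#'   Ct values must lie in `[1, 45]` cycles.
#' @return The relative quantity (fold), a single number.
#' @examples
#' ctl <- data.frame(target = "HIF1A", ct_target = 25, ct_reference = 15)
#' trt <- data.frame(target = "HIF1A", ct_target = 26, ct_reference = 15)
#' relative_quantity(ctl, trt)  # 0.5
#' @export
relative_quantity <- function(control, treated) {
  for (df in list(control, treated)) {
    if (nrow(df) == 0) stop("empty qPCR group", call. = FALSE)
    ct <- c(df$ct_target, df$ct_reference)
    if (any(is.na(ct)) || any(ct < 1) || any(ct > 45)) {
      stop("Ct values must lie in [1, 45] cycles", call. = FALSE)
    }
  }
  if (!all(unique(treated$target) %in% unique(control$target)) ||
      length(unique(c(control$target, treated$target))) != 1) {
    stop("mismatched qPCR targets between groups", call. = FALSE)
  }
  dct_c <- mean(control$ct_target - control$ct_reference)
  dct_t <- mean(treated$ct_target - treated$ct_reference)
  2^(-(dct_t - dct_c))
}

#' Pearson correlation between two marker summaries
#'
#' Sample Pearson correlation, after checking that the vectors have equal
#' length at least 3 and non-zero variance. Used e.g. to relate group-level
#' ROS fold changes to apoptosis percentages.
#'
#' @param x,y Numeric vectors.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3) stop("need at least 3 paired observations",
                          call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in input", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Read a tidy marker table
#'
#' CSV with header `marker, units, group, replicate, value`; one row per
#' replicate measurement. Units are one of `U_per_mg_protein`,
#' `umol_per_mg_protein`, `nmol_per_mg_protein`, `fold_of_control`,
#' `percent_of_control`, `percent_cells`, `MFI`.
#'
#' @param path Path to the CSV file.
#' @return A named list of marker panels; each panel has fields `marker`,
#'   `units` and `groups` (named list of replicate value vectors).
#' @export
read_marker_table <- function(path) {
  if (!file.exists(path)) stop("marker table not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("marker", "units", "group", "replicate", "value")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("marker table format error: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  units_ok <- c("U_per_mg_protein", "umol_per_mg_protein",
                "nmol_per_mg_protein", "fold_of_control",
                "percent_of_control", "percent_cells", "MFI")
  bad <- setdiff(unique(df$units), units_ok)
  if (length(bad) > 0) {
    stop("marker table format error: unknown units: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(df$value < 0)) {
    stop("marker values must be non-negative", call. = FALSE)
  }
  panels <- lapply(split(df, df$marker), function(d) {
    list(marker = d$marker[1], units = d$units[1],
         groups = lapply(split(d, d$group), function(g) g$value))
  })
  panels[unique(df$marker)]
}

#' Read a tidy qPCR Ct table
#'
#' CSV with header `group, target, replicate, ct_target, ct_reference`.
#'
#' @param path Path to the CSV file.
#' @return A data frame with those columns, Ct values validated to
#'   `[1, 45]`.
#' @export
read_qpcr_table <- function(path) {
  if (!file.exists(path)) stop("qPCR table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("group", "target", "replicate", "ct_target", "ct_reference")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("qPCR table format error: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  ct <- c(df$ct_target, df$ct_reference)
  if (any(is.na(ct)) || any(ct < 1) || any(ct > 45)) {
    stop("Ct values must lie in [1, 45] cycles", call. = FALSE)
  }
  df
}

#' Summarise a marker panel
#'
#' Mean, SD and n per group, plus fold change and percent change versus the
#' control group when it is present.
#'
#' @param panel One element of [read_marker_table()]'s result.
#' @param control_group Label of the control group (default `"control"`).
#' @return A data frame with one row per group.
#' @export
summarise_marker <- function(panel, control_group = "control") {
  ctrl <- panel$groups[[control_group]]
  rows <- lapply(names(panel$groups), function(g) {
    v <- panel$groups[[g]]
    fc <- if (!is.null(ctrl)) fold_change(v, ctrl) else NA_real_
    data.frame(marker = panel$marker, units = panel$units, group = g,
               mean = mean(v),
               sd = if (length(v) > 1) stats::sd(v) else 0,
               n = length(v),
               fold_vs_control = fc,
               percent_change = if (is.na(fc)) NA_real_ else (fc - 1) * 100)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
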