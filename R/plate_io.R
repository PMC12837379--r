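#' Read a tidy well-level viability table
#'
#' Reads a plate-reader export in the package's tidy CSV layout: one row per
#' well, comma-separated, UTF-8, decimal point, with the header
#' `agent_a, dose_a, agent_b, dose_b, replicate, response, response_kind`.
#' An empty `agent_b` cell marks a single-agent well (its `dose_b` must then
#' be 0). `response_kind` is either `"raw_signal"` (e.g. raw absorbance) or
#' `"percent_viability"`.
#'
#' @param path Path to the CSV file.
#' @return A data frame of class `well_table`, one row per well, rows in
#'   input order, with doses in µM.
#' @seealso [build_series()] to aggregate wells into dose-response series.
#' @export
read_well_table <- function(path) {
  if (!file.exists(path)) {
    stop("well table not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = TRUE)
  required <- c("agent_a", "dose_a", "agent_b", "dose_b",
                "replicate", "response", "response_kind")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("well table format error: missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[, required]
  num <- function(col) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) & !(is.na(df[[col]]) | df[[col]] == ""))
    if (length(bad) > 0) {
      stop("well table error: non-numeric ", col, " at row ", bad[1],
           " (value '", df[[col]][bad[1]], "')", call. = FALSE)
    }
    x
  }
  out <- data.frame(
    agent_a = trimws(df$agent_a),
    dose_a = num("dose_a"),
    agent_b = trimws(df$agent_b),
    dose_b = num("dose_b"),
    replicate = num("replicate"),
    response = num("response"),
    response_kind = trimws(df$response_kind),
    stringsAsFactors = FALSE
  )
  out$agent_b[is.na(out$agent_b)] <- ""
  out$dose_b[is.na(out$dose_b) & out$agent_b == ""] <- 0
  validate_well_table(out)
}

validate_well_table <- function(df) {
  ok_kind <- df$response_kind %in% c("raw_signal", "percent_viability")
  if (any(!ok_kind)) {
    stop("well table format error: unknown response_kind '",
         df$response_kind[which(!ok_kind)[1]], "'", call. = FALSE)
  }
  if (any(is.na(df$dose_a)) || any(df$dose_a < 0) || any(df$dose_b < 0)) {
    stop("well table error: doses must be non-negative", call. = FALSE)
  }
  if (any(is.na(df$response)) || any(df$response < 0)) {
    stop("well table error: responses must be non-negative", call. = FALSE)
  }
  if (any(is.na(df$replicate)) || any(df$replicate < 1)) {
    stop("well table error: replicate must be a positive integer", call. = FALSE)
  }
  class(df) <- c("well_table", "data.frame")
  df
}

#' Construct a well table in memory
#'
#' Convenience constructor applying the same validation as
#' [read_well_table()].
#'
#' @param agent_a,dose_a Primary agent label and dose (µM).
#' @param agent_b,dose_b Optional second agent; `agent_b = ""` and
#'   `dose_b = 0` for single-agent wells.
#' @param replicate Positive integer replicate index.
#' @param response Raw signal or percent viability, per `response_kind`.
#' @param response_kind `"raw_signal"` or `"percent_viability"`.
#' @return A `well_table` data frame.
#' @export
well_table <- function(agent_a, dose_a, agent_b = "", dose_b = 0,
                       replicate = 1L, response,
                       response_kind = "percent_viability") {
  df <- data.frame(agent_a = agent_a, dose_a = dose_a, agent_b = agent_b,
                   dose_b = dose_b, replicate = replicate,
                   response = response, response_kind = response_kind,
                   stringsAsFactors = FALSE)
  validate_well_table(df)
}

# Combination identity: unordered agent pair + mixing ratio rounded to
# 6 significant digits, so float jitter in dose columns cannot split a series.
combo_key <- function(agent_a, agent_b, dose_a, dose_b) {
  agents <- c(agent_a, agent_b)
  doses <- c(dose_a, dose_b)
  ord <- order(agents)
  w <- signif(doses[ord] / sum(doses), 6)
  paste0(agents[ord][1], "+", agents[ord][2], "@", w[1], ":", w[2])
}

#' Aggregate wells into dose-response series
#'
#' Groups wells by agent (single agents) or by unordered agent pair and
#' mixing ratio (fixed-ratio combinations), converts raw signals to percent
#' of the mean untreated control, and aggregates replicates to mean, SD and
#' n per dose. Combination series are keyed by total dose (`dose_a +
#' dose_b`) with the mixing ratio stored alongside. Untreated control wells
#' (all doses 0) contribute a dose-0 anchor point to every series.
#'
#' Viability values above 100% (stimulation) are retained but flagged in the
#' series' `flagged` field; downstream analyses decide what to do with them.
#'
#' @param wells A `well_table` (see [read_well_table()]).
#' @return A named list of `dose_response_series` objects. Each has fields
#'   `label`, `agents`, `ratio` (`NULL` for single agents; combination
#'   mixing weights summing to 1 otherwise), and `data`, a data frame with
#'   columns `total_dose`, `mean_viability`, `sd`, `n`.
#' @export
build_series <- function(wells) {
  stopifnot(inherits(wells, "well_table"))
  kinds <- unique(wells$response_kind)
  if (length(kinds) > 1) {
    stop("well table mixes response kinds; split before aggregation",
         call. = FALSE)
  }
  is_control <- wells$dose_a == 0 & wells$dose_b == 0
  if (kinds == "raw_signal") {
    if (!any(is_control)) {
      stop("normalization error: raw signals require at least one untreated ",
           "control well (all doses 0)", call. = FALSE)
    }
    scale <- mean(wells$response[is_control])
    viability <- 100 * wells$response / scale
  } else {
    viability <- wells$response
  }

  is_combo <- wells$agent_b != "" & wells$dose_b > 0 & !is_control
  key <- character(nrow(wells))
  key[is_control] <- ".control"
  single <- !is_control & !is_combo
  key[single] <- wells$agent_a[single]
  if (any(is_combo)) {
    key[is_combo] <- mapply(combo_key,
                            wells$agent_a[is_combo], wells$agent_b[is_combo],
                            wells$dose_a[is_combo], wells$dose_b[is_combo])
  }

  agg <- function(idx) {
    total <- wells$dose_a[idx] + wells$dose_b[idx]
    # sort groups by dose value, not insertion order, so series are
    # invariant to row permutation
    sp <- split(viability[idx], total)
    d <- as.numeric(names(sp))
    o <- order(d)
    data.frame(
      total_dose = d[o],
      mean_viability = vapply(sp, mean, 0)[o],
      sd = vapply(sp, function(v) if (length(v) > 1) stats::sd(v) else 0, 0)[o],
      n = vapply(sp, length, 0L)[o],
      row.names = NULL
    )
  }

  control_point <- if (any(is_control)) agg(which(is_control)) else NULL

  labels <- sort(setdiff(unique(key), ".control"))
  if (length(labels) == 0 && !is.null(control_point)) {
    s <- new_series(".control", agents = unique(wells$agent_a[is_control]),
                    ratio = NULL, data = control_point)
    return(stats::setNames(list(s), ".control"))
  }

  out <- lapply(labels, function(lab) {
    idx <- which(key == lab)
    dat <- agg(idx)
    ratio <- NULL
    agents <- unique(wells$agent_a[idx])
    if (any(is_combo[idx])) {
      agents <- c(wells$agent_a[idx][1], wells$agent_b[idx][1])
      w <- cbind(wells$dose_a[idx], wells$dose_b[idx])
      w <- w / rowSums(w)
      w6 <- unique(round(signif(w, 6), 12))
      if (nrow(w6) > 1) {
        stop("grouping error: inconsistent mixing ratios within combination '",
             lab, "'", call. = FALSE)
      }
      ratio <- as.numeric(w[1, ])
      names(ratio) <- agents
    }
    if (!is.null(control_point)) dat <- rbind(control_point, dat)
    new_series(lab, agents = agents, ratio = ratio, data = dat)
  })
  stats::setNames(out, labels)
}

new_series <- function(label, agents, ratio, data) {
  stopifnot(all(diff(data$total_dose) > 0), all(data$n >= 1))
  structure(
    list(label = label, agents = agents, ratio = ratio, data = data,
         flagged = data$total_dose[data$mean_viability > 100]),
    class = "dose_response_series"
  )
}

#' @export
print.dose_response_series <- function(x, ...) {
  cat("Dose-response series:", x$label, "\n")
  if (!is.null(x$ratio)) {
    cat("  fixed-ratio combination, weights ",
        paste(sprintf("%s=%.4g", names(x$ratio), x$ratio), collapse = ", "),
        "\n", sep = "")
  }
  print(x$data, row.names = FALSE, ...)
  if (length(x$flagged) > 0) {
    cat("  note: viability > 100% at dose(s) ",
        paste(x$flagged, collapse = ", "), " (retained, flagged)\n", sep = "")
  }
  invisible(x)
}

#' Default run configuration
#'
#' @return A nested list with sections `io`, `dose_response`, `synergy`,
#'   `markers` and `simulate` holding the package defaults: unweighted 4PL
#'   fits, mutually exclusive CI (`alpha = 0`), Fa grid 0.25-0.90 in steps
#'   of 0.05, CI additive tolerance 0.05, Bliss additive tolerance 0.01.
#' @export
default_config <- function() {
  list(
    io = list(wells = NULL, markers = NULL, qpcr = NULL, out = NULL),
    dose_response = list(replicate_weighting = FALSE),
    synergy = list(alpha = 0, fa_min = 0.25, fa_max = 0.90, fa_step = 0.05,
                   ci_tolerance = 0.05, bliss_tolerance = 0.01,
                   interpolate_singles = FALSE),
    markers = list(control_group = "control"),
    simulate = NULL
  )
}

#' Load a YAML run configuration
#'
#' Reads a YAML file with any of the sections `io`, `dose_response`,
#' `synergy`, `markers`, `simulate` and merges it over [default_config()].
#' Unknown keys produce a warning, not an error.
#'
#' @param path Path to a YAML file.
#' @return The merged configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  merge_config(default_config(), user, prefix = "")
}

merge_config <- function(base, user, prefix) {
  for (k in names(user)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", k) else k
    if (!k %in% names(base) && prefix != "" && prefix != "simulate") {
      warning("unknown config key ignored: ", full, call. = FALSE)
      next
    }
    if (is.list(base[[k]]) && is.list(user[[k]]) && k != "simulate") {
      base[[k]] <- merge_config(base[[k]], user[[k]], full)
    } else {
      base[[k]] <- user[[k]]
    }
  }
  base
}

#' Write an analysis report to JSON
#'
#' Serialises a report (any nested list of scalars, vectors and data frames)
#' to pretty-printed JSON with full numeric precision. Writing the same
#' object twice produces byte-identical files.
#'
#' @param results A list, e.g. a `run_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_report()]
#' @export
write_report <- function(results, path) {
  results <- unclass_recursive(results)
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

unclass_recursive <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) {
    x <- unclass(x)
    return(lapply(x, unclass_recursive))
  }
  x
}

#' Read a JSON report written by [write_report()]
#'
#' @param path Path to the JSON file.
#' @return The parsed list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
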