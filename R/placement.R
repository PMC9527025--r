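#' Nearest relative of a focal species by genetic distance
#'
#' Among non-focal species, finds the one minimising the minimum percent
#' distance to the focal species. Ties on the minimum are broken by smaller
#' range midpoint, then lexicographic species name, with a warning.
#'
#' @param ranges a [species_pair_ranges()] result.
#' @param focal focal species name.
#' @return a list with `species`, `min_percent`, `max_percent`.
#' @export
nearest_relative <- function(ranges, focal) {
  btw <- ranges[ranges$type == "between" &
                  (ranges$species_a == focal | ranges$species_b == focal), ,
                drop = FALSE]
  if (!nrow(btw)) {
    if (!focal %in% c(ranges$species_a, ranges$species_b)) {
      stop("focal species '", focal, "' not present in the range table")
    }
    stop("no non-focal species to compare against")
  }
  other <- ifelse(btw$species_a == focal, btw$species_b, btw$species_a)
  mid <- (btw$min_percent + btw$max_percent) / 2
  ord <- order(btw$min_percent, mid, other)
  best <- ord[1]
  ties <- which(btw$min_percent == btw$min_percent[best])
  if (length(ties) > 1L) {
    warning("tie on minimum distance among: ",
            paste(sort(other[ties]), collapse = ", "),
            "; broken by midpoint then name")
  }
  out <- list(species = other[best],
              min_percent = btw$min_percent[best],
              max_percent = btw$max_percent[best])
  if (all(c("min_percent_raw", "max_percent_raw") %in% names(btw))) {
    out$min_percent_raw <- btw$min_percent_raw[best]
    out$max_percent_raw <- btw$max_percent_raw[best]
  }
  out
}

#' Flag whether a predicted divergence pre-dates the Quaternary
#'
#' @param prediction a [predict_time()] result.
#' @param boundary period boundary in My (default 2.58, the base of the
#'   Quaternary).
#' @param use compare the interval's `"lower"` bound (default) or the
#'   `"point"` estimate against the boundary.
#' @return `TRUE` if the chosen value exceeds `boundary`.
#' @export
quaternary_flag <- function(prediction, boundary = 2.58,
                            use = c("lower", "point")) {
  use <- match.arg(use)
  val <- if (use == "lower") prediction$lower else prediction$point
  isTRUE(val > boundary)
}

#' Place a focal taxon on a calibrated timescale
#'
#' End-to-end pipeline: computes the p-distance matrix and species-pair
#' percent ranges from the alignment, finds the focal species' nearest
#' relative, builds a calibration table from the non-focal species pairs
#' (distances from the alignment, times from the chronogram), fits the
#' calibration line in both modes, and predicts the focal species' minimum
#' divergence time from its distance to the nearest relative.
#'
#' The focal species must be absent from the chronogram: it is the taxon
#' being placed, and letting its true divergence time into the calibration
#' would leak the answer.
#'
#' @param aln an [alignment] containing the focal species' sequences and
#'   those of its relatives.
#' @param sm a [species_map] covering every alignment tip.
#' @param tree_or_table a `"chronogram"` (divergence times are extracted
#'   with [pair_time_table()]) or a pre-built `"calibration_table"` /
#'   data frame with columns `species_a`, `species_b`, `distance_percent`,
#'   `time_my` (rows involving the focal species are refused).
#' @param focal focal species name (at least one sequence in `aln`).
#' @param summary distance summary entering prediction: `"mean"` midpoint of
#'   the min--max range to the nearest relative (default), or `"min"` to use
#'   the smallest observed distance literally.
#' @param fit_mode headline fit: `"unconstrained"` (default) or
#'   `"through_origin"`; the other mode is reported alongside.
#' @param interval,level,halfwidth interval options passed to
#'   [predict_time()].
#' @param decimals percent rounding for the range table (default 1).
#' @param min_comparable comparable-site warning floor, see
#'   [distance_matrix()].
#' @param cherries_only restrict calibration pairs to cherries, see
#'   [pair_time_table()].
#' @return an object of class `"placement_report"`.
#' @export
place_taxon <- function(aln, sm, tree_or_table, focal,
                        summary = c("mean", "min"),
                        fit_mode = c("unconstrained", "through_origin"),
                        interval = c("prediction", "fixed"),
                        level = 0.95, halfwidth = NULL,
                        decimals = 1L, min_comparable = 50L,
                        cherries_only = FALSE) {
  summary <- match.arg(summary)
  fit_mode <- match.arg(fit_mode)
  interval <- match.arg(interval)
  warnings <- character()
  note <- function(...) warnings <<- c(warnings, paste0(...))

  if (!focal %in% sm$species) stop("focal species '", focal,
                                   "' not in species map")
  focal_tips <- sm$tip_id[sm$species == focal]
  if (!any(focal_tips %in% aln$tip_ids)) {
    stop("focal species has no sequence in the alignment")
  }

  withCallingHandlers({
    dm <- distance_matrix(aln, min_comparable = min_comparable)
    ranges <- species_pair_ranges(dm, sm, decimals = decimals)
  }, warning = function(w) {
    note(conditionMessage(w)); invokeRestart("muffleWarning")
  })

  nn <- withCallingHandlers(
    nearest_relative(ranges, focal),
    warning = function(w) {
      note(conditionMessage(w)); invokeRestart("muffleWarning")
    })

  if (inherits(tree_or_table, "chronogram")) {
    tree_tips <- tree_or_table$phy$tip.label
    tree_species <- unique(
      ifelse(tree_tips %in% sm$tip_id,
             stats::setNames(sm$species, sm$tip_id)[tree_tips], tree_tips))
    if (focal %in% tree_species || any(focal_tips %in% tree_tips)) {
      stop("focal species '", focal, "' is present in the chronogram; ",
           "refusing to calibrate on the taxon being placed")
    }
    times <- withCallingHandlers(
      pair_time_table(tree_or_table, sm = sm, cherries_only = cherries_only),
      warning = function(w) {
        note(conditionMessage(w)); invokeRestart("muffleWarning")
      })
  } else {
    times <- tree_or_table
    need <- c("species_a", "species_b", "time_my")
    if (inherits(times, "calibration_table") ||
        all(c(need, "distance_percent") %in% names(times))) {
      if (focal %in% c(times$species_a, times$species_b)) {
        stop("calibration table contains pairs involving the focal species")
      }
      caltab <- times
      caltab <- structure(caltab, class = c("calibration_table", "data.frame"))
      times <- NULL
    } else {
      stop("tree_or_table must be a chronogram or a calibration table")
    }
  }

  if (!is.null(times)) {
    if (focal %in% c(times$species_a, times$species_b)) {
      stop("divergence-time table contains the focal species")
    }
    keep <- ranges$species_a != focal & ranges$species_b != focal
    caltab <- suppressMessages(
      build_calibration_table(ranges[keep, , drop = FALSE], times,
                              summary = "mean"))
  }

  fits <- list(
    unconstrained = fit_calibration(caltab, mode = "unconstrained"),
    through_origin = fit_calibration(caltab, mode = "through_origin")
  )
  headline <- fits[[fit_mode]]

  # rounded values are for display; full-precision endpoints drive prediction
  x_used <- if (summary == "mean") {
    distance_range_summary(nn$min_percent_raw, nn$max_percent_raw)
  } else {
    nn$min_percent_raw
  }
  pred <- predict_time(headline, x_used, interval = interval,
                       level = level, halfwidth = halfwidth)
  if (pred$clipped) note("prediction interval clipped at 0 My")

  within <- NULL
  if (sum(focal_tips %in% aln$tip_ids) >= 2L) {
    within <- within_species_divergence(dm, sm, focal)
  }

  structure(
    list(focal = focal,
         nearest_relative = nn$species,
         nearest_range_percent = c(nn$min_percent, nn$max_percent),
         distance_summary = summary,
         distance_used_percent = x_used,
         fits = lapply(fits, fit_summary),
         headline_mode = fit_mode,
         prediction = unclass(pred),
         predates_quaternary = quaternary_flag(pred),
         within_focal_percent = within,
         n_calibration_pairs = nrow(caltab),
         warnings = warnings),
    class = "placement_report"
  )
}

#' @export
print.placement_report <- function(x, ...) {
  cat("Placement report for '", x$focal, "'\n", sep = "")
  cat(sprintf("  nearest relative: %s (%.1f-%.1f%%)\n", x$nearest_relative,
              x$nearest_range_percent[1], x$nearest_range_percent[2]))
  cat(sprintf("  distance used: %.3f%% (%s of range)\n",
              x$distance_used_percent, x$distance_summary))
  for (m in names(x$fits)) {
    f <- x$fits[[m]]
    cat(sprintf("  fit %-14s y = %.3f x + %.3f, R^2 = %.3f, n = %d%s\n",
                paste0(m, ":"), f$slope, f$intercept, f$r_squared,
                f$n_points, if (m == x$headline_mode) "  [headline]" else ""))
  }
  p <- x$prediction
  cat(sprintf("  predicted divergence: %.1f My (%.1f-%.1f; %s)\n",
              p$point, p$lower, p$upper, p$method))
  cat("  pre-dates Quaternary (2.58 My):",
      if (x$predates_quaternary) "yes" else "no", "\n")
  if (!is.null(x$within_focal_percent)) {
    w <- x$within_focal_percent
    cat(sprintf("  within-focal divergence: %.1f-%.1f%% (%s reference %.1f-%.1f)\n",
                w$min_percent, w$max_percent, w$relation,
                w$reference[1], w$reference[2]))
  }
  if (length(x$warnings)) {
    cat("  warnings:\n")
    for (w in x$warnings) cat("   -", w, "\n")
  }
  invisible(x)
}

#' Serialize a placement report (or other result) to JSON
#'
#' Deterministic JSON: identical inputs yield byte-identical output.
#'
#' @param x a report or list.
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @return JSON text (invisibly, when written to `path`).
#' @export
report_json <- function(x, path = NULL) {
  json <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
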