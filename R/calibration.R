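#' Join distance ranges and divergence times into a calibration table
#'
#' Each calibration point pairs a species pair's percent genetic distance
#' (a summary of its min--max range; by default the midpoint) with its
#' divergence time in My from the chronogram. Pairs present in only one of
#' the two inputs are dropped with a message.
#'
#' @param ranges a [species_pair_ranges()] result (between-species rows are
#'   used).
#' @param times a [pair_time_table()] result.
#' @param summary which summary of the percent range to use as x:
#'   `"mean"` (midpoint, default), `"min"` or `"max"`.
#' @param precision use the full-precision percent values when the range
#'   table carries them (`"raw"`, default) or the rounded display values
#'   (`"display"`).
#' @return a data frame of class `"calibration_table"` with columns
#'   `species_a`, `species_b`, `distance_percent`, `time_my`.
#' @export
build_calibration_table <- function(ranges, times,
                                    summary = c("mean", "min", "max"),
                                    precision = c("raw", "display")) {
  summary <- match.arg(summary)
  precision <- match.arg(precision)
  btw <- ranges[ranges$type == "between", , drop = FALSE]
  raw <- precision == "raw" &&
    all(c("min_percent_raw", "max_percent_raw") %in% names(btw))
  lo <- if (raw) btw$min_percent_raw else btw$min_percent
  hi <- if (raw) btw$max_percent_raw else btw$max_percent
  x <- switch(summary,
              mean = (lo + hi) / 2,
              min = lo,
              max = hi)
  rkey <- pair_key(btw$species_a, btw$species_b)
  tkey <- pair_key(times$species_a, times$species_b)
  if (anyDuplicated(rkey) || anyDuplicated(tkey)) {
    stop("duplicate unordered species pairs in input tables")
  }
  shared <- intersect(rkey, tkey)
  n_drop <- (length(rkey) - length(shared)) + (length(tkey) - length(shared))
  if (n_drop > 0) {
    message(n_drop, " pair(s) present in only one table dropped")
  }
  if (length(shared) < 2L) {
    stop("need at least 2 species pairs shared by both tables, got ",
         length(shared))
  }
  ri <- match(shared, rkey)
  ti <- match(shared, tkey)
  out <- data.frame(
    species_a = btw$species_a[ri],
    species_b = btw$species_b[ri],
    distance_percent = x[ri],
    time_my = times$time_my[ti],
    stringsAsFactors = FALSE
  )
  class(out) <- c("calibration_table", "data.frame")
  out
}

#' Read a calibration table from CSV
#'
#' Expects columns `species_a,species_b,distance_percent,time_my`.
#'
#' @param path CSV path.
#' @return a `"calibration_table"` data frame.
#' @export
read_calibration_table <- function(path) {
  if (!file.exists(path)) stop("calibration table not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_a", "species_b", "distance_percent", "time_my")
  if (!all(need %in% names(df))) {
    stop("calibration table must have columns ",
         paste(need, collapse = ", "))
  }
  if (any(df$distance_percent < 0)) stop("distances must be >= 0")
  if (any(df$time_my <= 0)) stop("divergence times must be > 0")
  if (anyDuplicated(pair_key(df$species_a, df$species_b))) {
    stop("duplicate unordered species pairs")
  }
  df <- df[, need]
  class(df) <- c("calibration_table", "data.frame")
  df
}

#' Construct a calibration fit from known coefficients
#'
#' Builds a `"calibration_fit"` directly from a slope and intercept, e.g. a
#' published calibration line, without the underlying points. Such a fit can
#' be used for point prediction and fixed-half-width intervals, but not for
#' residual-based prediction intervals.
#'
#' @param slope slope in My per percent distance.
#' @param intercept intercept in My (0 for a through-origin line).
#' @param mode `"unconstrained"` or `"through_origin"`.
#' @param r_squared optional known coefficient of determination.
#' @return a `"calibration_fit"` object.
#' @export
calibration_fit <- function(slope, intercept = 0,
                            mode = c("unconstrained", "through_origin"),
                            r_squared = NA_real_) {
  mode <- match.arg(mode)
  if (mode == "through_origin" && intercept != 0) {
    stop("through-origin fit must have intercept 0")
  }
  structure(
    list(mode = mode, slope = slope, intercept = intercept,
         r_squared = r_squared, n_points = NA_integer_,
         model = NULL, data = NULL),
    class = "calibration_fit"
  )
}

#' Fit the time-versus-distance calibration line
#'
#' Ordinary least squares of divergence time (My) on percent genetic
#' distance. In `"unconstrained"` mode, slope and intercept are fitted and
#' R^2 is the usual centered 1 - SSres/SStot. In `"through_origin"` mode the
#' line is constrained through the origin (slope = sum(xy)/sum(x^2)) and R^2
#' uses the uncentered definition 1 - SSres/sum(y^2), which is the
#' conventional choice for no-intercept regression.
#'
#' @param table a `"calibration_table"` (or data frame with columns
#'   `distance_percent`, `time_my`).
#' @param mode `"unconstrained"` (default) or `"through_origin"`.
#' @return a `"calibration_fit"`: `mode`, `slope` (My/percent), `intercept`
#'   (My), `r_squared`, `n_points`, plus the underlying `lm` model and data
#'   for interval prediction.
#' @export
fit_calibration <- function(table,
                            mode = c("unconstrained", "through_origin")) {
  mode <- match.arg(mode)
  x <- table$distance_percent
  y <- table$time_my
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  dat <- data.frame(x = x, y = y)
  if (mode == "unconstrained") {
    if (n < 2L) stop("unconstrained fit needs at least 2 points")
    if (length(unique(x)) < 2L) stop("degenerate design: all x identical")
    fm <- stats::lm(y ~ x, data = dat)
    slope <- unname(stats::coef(fm)["x"])
    intercept <- unname(stats::coef(fm)["(Intercept)"])
    ss_res <- sum(stats::residuals(fm)^2)
    ss_tot <- sum((y - mean(y))^2)
    r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  } else {
    if (n < 1L) stop("through-origin fit needs at least 1 point")
    if (all(x == 0)) stop("degenerate design: all x are 0")
    fm <- stats::lm(y ~ x + 0, data = dat)
    slope <- unname(stats::coef(fm)["x"])
    intercept <- 0
    ss_res <- sum(stats::residuals(fm)^2)
    r2 <- 1 - ss_res / sum(y^2)
  }
  structure(
    list(mode = mode, slope = slope, intercept = intercept,
         r_squared = r2, n_points = n, model = fm, data = dat),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("Calibration fit (%s): y = %.4g x %s %.4g   R^2 = %s   n = %s\n",
              x$mode, x$slope, if (x$intercept < 0) "-" else "+",
              abs(x$intercept),
              if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared),
              if (is.na(x$n_points)) "NA" else x$n_points))
  invisible(x)
}

#' Mean of a percent-distance range
#'
#' Arithmetic mean of the endpoints of a min--max percent distance range,
#' the summary used to pick the single distance entering time prediction.
#'
#' @param min_pct,max_pct range endpoints in percent, `0 <= min <= max`.
#' @return the midpoint in percent.
#' @export
distance_range_summary <- function(min_pct, max_pct) {
  if (min_pct < 0) stop("percent distances must be >= 0")
  if (max_pct < min_pct) stop("inverted range: max < min")
  (min_pct + max_pct) / 2
}

#' Predict a divergence time from a calibration fit
#'
#' Point estimate `slope * x + intercept` with an uncertainty interval:
#' either a regression prediction interval computed from the fit's residuals
#' (`interval = "prediction"`, requires a fitted table of at least 3 points)
#' or a fixed half-width supplied by the user (`interval = "fixed"`),
#' mirroring the convention of quoting a calibration estimate as
#' "point +/- halfwidth". Negative bounds (possible with a negative
#' intercept at small x) are clipped to 0 and flagged.
#'
#' @param fit a `"calibration_fit"`.
#' @param x percent genetic distance (must be >= 0).
#' @param interval `"prediction"`, `"fixed"` or `"none"`.
#' @param level coverage level for the prediction interval (default 0.95).
#' @param halfwidth half-width in My for `interval = "fixed"`.
#' @return an object of class `"time_prediction"`: `x_input`, `point`,
#'   `lower`, `upper`, `level`, `method`, `clipped`.
#' @export
predict_time <- function(fit, x,
                         interval = c("prediction", "fixed", "none"),
                         level = 0.95, halfwidth = NULL) {
  stopifnot(inherits(fit, "calibration_fit"))
  interval <- match.arg(interval)
  if (!is.finite(x) || x < 0) stop("x must be a finite percent >= 0")
  point <- fit$slope * x + fit$intercept
  if (interval == "prediction") {
    if (is.null(fit$model)) {
      stop("prediction interval needs a fit with underlying points; ",
           "use interval = 'fixed' for a coefficients-only fit")
    }
    if (fit$n_points < 3L) {
      stop("prediction interval requires at least 3 calibration points")
    }
    pr <- stats::predict(fit$model, newdata = data.frame(x = x),
                         interval = "prediction", level = level)
    lower <- pr[1, "lwr"]; upper <- pr[1, "upr"]
    method <- sprintf("regression prediction interval, level %.2f", level)
  } else if (interval == "fixed") {
    if (is.null(halfwidth) || !is.finite(halfwidth) || halfwidth < 0) {
      stop("interval = 'fixed' requires a non-negative halfwidth")
    }
    lower <- point - halfwidth
    upper <- point + halfwidth
    method <- sprintf("fixed half-width %.3g My", halfwidth)
    level <- NA_real_
  } else {
    lower <- point
    upper <- point
    method <- "point estimate only"
    level <- NA_real_
  }
  clipped <- FALSE
  if (lower < 0) { lower <- 0; clipped <- TRUE }
  if (point < 0) { point <- 0; clipped <- TRUE }
  if (upper < 0) { upper <- 0; clipped <- TRUE }
  structure(
    list(x_input = x, point = unname(point), lower = unname(lower),
         upper = unname(upper), level = level, method = method,
         clipped = clipped),
    class = "time_prediction"
  )
}

#' @export
print.time_prediction <- function(x, ...) {
  cat(sprintf("Predicted divergence time: %.1f My (%.1f-%.1f My; %s)%s\n",
              x$point, x$lower, x$upper, x$method,
              if (x$clipped) " [clipped at 0]" else ""))
  invisible(x)
}

# Serializable summary of a fit (used in reports / JSON output).
fit_summary <- function(fit) {
  list(mode = fit$mode, slope = fit$slope, intercept = fit$intercept,
       r_squared = fit$r_squared, n_points = fit$n_points)
}
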