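#' Calibration curve container
#'
#' Holds a fitted printer-calibration curve: either the cubic grey-to-ink
#' relation or the linear ink-to-counts relation, with its goodness of fit
#' and validity domain. Curves must be monotone non-decreasing on their
#' domain so that they can be inverted.
#'
#' @param kind `"cubic"` or `"linear"`.
#' @param coefficients numeric coefficients, constant term first (4 for
#'   cubic, 2 for linear).
#' @param r_squared coefficient of determination in \[0, 1\].
#' @param domain length-2 numeric, valid input interval.
#' @return An object of class `calibration_curve`.
#' @export
calibration_curve <- function(kind = c("cubic", "linear"), coefficients,
                              r_squared = NA_real_, domain = c(0, 1)) {
  kind <- match.arg(kind)
  n_expected <- if (kind == "cubic") 4L else 2L
  if (length(coefficients) != n_expected)
    stop("calibration_curve: ", kind, " needs ", n_expected, " coefficients")
  structure(list(kind = kind, coefficients = as.numeric(coefficients),
                 r_squared = r_squared, domain = as.numeric(domain)),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s, R^2 = %s, domain [%g, %g]\n",
              x$kind,
              ifelse(is.na(x$r_squared), "NA", sprintf("%.4f", x$r_squared)),
              x$domain[1], x$domain[2]))
  invisible(x)
}

#' Evaluate a calibration curve
#'
#' @param curve a `calibration_curve`.
#' @param x input values.
#' @export
eval_curve <- function(curve, x) {
  co <- curve$coefficients
  drop(outer(x, seq_along(co) - 1, `^`) %*% co)
}

curve_is_monotone <- function(curve, n_check = 512L) {
  xs <- seq(curve$domain[1], curve$domain[2], length.out = n_check)
  all(diff(eval_curve(curve, xs)) >= -1e-12 * max(1, abs(diff(range(
    eval_curve(curve, xs))))))
}

r_squared_of <- function(y, fitted) {
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(1)
  1 - ss_res / ss_tot
}

#' Calibration samples
#'
#' Builds the sample table used by the calibration fits. All arguments are
#' recycled to a common length.
#'
#' @param grey_level fraction of maximum printed intensity, in \[0, 1\].
#' @param ink_weight_mg deposited ink, mg.
#' @param counts decay-corrected detector counts (>= 0).
#' @param activity_rel relative activity concentration of the ink mixture.
#' @return A data.frame of class `calibration_samples`.
#' @export
calibration_samples <- function(grey_level, ink_weight_mg = NA_real_,
                                counts = NA_real_, activity_rel = 1) {
  df <- data.frame(grey_level = grey_level, ink_weight_mg = ink_weight_mg,
                   counts = counts, activity_rel = activity_rel)
  if (any(df$grey_level < 0 | df$grey_level > 1, na.rm = TRUE))
    stop("calibration_samples: grey_level must be in [0, 1]")
  if (any(df$counts < 0, na.rm = TRUE))
    stop("calibration_samples: counts must be >= 0")
  class(df) <- c("calibration_samples", "data.frame")
  df
}

#' Fit the cubic grey-to-ink calibration
#'
#' Least-squares third-degree polynomial for deposited ink weight as a
#' function of specified grey level, fitted to all replicates. The fit must
#' be monotone non-decreasing over the observed grey range, otherwise an
#' error advises densifying the sampling.
#'
#' @param samples a [calibration_samples()] data.frame with `grey_level` and
#'   `ink_weight_mg`.
#' @return A `calibration_curve` of kind `"cubic"`.
#' @export
fit_grey_to_ink <- function(samples) {
  g <- samples$grey_level
  w <- samples$ink_weight_mg
  keep <- is.finite(g) & is.finite(w)
  g <- g[keep]; w <- w[keep]
  if (length(unique(g)) < 5L)
    stop("fit_grey_to_ink: need at least 5 distinct grey levels")
  fit <- stats::lm(w ~ g + I(g^2) + I(g^3))
  co <- unname(stats::coef(fit))
  if (any(!is.finite(co)))
    stop("fit_grey_to_ink: rank-deficient design")
  curve <- calibration_curve("cubic", co,
                             r_squared = r_squared_of(w, stats::fitted(fit)),
                             domain = range(g))
  if (!curve_is_monotone(curve))
    stop("fit_grey_to_ink: fitted cubic is not monotone on the sampled ",
         "grey range; densify the grey-level sampling")
  curve
}

#' Fit the linear ink-to-counts calibration
#'
#' Pools samples across activity concentrations: the predictor is deposited
#' ink weight times relative activity, the response the decay-corrected
#' counts. Least-squares line.
#'
#' @param samples a [calibration_samples()] data.frame with `ink_weight_mg`,
#'   `activity_rel` and `counts`.
#' @return A `calibration_curve` of kind `"linear"`.
#' @export
fit_ink_to_counts <- function(samples) {
  x <- samples$ink_weight_mg * samples$activity_rel
  y <- samples$counts
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L)
    stop("fit_ink_to_counts: need at least 3 points")
  if (all(samples$activity_rel == 0)) {
    # no activity anywhere: counts carry no signal, slope is zero
    return(calibration_curve("linear", c(mean(y), 0), r_squared = 1,
                             domain = c(0, max(x, 1))))
  }
  if (stats::var(x) == 0)
    stop("fit_ink_to_counts: degenerate design (no spread in ink x activity)")
  fit <- stats::lm(y ~ x)
  calibration_curve("linear", unname(stats::coef(fit)),
                    r_squared = r_squared_of(y, stats::fitted(fit)),
                    domain = range(x))
}

#' Correct counts for radioactive decay
#'
#' Scales counts measured `elapsed_minutes` after the reference time back to
#' that reference: `counts * 2^(elapsed / half_life)`. Negative elapsed
#' times decay forward (halve).
#'
#' @param counts non-negative counts.
#' @param elapsed_minutes minutes since the common reference time.
#' @param half_life_minutes isotope half-life (default 109.77, 18F).
#' @export
decay_correct <- function(counts, elapsed_minutes,
                          half_life_minutes = 109.77) {
  if (any(counts < 0)) stop("decay_correct: counts must be >= 0")
  counts * 2^(elapsed_minutes / half_life_minutes)
}

#' Grey level to print for a target relative activity
#'
#' Numerically inverts the composed calibration
#' `counts(grey) = ink_to_counts(grey_to_ink(grey))`, normalised so that
#' grey = 1 maps to relative activity 1, by bisection to a grey tolerance of
#' 1e-6.
#'
#' @param target relative activity in \[0, 1\] of the composed maximum.
#' @param grey_to_ink cubic `calibration_curve` from [fit_grey_to_ink()].
#' @param ink_to_counts linear `calibration_curve` from
#'   [fit_ink_to_counts()].
#' @param tol bisection tolerance in grey (default 1e-6).
#' @return The grey level in \[domain\] achieving the target.
#' @export
grey_for_target_activity <- function(target, grey_to_ink, ink_to_counts,
                                     tol = 1e-6) {
  if (!curve_is_monotone(grey_to_ink) || !curve_is_monotone(ink_to_counts))
    stop("grey_for_target_activity: curves must be monotone")
  lo <- grey_to_ink$domain[1]; hi <- grey_to_ink$domain[2]
  f <- function(g) eval_curve(ink_to_counts, eval_curve(grey_to_ink, g))
  c_lo <- f(lo); c_hi <- f(hi)
  if (c_hi <= c_lo)
    stop("grey_for_target_activity: degenerate calibration (flat response)")
  rel <- function(g) (f(g) - c_lo) / (c_hi - c_lo)
  if (target < -1e-12 || target > 1 + 1e-12)
    stop(sprintf(paste0("grey_for_target_activity: target %.4g outside the ",
                        "achievable relative range [0, 1]"), target))
  target <- min(max(target, 0), 1)
  a <- lo; b <- hi
  while (b - a > tol) {
    m <- (a + b) / 2
    if (rel(m) < target) a <- m else b <- m
  }
  (a + b) / 2
}

#' Read calibration samples from CSV
#'
#' Expected columns: `grey_level`, `ink_weight_mg`, `counts`,
#' `activity_rel`, `elapsed_min`. If `correct_decay` is `TRUE` (default),
#' counts are decay-corrected to the common reference using `elapsed_min`.
#'
#' @param path CSV file path.
#' @param correct_decay apply [decay_correct()] to the counts column.
#' @param half_life_minutes isotope half-life for the correction.
#' @return A `calibration_samples` data.frame.
#' @export
read_calibration_csv <- function(path, correct_decay = TRUE,
                                 half_life_minutes = 109.77) {
  df <- utils::read.csv(path)
  need <- c("grey_level", "ink_weight_mg", "counts", "activity_rel")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("read_calibration_csv: missing columns: ",
         paste(miss, collapse = ", "))
  counts <- df$counts
  if (correct_decay && "elapsed_min" %in% names(df))
    counts <- decay_correct(counts, df$elapsed_min, half_life_minutes)
  calibration_samples(df$grey_level, df$ink_weight_mg, counts,
                      df$activity_rel)
}

#' Serialise a calibration curve to JSON (and back)
#'
#' @param curve a `calibration_curve`.
#' @param path optional file; if `NULL`, the JSON string is returned.
#' @export
curve_to_json <- function(curve, path = NULL) {
  js <- jsonlite::toJSON(unclass(curve), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname curve_to_json
#' @param json JSON string or file path produced by [curve_to_json()].
#' @export
curve_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  calibration_curve(obj$kind, obj$coefficients, obj$r_squared, obj$domain)
}
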