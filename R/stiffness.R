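#' Summed absolute Bragg shift of one press
#'
#' The probe's first-order, non-vectorial stiffness statistic: the absolute
#' per-channel Bragg peak shifts of one press are summed over all four
#' gratings. Under constant indentation depth a stiffer target deforms the
#' dome more, so larger summed shifts indicate stiffer tissue.
#'
#' @param shifts a `shift_vector` from [compute_shifts()], or any finite
#'   numeric vector of per-channel shifts in pm.
#' @return The summed absolute shift `S` in pm (non-negative scalar).
#' @examples
#' summed_shift(c(10, -5, 2, -3))  # 20 pm
#' @export
summed_shift <- function(shifts) {
  shifts <- as.numeric(shifts)
  if (!length(shifts) || any(!is.finite(shifts))) {
    stop("shifts must be a non-empty vector of finite values")
  }
  sum(abs(shifts))
}

#' Assemble per-point stiffness records
#'
#' @param point_id identifier of each press point.
#' @param x_rel,y_rel relative coordinates of each press point (mm).
#' @param shifts a list of `shift_vector`s (or numeric vectors, pm), one per
#'   point.
#' @return A data frame of class `stiffness_records` with per-channel shift
#'   columns `d<i>_pm`, the summed statistic `S_pm` and a placeholder
#'   `s_norm` column (`NA` until [normalize_session()] assigns it).
#' @export
stiffness_records <- function(point_id, x_rel, y_rel, shifts) {
  n <- length(point_id)
  stopifnot(length(x_rel) == n, length(y_rel) == n, length(shifts) == n)
  if (anyDuplicated(point_id)) stop("point ids must be unique")
  n_ch <- length(shifts[[1]])
  mat <- t(vapply(shifts, as.numeric, numeric(n_ch)))
  colnames(mat) <- paste0("d", seq_len(n_ch), "_pm")
  out <- data.frame(point_id = point_id, x_rel = as.numeric(x_rel),
                    y_rel = as.numeric(y_rel), mat)
  out$S_pm <- vapply(shifts, summed_shift, numeric(1))
  out$s_norm <- NA_real_
  class(out) <- c("stiffness_records", "data.frame")
  out
}

#' Normalize summed shifts to relative stiffness within a session
#'
#' Min-max normalization over one palpation session (one organ scan): the
#' stiffest point (largest `S`) maps to exactly 1 and the softest (smallest
#' `S`) to exactly 0. Values are comparable only within the session they were
#' normalized in; no cross-organ comparability is implied.
#'
#' If every `S` in the session is equal there is no stiffness contrast to
#' resolve: all points are assigned 0 and a degenerate-session warning is
#' emitted (uniformly "softest" is a safer report than `NaN`).
#'
#' @param records a `stiffness_records` data frame (or any data frame with an
#'   `S_pm` column) with at least 2 rows.
#' @return The records with `s_norm` filled in.
#' @examples
#' r <- stiffness_records(1:4, c(0, 1, 0, 1), c(0, 0, 1, 1),
#'                        list(c(5, 0, 0, 0), c(10, 0, 0, 0),
#'                             c(20, 0, 0, 0), c(40, 0, 0, 0)))
#' normalize_session(r)$s_norm  # 0, 5/35, 15/35, 1
#' @export
normalize_session <- function(records) {
  if (!is.data.frame(records) || is.null(records$S_pm)) {
    stop("`records` must be a data frame with an `S_pm` column")
  }
  if (nrow(records) < 2L) {
    stop("a session needs at least 2 records to normalize")
  }
  if (any(!is.finite(records$S_pm)) || any(records$S_pm < 0)) {
    stop("summed shifts must be finite and non-negative")
  }
  s_min <- min(records$S_pm)
  s_max <- max(records$S_pm)
  # contrast below numerical fit residuals (1e-9 relative) is no contrast:
  # far below any physical stiffness difference the probe can express
  if (s_max - s_min <= 1e-9 * max(s_max, 1)) {
    warning("degenerate session: all summed shifts are equal; assigning relative stiffness 0 to every point")
    records$s_norm <- rep(0, nrow(records))
  } else {
    records$s_norm <- (records$S_pm - s_min) / (s_max - s_min)
  }
  records
}

#' Fit a linear calibration curve for the probe head
#'
#' The probe responds linearly over its working range, both in mean Bragg
#' shift versus indentation depth against a fixed target and in mean Bragg
#' shift versus target Shore A hardness at fixed indentation. This fits that
#' relation by ordinary least squares and records the support over which the
#' line was measured; predictions outside the support are extrapolations and
#' are flagged as such by [predict.calibration_curve()].
#'
#' @param x indentation depth (mm) or Shore A hardness of each measurement;
#'   at least 3 distinct values.
#' @param y mean Bragg wavelength shift at each `x`, pm.
#' @param kind `"indentation-response"` or `"hardness-response"`.
#' @return An object of class `calibration_curve` with fields `kind`, `slope`,
#'   `intercept`, `r2`, `support`.
#' @examples
#' cal <- fit_calibration(0:5 * 0.4, 0:5 * 0.4 * 21,
#'                        kind = "indentation-response")
#' cal$slope  # pm per mm
#' @export
fit_calibration <- function(x, y,
                            kind = c("indentation-response",
                                     "hardness-response")) {
  kind <- match.arg(kind)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  if (length(x) < 3L) {
    stop("calibration requires at least 3 points")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("calibration data must be finite")
  }
  if (length(unique(x)) < 2L) {
    stop("calibration requires distinct x values")
  }
  fit <- stats::lm(y ~ x)
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact lines are fine input
  structure(
    list(kind = kind,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r2 = r2,
         support = range(x)),
    class = "calibration_curve"
  )
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s: shift = %.4g * x + %.4g (r2 = %.4f, support [%g, %g])\n",
              x$kind, x$slope, x$intercept, x$r2, x$support[1], x$support[2]))
  invisible(x)
}

#' Predict from a calibration curve
#'
#' @param object a [fit_calibration()] result.
#' @param newdata numeric vector of x values.
#' @param ... unused.
#' @return A data frame with columns `x`, `shift_pm` and `extrapolated`
#'   (`TRUE` where `x` falls outside the calibration support).
#' @export
predict.calibration_curve <- function(object, newdata, ...) {
  newdata <- as.numeric(newdata)
  data.frame(
    x = newdata,
    shift_pm = object$slope * newdata + object$intercept,
    extrapolated = newdata < object$support[1] | newdata > object$support[2]
  )
}

#' Write a stiffness table
#'
#' @param records a normalized `stiffness_records` data frame.
#' @param path destination CSV file.
#' @return `path`, invisibly.
#' @export
write_stiffness_table <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}
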