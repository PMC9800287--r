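# Visibility-distance modelling and scenario comparison.

records_frame <- function(records) {
  d <- as.data.frame(records)
  if (!all(c("distance", "visibility") %in% names(d)))
    stop("records must have 'distance' and 'visibility' columns")
  d
}

#' Fit the logarithmic visibility-distance model
#'
#' Ordinary least squares of visibility (as a fraction, 0-1) on the natural
#' logarithm of distance: `visibility = intercept + slope * log(distance)`.
#' The cumulative build-up of occluding points with distance makes the decay
#' of visibility approximately logarithmic in forest scenes; the intercept is
#' the modelled visibility fraction at 1 m and the slope the change per
#' log-metre (negative in occluding environments). Invalid (NA) records are
#' dropped.
#'
#' @param records A `visibility_survey`, or a data frame with `distance`
#'   (metres) and `visibility` (percent) columns.
#' @return A `visibility_logfit` model object with `intercept`, `slope`, `r2`
#'   and `n_used`; supports `print`, `summary`, `coef`, `predict`, `fitted`,
#'   `residuals` and `plot`.
#' @examples
#' d <- data.frame(distance = 1:40,
#'                 visibility = pmax(0, 100 * (1 - 0.25 * log(1:40))))
#' fit_log_model(d)
#' @export
fit_log_model <- function(records) {
  d <- records_frame(records)
  d <- d[is.finite(d$visibility) & is.finite(d$distance) & d$distance > 0, ]
  if (nrow(d) < 3L)
    stop("need at least 3 valid records to fit the log model")
  if (length(unique(d$distance)) < 2L)
    stop("singular fit: all records share the same distance")
  vfrac <- d$visibility / 100
  m <- stats::lm(vfrac ~ log(d$distance))
  ss_res <- sum(stats::residuals(m)^2)
  ss_tot <- sum((vfrac - mean(vfrac))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 0
  structure(list(intercept = unname(stats::coef(m)[1]),
                 slope = unname(stats::coef(m)[2]),
                 r2 = r2, n_used = nrow(d),
                 data = data.frame(distance = d$distance, visibility_frac = vfrac)),
            class = "visibility_logfit")
}

#' @export
print.visibility_logfit <- function(x, ...) {
  cat(sprintf("visibility = %.3f %+.3f log(distance)   (fractions; R2 = %.3f, n = %d)\n",
              x$intercept, x$slope, x$r2, x$n_used))
  invisible(x)
}

#' @export
summary.visibility_logfit <- function(object, ...) {
  m <- stats::lm(visibility_frac ~ log(distance), data = object$data)
  s <- summary(m)
  cat("Logarithmic visibility-distance model (visibility as fraction):\n\n")
  stats::printCoefmat(s$coefficients)
  cat(sprintf("\nR-squared: %.4f on %d records\n", object$r2, object$n_used))
  invisible(s)
}

#' @export
coef.visibility_logfit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
predict.visibility_logfit <- function(object, distance = NULL, ...) {
  if (is.null(distance)) distance <- object$data$distance
  object$intercept + object$slope * log(distance)
}

#' @export
fitted.visibility_logfit <- function(object, ...) predict(object)

#' @export
residuals.visibility_logfit <- function(object, ...) {
  object$data$visibility_frac - predict(object)
}

#' @export
plot.visibility_logfit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$distance, 100 * d$visibility_frac, pch = 16,
                 col = grDevices::grey(0.3, alpha = 0.4),
                 xlab = "distance (m)", ylab = "visibility (%)", ...)
  xs <- seq(min(d$distance), max(d$distance), length.out = 200)
  graphics::lines(xs, 100 * predict(x, xs), col = "red3", lwd = 2)
  graphics::legend("topright", bty = "n", legend = sprintf(
    "V = %.3f %+.3f ln(d),  R2 = %.2f", x$intercept, x$slope, x$r2))
  invisible(x)
}

#' Visibility deviation between scenarios
#'
#' Per matched sample, the visibility difference `V_non-normalized -
#' V_normalized` in percentage points: the terrain-induced departure from the
#' purely cumulative occlusion pattern. Positive values mean terrain relief
#' exposes the target (visibility increases); negative values mean the
#' terrain itself occludes it. The per-direction peak (largest absolute
#' deviation) summarises how strongly relief distorts visibility in that
#' direction.
#'
#' @param norm,notnorm `visibility_survey` objects (or record data frames)
#'   from the normalized and non-normalized scenarios, on the same sample
#'   grid and with the same rectangle.
#' @return A `visibility_deviation`: list with `series` (theta, distance,
#'   deviation) and `peaks` (theta, peak_deviation signed at the largest
#'   magnitude, peak_abs).
#' @export
deviation_between <- function(norm, notnorm) {
  a <- records_frame(norm); b <- records_frame(notnorm)
  a <- a[order(a$theta, a$distance), ]
  b <- b[order(b$theta, b$distance), ]
  if (nrow(a) != nrow(b) ||
      any(abs(a$theta - b$theta) > 1e-9) ||
      any(abs(a$distance - b$distance) > 1e-9))
    stop("the two record sets are not on the same (theta, distance) grid")
  if (!is.null(a$n_total) && !is.null(b$n_total) &&
      any(a$n_total != b$n_total, na.rm = TRUE))
    stop("the two record sets use different rectangle rasters")
  series <- data.frame(theta = a$theta, distance = a$distance,
                       deviation = b$visibility - a$visibility)
  peaks <- do.call(rbind, lapply(split(series, series$theta), function(d) {
    dv <- d$deviation[is.finite(d$deviation)]
    pk <- if (length(dv)) dv[which.max(abs(dv))] else NA_real_
    data.frame(theta = d$theta[1], peak_deviation = pk,
               peak_abs = if (length(dv)) max(abs(dv)) else NA_real_)
  }))
  rownames(peaks) <- NULL
  structure(list(series = series, peaks = peaks), class = "visibility_deviation")
}

#' @export
print.visibility_deviation <- function(x, ...) {
  cat(sprintf("<visibility_deviation> %d samples, %d directions\n",
              nrow(x$series), nrow(x$peaks)))
  cat(sprintf("  peak |deviation|: %.2f pp (direction %g deg)\n",
              max(x$peaks$peak_abs, na.rm = TRUE),
              x$peaks$theta[which.max(x$peaks$peak_abs)]))
  invisible(x)
}

#' @export
plot.visibility_deviation <- function(x, theta = NULL, ...) {
  s <- x$series
  if (!is.null(theta)) s <- s[s$theta %in% theta, ]
  graphics::plot(NULL, xlim = range(s$distance),
                 ylim = range(s$deviation, 0, na.rm = TRUE),
                 xlab = "distance (m)", ylab = "visibility deviation (pp)", ...)
  graphics::abline(h = 0, lty = 3)
  for (th in unique(s$theta)) {
    d <- s[s$theta == th, ]
    graphics::lines(d$distance, d$deviation, col = grDevices::grey(0.2, alpha = 0.4))
  }
  invisible(x)
}

#' Monotonicity violation of a visibility sequence
#'
#' In the normalized scenario, occlusion is strictly cumulative: a target
#' farther along a direction can only be at most as visible as a nearer one.
#' This statistic measures any excess over the running minimum,
#' `excess(i) = V(i) - min_(j <= i) V(j)`; an all-zero result certifies a
#' non-increasing sequence, and nonzero values detect terrain-induced
#' deviation within a single scenario.
#'
#' @param records A `visibility_survey` or record data frame; may contain
#'   several directions (each is processed separately, ordered by distance).
#' @return Data frame `theta`, `distance`, `excess` (percentage points).
#' @export
monotonicity_violation <- function(records) {
  d <- records_frame(records)
  if (is.null(d$theta)) d$theta <- 0
  out <- do.call(rbind, lapply(split(d, d$theta), function(g) {
    g <- g[order(g$distance), ]
    v <- g$visibility
    data.frame(theta = g$theta, distance = g$distance,
               excess = v - cummin(v))
  }))
  rownames(out) <- NULL
  out
}
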