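#' Digitization accuracy: RMSE, bias and percent accuracy
#'
#' Summarizes calibration measurements of a standard object with known
#' segment lengths: `RMSE = sqrt(mean((x - y)^2))` over digitized lengths
#' x and true lengths y; bias as the mean difference `mean(x - y)` (the
#' variant squaring the terms, a difference of mean squares, is available
#' via `as_typeset = TRUE`); and per known length L the accuracy
#' `1 - RMSE_L / L`. If transmitter distances are present, the metrics
#' are also banded by distance (defaults: <100, 100-150, >150 cm).
#'
#' @param records data.frame with columns `digitized`, `true` (cm) and
#'   optionally `distance` (cm to the transmitter).
#' @param bands distance band boundaries, cm.
#' @param as_typeset use the difference-of-mean-squares bias variant.
#' @return list of class `accuracy_report`: `rmse`, `bias`,
#'   `accuracy` (data.frame per true length), `by_band` (or `NULL`), `n`.
#' @export
rmse_bias_accuracy <- function(records, bands = c(100, 150),
                               as_typeset = FALSE) {
  if (!nrow(records)) stop("empty calibration input")
  x <- records$digitized; y <- records$true
  stopifnot(all(is.finite(x)), all(is.finite(y)), all(y > 0))
  rmse <- sqrt(mean((x - y)^2))
  bias <- if (as_typeset) mean(x^2) - mean(y^2) else mean(x - y)
  acc <- do.call(rbind, lapply(sort(unique(y)), function(L) {
    sel <- y == L
    data.frame(true_length = L,
               rmse = sqrt(mean((x[sel] - y[sel])^2)),
               accuracy = 1 - sqrt(mean((x[sel] - y[sel])^2)) / L,
               n = sum(sel))
  }))
  by_band <- NULL
  if ("distance" %in% names(records)) {
    bb <- c(0, bands, Inf)
    lab <- c(paste0("<", bands[1]),
             if (length(bands) > 1)
               paste(bands[-length(bands)], bands[-1], sep = "-"),
             paste0(">", bands[length(bands)]))
    grp <- cut(records$distance, bb, labels = lab, right = TRUE)
    by_band <- do.call(rbind, lapply(levels(grp), function(g) {
      sel <- grp == g
      if (!any(sel)) return(NULL)
      data.frame(band = g, n = sum(sel),
                 rmse = sqrt(mean((x[sel] - y[sel])^2)),
                 bias = mean(x[sel] - y[sel]))
    }))
  }
  structure(list(rmse = rmse, bias = bias, accuracy = acc,
                 by_band = by_band, n = length(x)),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("digitization accuracy (n = %d): RMSE %.3f cm, bias %.3f cm\n",
              x$n, x$rmse, x$bias))
  print(x$accuracy, row.names = FALSE)
  if (!is.null(x$by_band)) print(x$by_band, row.names = FALSE)
  invisible(x)
}

#' Double-point deviation statistics
#'
#' Operator-induced error of the double-digitized branch points: the
#' Euclidean distance between the two recordings of each branch point,
#' its mean, per-distance-band means, and the ordinary least-squares
#' trend of deviation on transmitter distance with its coefficient of
#' determination.
#'
#' @param pairs data.frame with columns `x1,y1,z1,x2,y2,z2` (cm) and
#'   optionally `distance` (cm).
#' @param bands distance band boundaries, cm.
#' @return list of class `double_point_report`: `mean_deviation`,
#'   `deviations`, `by_band`, `r_squared`, `slope` (the last two `NULL`
#'   without distances or with < 2 pairs).
#' @export
double_point_stats <- function(pairs, bands = c(100, 150)) {
  if (!nrow(pairs)) stop("empty double-point input")
  dev <- sqrt((pairs$x1 - pairs$x2)^2 + (pairs$y1 - pairs$y2)^2 +
                (pairs$z1 - pairs$z2)^2)
  by_band <- NULL; r2 <- NULL; slope <- NULL
  if ("distance" %in% names(pairs)) {
    bb <- c(0, bands, Inf)
    lab <- c(paste0("<", bands[1]),
             if (length(bands) > 1)
               paste(bands[-length(bands)], bands[-1], sep = "-"),
             paste0(">", bands[length(bands)]))
    grp <- cut(pairs$distance, bb, labels = lab, right = TRUE)
    by_band <- do.call(rbind, lapply(levels(grp), function(g) {
      sel <- grp == g
      if (!any(sel)) return(NULL)
      data.frame(band = g, n = sum(sel), mean_deviation = mean(dev[sel]))
    }))
    if (nrow(pairs) >= 2L && stats::var(pairs$distance) > 0) {
      fit <- stats::lm(dev ~ pairs$distance)
      r2 <- summary(fit)$r.squared
      slope <- stats::coef(fit)[[2]]
    }
  }
  structure(list(mean_deviation = mean(dev), deviations = dev,
                 by_band = by_band, r_squared = r2, slope = slope),
            class = "double_point_report")
}

#' @export
print.double_point_report <- function(x, ...) {
  cat(sprintf("double points (n = %d): mean deviation %.3f cm",
              length(x$deviations), x$mean_deviation))
  if (!is.null(x$r_squared)) cat(sprintf(", R^2 vs distance %.4f", x$r_squared))
  cat("\n")
  invisible(x)
}
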