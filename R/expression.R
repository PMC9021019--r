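#' Normalize eGFP fluorescence intensities
#'
#' Per-line mean intensities are background-corrected by subtracting the
#' intensity of non-fluorescent control cells, divided by the average
#' corrected intensity of all lines whose enhancer inserted within a
#' window centred on the promoter (so promoter-proximal expression reads
#' as ~1), and multiplied by a common factor. Negative post-subtraction
#' values are clipped to zero with a warning.
#'
#' @param records data.frame with columns `id`, `coord` (insertion
#'   coordinate, bp; `NA` allowed for promoter-only lines) and one column
#'   per measurement day (matched by `intensity_cols`).
#' @param promoter_coord promoter coordinate (bp).
#' @param background mean intensity of background (non-eGFP) cells,
#'   scalar or per-line vector.
#' @param window width of the promoter-centred window (bp, default 40 kb).
#' @param common_factor final multiplicative factor (default 1).
#' @param intensity_cols names (or indices) of the replicate intensity
#'   columns; defaults to all numeric columns except `coord`.
#' @return The input data.frame with added columns `raw_mean`, `raw_sd`,
#'   `norm_mean`, `norm_sd` and `n_rep`; attribute `window_average` holds
#'   the normalizer.
#' @export
normalize_egfp <- function(records, promoter_coord, background = 0,
                           window = 40e3, common_factor = 1,
                           intensity_cols = NULL) {
  stopifnot(is.data.frame(records), "coord" %in% names(records))
  if (is.null(intensity_cols)) {
    num <- vapply(records, is.numeric, logical(1))
    intensity_cols <- setdiff(names(records)[num], c("coord"))
  }
  if (length(intensity_cols) < 1) stop("no intensity columns found")
  mat <- as.matrix(records[, intensity_cols, drop = FALSE])
  corrected <- mat - background
  if (any(corrected < 0)) {
    warning("negative background-corrected intensities clipped to 0")
    corrected[corrected < 0] <- 0
  }
  raw_mean <- rowMeans(corrected)
  raw_sd <- apply(corrected, 1, stats::sd)
  inside <- !is.na(records$coord) &
    abs(records$coord - promoter_coord) <= window / 2
  if (!any(inside))
    stop("no lines inside the ", window / 1e3, " kb promoter window")
  wavg <- mean(raw_mean[inside])
  if (wavg <= 0) stop("window average is not positive")
  records$raw_mean <- raw_mean
  records$raw_sd <- raw_sd
  records$norm_mean <- raw_mean / wavg * common_factor
  records$norm_sd <- raw_sd / wavg * common_factor
  records$n_rep <- ncol(mat)
  attr(records, "window_average") <- wavg
  records
}

#' Calibrate mean mRNA numbers against eGFP intensity
#'
#' Ordinary least-squares line predicting the mean number of mRNAs per
#' cell (from smFISH) from the mean eGFP fluorescence intensity (from flow
#' cytometry), fitted on the lines measured with both assays.
#'
#' @param intensity per-line mean eGFP intensities.
#' @param fish_mean per-line mean mRNA counts from smFISH.
#' @return Object of class `mrna_calibration`: `slope`, `intercept`, `r2`,
#'   `n`, and the underlying `lm` fit. Use [predict_mrna()] to apply it.
#' @export
calibrate_mrna <- function(intensity, fish_mean) {
  stopifnot(length(intensity) == length(fish_mean))
  if (length(intensity) < 2) stop("need at least 2 paired points")
  if (stats::sd(intensity) == 0)
    stop("degenerate fit: intensities are constant")
  fit <- stats::lm(fish_mean ~ intensity)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = summary(fit)$r.squared,
                 n = length(intensity), lm = fit),
            class = "mrna_calibration")
}

#' @export
print.mrna_calibration <- function(x, ...) {
  cat(sprintf(
    "mRNA calibration: mRNA = %.4g + %.4g * intensity (R^2 = %.4f, n = %d)\n",
    x$intercept, x$slope, x$r2, x$n))
  invisible(x)
}

#' Predict mean mRNA numbers from intensities
#' @param cal a [calibrate_mrna()] model.
#' @param intensity intensities to convert.
#' @return Predicted mean mRNA counts.
#' @export
predict_mrna <- function(cal, intensity) {
  stopifnot(inherits(cal, "mrna_calibration"))
  cal$intercept + cal$slope * intensity
}

#' Binned trend of expression along the genome
#'
#' Averages per-line values within equally spaced genomic bins and fits a
#' smoothing spline (generalized cross-validation) through the nonempty
#' bin means; with fewer than 4 nonempty bins a piecewise-linear
#' interpolant is used instead.
#'
#' @param positions per-line genomic coordinates (bp).
#' @param values per-line values (e.g. normalized expression).
#' @param region `c(start, end)` of the binned region; defaults to the
#'   data range.
#' @param binsize bin width in bp (default 20 kb).
#' @return Object of class `trend_curve`: data.frame `bins` (`center`,
#'   `mean`, `sd`, `n`), the interpolant, and `binsize`. Evaluate with
#'   [predict_trend()].
#' @export
bin_trend <- function(positions, values, region = range(positions),
                      binsize = 20e3) {
  stopifnot(length(positions) == length(values))
  ok <- !is.na(positions) & !is.na(values)
  positions <- positions[ok]; values <- values[ok]
  if (any(positions < region[1] | positions > region[2]))
    stop("positions outside the declared region")
  breaks <- seq(region[1], region[2] + binsize, by = binsize)
  idx <- findInterval(positions, breaks, rightmost.closed = TRUE)
  center <- breaks[-length(breaks)] + binsize / 2
  mean_v <- tapply(values, factor(idx, levels = seq_along(center)), mean)
  sd_v <- tapply(values, factor(idx, levels = seq_along(center)), stats::sd)
  n_v <- tapply(values, factor(idx, levels = seq_along(center)), length)
  bins <- data.frame(center = center, mean = as.numeric(mean_v),
                     sd = as.numeric(sd_v),
                     n = ifelse(is.na(n_v), 0L, as.integer(n_v)))
  nonempty <- bins[bins$n > 0, ]
  if (nrow(nonempty) >= 4) {
    sp <- stats::smooth.spline(nonempty$center, nonempty$mean, cv = FALSE)
    interp <- function(x) stats::predict(sp, x)$y
    kind <- "smoothing_spline"
  } else if (nrow(nonempty) >= 2) {
    interp <- stats::approxfun(nonempty$center, nonempty$mean, rule = 2)
    kind <- "piecewise_linear"
  } else {
    v <- nonempty$mean[1]
    interp <- function(x) rep(v, length(x))
    kind <- "constant"
  }
  structure(list(bins = bins, interpolant = interp, kind = kind,
                 binsize = binsize, region = region),
            class = "trend_curve")
}

#' Evaluate a trend curve
#' @param trend a [bin_trend()] object.
#' @param x coordinates at which to evaluate the interpolant.
#' @return Numeric vector of trend values.
#' @export
predict_trend <- function(trend, x) {
  stopifnot(inherits(trend, "trend_curve"))
  trend$interpolant(x)
}

#' Per-line coefficient of variation versus contact probability
#'
#' Computes sd/mean of each line's per-cell count distribution and pairs it
#' with the line's contact probability, together with the Spearman rank
#' correlation between the two. Zero-mean lines are dropped with a warning.
#'
#' @param fish a [fish_dataset()].
#' @return data.frame (`id`, `p_c`, `mean`, `cv`) with attributes `rho`
#'   and `p_value` from the rank-correlation test.
#' @export
cv_curve <- function(fish) {
  stopifnot(inherits(fish, "fish_dataset"))
  rows <- lapply(seq_along(fish$id), function(i) {
    h <- fish$hist[[i]]
    p <- h / sum(h)
    mo <- pmf_moments(p)
    data.frame(id = fish$id[i], p_c = fish$p_c[i], mean = mo[["mean"]],
               cv = mo[["cv"]])
  })
  out <- do.call(rbind, rows)
  if (any(!is.finite(out$cv))) {
    warning("lines with zero mean excluded from the CV curve")
    out <- out[is.finite(out$cv), ]
  }
  if (nrow(out) >= 2 && stats::sd(out$cv) > 0 && stats::sd(out$p_c) > 0) {
    ct <- suppressWarnings(
      stats::cor.test(out$cv, out$p_c, method = "spearman"))
    attr(out, "rho") <- unname(ct$estimate)
    attr(out, "p_value") <- ct$p.value
  } else {
    attr(out, "rho") <- 0
    attr(out, "p_value") <- NA_real_
  }
  out
}

#' Percentage fold change between two trend curves
#'
#' `100 * (trend_b - trend_a) / trend_a` evaluated on a genomic grid;
#' points where the reference trend is not positive are returned as `NA`.
#'
#' @param trend_a reference [bin_trend()] curve.
#' @param trend_b comparison curve.
#' @param grid coordinates at which to evaluate (defaults to the overlap of
#'   the two regions at 1 kb spacing).
#' @return data.frame with columns `position` and `pct_change`.
#' @export
fold_change_curve <- function(trend_a, trend_b, grid = NULL) {
  stopifnot(inherits(trend_a, "trend_curve"),
            inherits(trend_b, "trend_curve"))
  if (is.null(grid)) {
    lo <- max(trend_a$region[1], trend_b$region[1])
    hi <- min(trend_a$region[2], trend_b$region[2])
    if (lo >= hi) stop("trend curves have no overlapping support")
    grid <- seq(lo, hi, by = 1e3)
  }
  a <- predict_trend(trend_a, grid)
  b <- predict_trend(trend_b, grid)
  pct <- 100 * (b - a) / a
  pct[a <= 0] <- NA
  data.frame(position = grid, pct_change = pct)
}
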