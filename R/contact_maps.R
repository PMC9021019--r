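#' Binned symmetric contact matrix
#'
#' Container for capture-C style binned contact counts over one genomic
#' region. Coordinates are 0-based half-open internally; bin `i` covers
#' `[start + (i-1)*binsize, start + i*binsize)`.
#'
#' @param counts symmetric numeric matrix of contact counts.
#' @param chrom chromosome name.
#' @param start region start (bp, 0-based).
#' @param binsize bin width in bp (default 6400).
#' @param mask optional logical vector marking filtered-out bins.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(counts, chrom, start, binsize = 6400L,
                           mask = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  if (max(abs(counts - t(counts)), 0) > 1e-9 * max(abs(counts), 1))
    stop("counts must be symmetric")
  if (any(counts < 0)) stop("counts must be non-negative")
  n <- nrow(counts)
  if (is.null(mask)) mask <- rep(FALSE, n)
  stopifnot(length(mask) == n)
  structure(list(counts = counts, chrom = chrom, start = as.numeric(start),
                 end = as.numeric(start) + n * binsize,
                 binsize = as.numeric(binsize), mask = mask),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("Contact matrix: %s:%d-%d, %d bins of %d bp (%d masked)\n",
              x$chrom, x$start, x$end, nrow(x$counts), x$binsize,
              sum(x$mask)))
  invisible(x)
}

#' Bin centers of a contact matrix
#' @param cm a [contact_matrix()].
#' @return Numeric vector of bin-center coordinates (bp).
#' @export
bin_centers <- function(cm) {
  cm$start + (seq_len(nrow(cm$counts)) - 0.5) * cm$binsize
}

#' Iterative correction (matrix balancing)
#'
#' Classic iterative correction: multiplicative per-bin factors are found
#' so that every unmasked row sums to the same total. Bins whose raw sum is
#' zero (or below `min_sum`) are masked and excluded.
#'
#' @param cm a [contact_matrix()].
#' @param tol convergence tolerance on the relative spread of row sums.
#' @param max_iter maximum iterations (error with the residual beyond it).
#' @param min_sum bins with raw marginal below this are masked.
#' @return Balanced [contact_matrix()] with attribute `biases`.
#' @export
ice_balance <- function(cm, tol = 1e-8, max_iter = 500L, min_sum = 0) {
  stopifnot(inherits(cm, "contact_matrix"))
  w <- cm$counts
  mask <- cm$mask | rowSums(w) <= min_sum
  w[mask, ] <- 0; w[, mask] <- 0
  bias <- rep(1, nrow(w))
  ok <- !mask
  if (!any(ok)) stop("all bins masked")
  for (it in seq_len(max_iter)) {
    s <- rowSums(w)[ok]
    s <- s / mean(s)
    resid <- max(abs(s - 1))
    if (resid < tol) {
      out <- contact_matrix(w, cm$chrom, cm$start, cm$binsize, mask)
      attr(out, "biases") <- bias
      attr(out, "iterations") <- it
      return(out)
    }
    d <- rep(1, nrow(w)); d[ok] <- s
    bias <- bias * d
    w <- w / outer(d, d)
  }
  stop("iterative correction did not converge in ", max_iter,
       " iterations (residual ", format(resid), ")")
}

#' Mean and s.d. of contacts per genomic distance
#'
#' Region-wide average and standard deviation of contact values at each
#' bin-distance `|i - j|`, over unmasked unique pairs (upper triangle).
#' Distances observed in fewer than two pairs get `NA` standard deviation
#' and are flagged.
#'
#' @param cm a [contact_matrix()] (raw or balanced).
#' @return data.frame of class `expected_curve` with columns `distance`
#'   (bins), `bp` (genomic distance), `exp`, `stdev`, `n`.
#' @export
expected_by_distance <- function(cm) {
  stopifnot(inherits(cm, "contact_matrix"))
  n <- nrow(cm$counts)
  ok <- outer(!cm$mask, !cm$mask, "&") & upper.tri(cm$counts, diag = TRUE)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  vals <- cm$counts[ok]
  dd <- d[ok]
  agg_m <- tapply(vals, dd, mean)
  agg_s <- tapply(vals, dd, stats::sd)
  agg_n <- tapply(vals, dd, length)
  dist <- as.integer(names(agg_m))
  out <- data.frame(distance = dist, bp = dist * cm$binsize,
                    exp = as.numeric(agg_m), stdev = as.numeric(agg_s),
                    n = as.integer(agg_n))
  out$stdev[out$n < 2] <- NA_real_
  class(out) <- c("expected_curve", "data.frame")
  out
}

#' Extract a viewpoint (anchor) profile from a contact matrix
#'
#' The matrix row at the bin containing `anchor`, as a one-dimensional
#' contact profile.
#'
#' @param cm a [contact_matrix()].
#' @param anchor genomic coordinate of the viewpoint (bp).
#' @return Object of class `viewpoint_profile`: list with `anchor_bin`,
#'   `anchor`, `position` (bin centers), `value`, `scale`
#'   (`"counts"`) and the bin geometry.
#' @export
viewpoint_profile <- function(cm, anchor) {
  stopifnot(inherits(cm, "contact_matrix"))
  i <- floor((anchor - cm$start) / cm$binsize) + 1
  if (i < 1 || i > nrow(cm$counts)) stop("anchor outside the region")
  structure(list(anchor_bin = i, anchor = anchor,
                 position = bin_centers(cm), value = cm$counts[i, ],
                 scale = "counts", chrom = cm$chrom, start = cm$start,
                 binsize = cm$binsize, mask = cm$mask),
            class = "viewpoint_profile")
}

#' Convert a viewpoint profile from counts to contact probabilities
#'
#' Divides the profile by a reference value so that contacts immediately
#' adjacent to the viewpoint read as probability ~1, then clips to
#' \[0, 1\]. The default reference is the mean of the two bins adjacent to
#' the anchor; the rule used is recorded in the result. This normalization
#' is an operational convention: short-range contacts are taken to be
#' near-certain.
#'
#' @param vp a [viewpoint_profile()] on the counts scale.
#' @param reference `"adjacent"` (mean of the two anchor-adjacent bins) or
#'   a positive number used directly.
#' @return The profile with `value` on the probability scale and
#'   `scale = "probability"`.
#' @export
counts_to_probability <- function(vp, reference = "adjacent") {
  stopifnot(inherits(vp, "viewpoint_profile"))
  if (identical(reference, "adjacent")) {
    i <- vp$anchor_bin
    adj <- c(if (i > 1) vp$value[i - 1], if (i < length(vp$value))
      vp$value[i + 1])
    ref <- mean(adj)
  } else {
    ref <- as.numeric(reference)
  }
  if (!is.finite(ref) || ref <= 0) stop("reference value is zero")
  vp$value <- pmin(vp$value / ref, 1)
  vp$scale <- "probability"
  vp$reference <- ref
  vp$reference_rule <- if (identical(reference, "adjacent")) "adjacent"
    else "fixed"
  vp
}

#' Z-score map relative to the distance-decay expectation
#'
#' Entrywise `(obs - exp) / stdev` where `exp` and `stdev` come from the
#' per-distance [expected_by_distance()] curve. Entries at distances with
#' undefined standard deviation (or zero) are `NA`.
#'
#' @param cm a [contact_matrix()].
#' @param e an [expected_by_distance()] curve (computed from `cm` if
#'   missing).
#' @return Numeric matrix of Z-scores.
#' @export
zscore_map <- function(cm, e = expected_by_distance(cm)) {
  n <- nrow(cm$counts)
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  expm <- matrix(e$exp[match(d, e$distance)], n, n)
  sdm <- matrix(e$stdev[match(d, e$distance)], n, n)
  sdm[!is.na(sdm) & sdm == 0] <- NA
  z <- (cm$counts - expm) / sdm
  z[cm$mask, ] <- NA; z[, cm$mask] <- NA
  z
}

#' Noise filter for contact-map entries
#'
#' Flags entries treated as noise: (i) bins with no reported interactions,
#' (ii) per-distance outliers by the interquartile rule
#' (outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` of the values at the same
#' genomic distance) and (iii) "singletons", the top 0.1 percentile of
#' Z-scores.
#'
#' @param cm a [contact_matrix()].
#' @param e expected curve (recomputed if missing).
#' @param iqr_k multiplier of the IQR rule (default 1.5).
#' @param singleton_quantile upper Z-score quantile flagged as singletons
#'   (default 0.999, i.e. the top 0.1 percentile).
#' @return Logical matrix, `TRUE` where the entry is filtered out.
#' @export
filter_noise <- function(cm, e = expected_by_distance(cm), iqr_k = 1.5,
                         singleton_quantile = 0.999) {
  n <- nrow(cm$counts)
  mask <- matrix(FALSE, n, n)
  zero_bin <- rowSums(cm$counts) == 0 | cm$mask
  mask[zero_bin, ] <- TRUE; mask[, zero_bin] <- TRUE
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  for (dist in unique(as.vector(d))) {
    sel <- d == dist & !mask
    v <- cm$counts[sel]
    if (length(v) < 4) next
    q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    bad <- cm$counts < q[1] - iqr_k * iqr | cm$counts > q[2] + iqr_k * iqr
    mask[sel & bad] <- TRUE
  }
  z <- zscore_map(cm, e)
  zv <- z[!is.na(z)]
  if (length(zv) > 0) {
    thr <- stats::quantile(zv, singleton_quantile, names = FALSE)
    mask[!is.na(z) & z > thr] <- TRUE
  }
  mask
}

# effective genomic distance (in bins) between bin pairs, correcting for an
# inserted ectopic interval: pairs spanning the insertion are closer in the
# reference genome by the insertion width
.effective_distance <- function(cm, insertion = NULL) {
  n <- nrow(cm$counts)
  centers <- bin_centers(cm)
  d <- abs(outer(centers, centers, "-"))
  if (!is.null(insertion)) {
    width <- insertion[2] - insertion[1]
    side <- centers > mean(insertion)
    spans <- outer(side, side, "!=")
    d[spans] <- pmax(d[spans] - width, cm$binsize / 2)
  }
  round(d / cm$binsize)
}

# distance normalization: each entry divided by the distance-decay SHAPE at
# its (insertion-corrected) genomic distance. The normalization factor has
# unit mean over the matrix, so overall sequencing depth is preserved and
# still visible in ratio maps.
.distance_normalize <- function(cm, insertion = NULL) {
  e <- expected_by_distance(cm)
  d <- .effective_distance(cm, insertion)
  d[d > max(e$distance)] <- max(e$distance)
  expm <- matrix(e$exp[match(d, e$distance)], nrow(d), nrow(d))
  expm <- expm / mean(expm[!is.na(expm) & expm > 0])
  out <- cm$counts / expm
  out[expm == 0 | is.na(expm)] <- NA
  out
}

# mean filter over a (2w+1) x (2w+1) window, ignoring NA / masked entries
.bilinear_smooth <- function(m, w) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(NA_real_, n1, n2)
  for (i in seq_len(n1)) {
    ri <- max(1, i - w):min(n1, i + w)
    for (j in seq_len(n2)) {
      rj <- max(1, j - w):min(n2, j + w)
      v <- m[ri, rj]
      if (all(is.na(v))) next
      out[i, j] <- mean(v, na.rm = TRUE)
    }
  }
  out
}

#' Distance-corrected differential (ratio) map
#'
#' Ratio of two distance-normalized, noise-filtered contact maps, smoothed
#' with a bilinear mean filter. Each map is first divided by its own
#' per-distance expectation (with genomic distances corrected for an
#' inserted ectopic interval in map `a`, if given); entries flagged by
#' [filter_noise()] in either map are masked ("grey pixels"); the ratio
#' `a/b` is then smoothed over a `(2*window+1)`-bin square window that
#' ignores masked entries.
#'
#' @param a,b [contact_matrix()] objects with identical geometry.
#' @param insertion optional `c(start, end)` of the ectopic insertion
#'   present in `a` but absent from `b`.
#' @param window smoothing half-window in bins (default 2).
#' @param smooth apply the smoothing filter (default `TRUE`).
#' @return Object of class `differential_map`: list with `ratio` (smoothed
#'   matrix), `raw_ratio`, `mask`, `window`, `insertion`.
#' @export
differential_map <- function(a, b, insertion = NULL, window = 2L,
                             smooth = TRUE) {
  stopifnot(inherits(a, "contact_matrix"), inherits(b, "contact_matrix"))
  if (nrow(a$counts) != nrow(b$counts) || a$binsize != b$binsize)
    stop("incompatible matrix geometries")
  na <- .distance_normalize(a, insertion)
  nb <- .distance_normalize(b)
  mask <- filter_noise(a) | filter_noise(b)
  ratio <- na / nb
  ratio[mask | !is.finite(ratio)] <- NA
  sm <- if (smooth) .bilinear_smooth(ratio, window) else ratio
  structure(list(ratio = sm, raw_ratio = ratio, mask = mask,
                 window = window, insertion = insertion,
                 chrom = a$chrom, start = a$start, binsize = a$binsize),
            class = "differential_map")
}

#' Contact-probability drop across a TAD boundary
#'
#' Fold change of the mean viewpoint contact probability over `flank` bins
#' immediately inside versus immediately outside a boundary.
#'
#' @param vp a [viewpoint_profile()] on the probability scale.
#' @param boundary boundary coordinate (bp).
#' @param flank number of bins averaged on each side (default 3).
#' @return Fold change (inside / outside). `Inf` with a warning when the
#'   outside mean is zero.
#' @export
boundary_drop <- function(vp, boundary, flank = 3L) {
  stopifnot(inherits(vp, "viewpoint_profile"), flank >= 1)
  if (vp$scale != "probability")
    stop("convert the profile to probabilities first")
  # bins are assigned to a side by their centers
  b <- floor((boundary - vp$start) / vp$binsize + 0.5)
  nb <- length(vp$value)
  if (b < 1 || b >= nb) stop("boundary outside the profile")
  # bins <= b lie left of the boundary; "inside" is the anchor's side
  if (vp$anchor_bin <= b) {
    inside <- max(1, b - flank + 1):b
    outside <- (b + 1):min(nb, b + flank)
  } else {
    inside <- (b + 1):min(nb, b + flank)
    outside <- max(1, b - flank + 1):b
  }
  m_in <- mean(vp$value[inside])
  m_out <- mean(vp$value[outside])
  if (m_out == 0) {
    warning("outside mean is zero; fold change is infinite")
    return(Inf)
  }
  m_in / m_out
}

# ---- plain-text I/O ------------------------------------------------------

#' Write / read a contact matrix as dense TSV
#'
#' Dense tab-separated matrix preceded by a header line
#' `#chrom<TAB>start<TAB>end<TAB>binsize`.
#'
#' @param cm a [contact_matrix()].
#' @param path output file.
#' @return `write_contact_matrix`: the path, invisibly.
#'   `read_contact_matrix`: a [contact_matrix()].
#' @export
write_contact_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "contact_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#%s\t%d\t%d\t%d", cm$chrom, cm$start, cm$end,
                     cm$binsize), con)
  utils::write.table(cm$counts, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_matrix
#' @export
read_contact_matrix <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "#")) stop("missing matrix header line")
  f <- strsplit(sub("^#", "", header), "\t")[[1]]
  counts <- as.matrix(utils::read.table(path, sep = "\t", skip = 1))
  dimnames(counts) <- NULL
  contact_matrix(counts, f[1], as.numeric(f[2]),
                 binsize = as.numeric(f[4]))
}

#' Write / read a contact matrix as triplet text
#'
#' Sparse text format: header line `#chrom<TAB>start<TAB>end<TAB>binsize`,
#' then one `bin_i<TAB>bin_j<TAB>count` row per nonzero upper-triangle
#' entry (1-based bin indices).
#'
#' @inheritParams write_contact_matrix
#' @return `write_contact_triplets`: the path, invisibly.
#'   `read_contact_triplets`: a [contact_matrix()].
#' @export
write_contact_triplets <- function(cm, path) {
  stopifnot(inherits(cm, "contact_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#%s\t%d\t%d\t%d", cm$chrom, cm$start, cm$end,
                     cm$binsize), con)
  idx <- which(upper.tri(cm$counts, diag = TRUE) & cm$counts != 0,
               arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2],
                   count = cm$counts[idx])
  utils::write.table(df[order(df$i, df$j), ], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_triplets
#' @export
read_contact_triplets <- function(path) {
  header <- readLines(path, n = 1)
  if (!startsWith(header, "#")) stop("missing matrix header line")
  f <- strsplit(sub("^#", "", header), "\t")[[1]]
  start <- as.numeric(f[2]); end <- as.numeric(f[3])
  binsize <- as.numeric(f[4])
  nb <- round((end - start) / binsize)
  df <- utils::read.table(path, sep = "\t", skip = 1,
                          col.names = c("i", "j", "count"))
  m <- matrix(0, nb, nb)
  m[cbind(df$i, df$j)] <- df$count
  m[cbind(df$j, df$i)] <- df$count
  contact_matrix(m, f[1], start, binsize = binsize)
}

#' Write a viewpoint profile as bedGraph
#'
#' @param vp a [viewpoint_profile()].
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_profile_bedgraph <- function(vp, path) {
  stopifnot(inherits(vp, "viewpoint_profile"))
  s <- vp$start + (seq_along(vp$value) - 1) * vp$binsize
  df <- data.frame(vp$chrom, as.integer(s), as.integer(s + vp$binsize),
                   vp$value)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write genomic intervals as BED
#'
#' @param df data.frame with columns `chrom`, `start`, `end` and optional
#'   `name`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_bed <- function(df, path) {
  cols <- df[, intersect(c("chrom", "start", "end", "name"), names(df))]
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' @param path BED file (3+ columns).
#' @return data.frame with `chrom`, `start`, `end` (+ `name` when present).
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "name"
  df
}
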