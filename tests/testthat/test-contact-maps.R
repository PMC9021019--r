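# deterministic toy matrix with power-law decay
toy_matrix <- function(n = 30, scale = 100, alpha = 0.8, start = 0,
                       binsize = 10) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  counts <- scale * pmax(d, 0.5)^(-alpha)
  contact_matrix(counts, "chrT", start, binsize)
}

test_that("iterative correction equalizes row sums and masks empty bins", {
  # already balanced (equal row sums): unchanged up to a global scale
  m0 <- matrix(1, 3, 3); diag(m0) <- 0
  cm <- contact_matrix(m0, "c", 0, 10)
  bal <- ice_balance(cm)
  r <- bal$counts / cm$counts
  expect_lt(diff(range(r[cm$counts > 0])), 1e-6)
  # heavy row becomes equal within tolerance
  m <- matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3)
  m[1, ] <- m[1, ] * 10; m[, 1] <- m[, 1] * 10; m[1, 1] <- 0
  bal2 <- ice_balance(contact_matrix(m, "c", 0, 10), tol = 1e-10)
  rs <- rowSums(bal2$counts)
  expect_lt(diff(range(rs)) / mean(rs), 1e-8)
  expect_lt(max(abs(bal2$counts - t(bal2$counts))), 1e-9)
  # an all-zero row is masked and excluded
  m3 <- matrix(1, 4, 4); diag(m3) <- 0; m3[4, ] <- 0; m3[, 4] <- 0
  bal3 <- ice_balance(contact_matrix(m3, "c", 0, 10))
  expect_true(bal3$mask[4])
  expect_false(any(bal3$mask[1:3]))
})

test_that("expected-by-distance matches brute-force diagonal statistics", {
  cm <- contact_matrix(matrix(5, 4, 4), "c", 0, 10)
  e <- expected_by_distance(cm)
  expect_true(all(e$exp == 5))
  expect_true(all(e$stdev[e$n >= 2] == 0))
  m <- matrix(c(1, 2, 3, 4,
                2, 5, 6, 7,
                3, 6, 8, 9,
                4, 7, 9, 10), 4)
  e2 <- expected_by_distance(contact_matrix(m, "c", 0, 10))
  expect_equal(e2$exp[e2$distance == 1], mean(c(2, 6, 9)))
  expect_equal(e2$n[e2$distance == 1], 3L)
  expect_equal(e2$exp[e2$distance == 3], 4)
  expect_true(is.na(e2$stdev[e2$distance == 3]))  # single pair, flagged
})

test_that("log-log slope of a sampled power-law matrix recovers the exponent", {
  set.seed(4)
  lam <- toy_matrix(n = 120, scale = 800, alpha = 0.8)$counts
  up <- upper.tri(lam, diag = TRUE)
  counts <- matrix(0, nrow(lam), ncol(lam))
  counts[up] <- rpois(sum(up), lam[up])
  counts <- counts + t(counts) - diag(diag(counts))
  cm <- contact_matrix(counts, "chrT", 0, 10)
  e <- expected_by_distance(cm)
  e <- e[e$distance >= 1 & e$distance <= 60, ]
  slope <- coef(lm(log(exp) ~ log(distance), data = e))[2]
  expect_equal(unname(slope), -0.8, tolerance = 0.05)
})

test_that("count-to-probability conversion anchors to the adjacent bins", {
  cm <- toy_matrix(n = 40)
  vp <- viewpoint_profile(cm, anchor = 200)
  pr <- counts_to_probability(vp)
  i <- pr$anchor_bin
  ref <- mean(vp$value[c(i - 1, i + 1)])
  expect_equal(pr$value[i - 1] * ref, vp$value[i - 1])
  expect_true(all(pr$value <= 1))
  expect_equal(counts_to_probability(vp, reference = vp$value[5])$value[5], 1)
  vp0 <- vp; vp0$value[] <- 0
  expect_error(counts_to_probability(vp0), "zero")
})

test_that("Z-scores match brute-force recomputation", {
  set.seed(8)
  m <- matrix(rpois(25, 20), 5); m <- m + t(m)
  cm <- contact_matrix(m, "c", 0, 10)
  e <- expected_by_distance(cm)
  z <- zscore_map(cm, e)
  for (i in 1:5) for (j in 1:5) {
    d <- abs(i - j)
    ex <- e$exp[e$distance == d]; sd_ <- e$stdev[e$distance == d]
    want <- if (is.na(sd_) || sd_ == 0) NA_real_ else (m[i, j] - ex) / sd_
    expect_equal(z[i, j], want)
  }
  # obs = exp everywhere -> all zeros at defined entries
  cm2 <- toy_matrix(10)
  z2 <- zscore_map(cm2)
  expect_true(all(is.na(z2) | abs(z2) < 1e-12))
})

test_that("noise filter flags zero bins, IQR outliers and Z singletons", {
  cm <- contact_matrix(matrix(3, 8, 8), "c", 0, 10)
  expect_true(all(!filter_noise(cm)))
  # a zero row is masked, nothing else
  m <- matrix(3, 8, 8); m[2, ] <- 0; m[, 2] <- 0
  f <- filter_noise(contact_matrix(m, "c", 0, 10))
  expect_true(all(f[2, ]) && all(f[, 2]))
  expect_false(any(f[-2, -2]))
  # an extreme spike lands in the top 0.1 percentile and the IQR rule
  set.seed(2)
  n <- 45  # ~1000 entries at the most-populated distances
  base <- matrix(100, n, n) + matrix(rnorm(n * n), n, n)
  base <- (base + t(base)) / 2
  base[10, 20] <- base[20, 10] <- 500
  fm <- filter_noise(contact_matrix(base, "c", 0, 10))
  expect_true(fm[10, 20] && fm[20, 10])
  # brute-force check of the singleton rule on the same matrix
  cm3 <- contact_matrix(base, "c", 0, 10)
  z <- zscore_map(cm3)
  thr <- quantile(z[!is.na(z)], 0.999)
  expect_true(all(fm[!is.na(z) & z > thr]))
})

test_that("differential maps are 1 for identical inputs and track fold changes", {
  set.seed(6)
  cm <- toy_matrix(n = 40, scale = 400)
  dm <- differential_map(cm, cm)
  v <- dm$ratio[!is.na(dm$ratio)]
  expect_true(all(abs(v - 1) < 1e-9))
  cm2 <- contact_matrix(cm$counts * 2, "chrT", 0, 10)
  dm2 <- differential_map(cm, cm2, smooth = FALSE)
  v2 <- dm2$ratio[!is.na(dm2$ratio)]
  expect_true(all(abs(v2 - 0.5) < 1e-9))
  expect_error(differential_map(cm, toy_matrix(n = 20)), "incompatible")
})

test_that("an injected loop survives distance normalization and smoothing", {
  # structurally heterogeneous matrix (a boundary splits the region) so
  # the per-distance IQR strata have realistic spread; the loop connects
  # the two sides at twice the background contact frequency
  set.seed(9)
  fold <- 2
  n <- 80
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  side <- seq_len(n) > 50
  cross <- outer(side, side, "!=")
  lam <- 3000 * pmax(d, 0.5)^(-0.8) * ifelse(cross, 1 / 3, 1)
  lam_b <- lam
  lam_b[30:34, 60:64] <- lam_b[30:34, 60:64] * fold
  lam_b[60:64, 30:34] <- t(lam_b[30:34, 60:64])
  sample_cm <- function(l) {
    up <- upper.tri(l, diag = TRUE)
    cnt <- matrix(0, nrow(l), ncol(l))
    cnt[up] <- rpois(sum(up), l[up])
    cnt <- cnt + t(cnt) - diag(diag(cnt))
    contact_matrix(cnt, "chrT", 0, 10)
  }
  a <- sample_cm(lam_b); b <- sample_cm(lam)
  dm <- differential_map(a, b, window = 2)
  expect_equal(dm$ratio[32, 62], fold, tolerance = 0.1 * fold)
})

test_that("smoothing preserves the mean on unmasked constant regions", {
  m <- matrix(2.5, 20, 20)
  sm <- epcomm:::.bilinear_smooth(m, 2)
  expect_true(all(abs(sm - 2.5) < 1e-12))
})

test_that("boundary drop reads step profiles correctly", {
  vp <- structure(list(anchor_bin = 5, anchor = 45,
                       position = seq(5, 195, 10), value = rep(0.06, 20),
                       scale = "probability", chrom = "c", start = 0,
                       binsize = 10, mask = rep(FALSE, 20)),
                  class = "viewpoint_profile")
  vp$value[11:20] <- 0.02
  expect_equal(boundary_drop(vp, boundary = 100, flank = 3), 3)
  vp_flat <- vp; vp_flat$value <- rep(0.04, 20)
  expect_equal(boundary_drop(vp_flat, boundary = 100), 1)
})

test_that("contact matrices round-trip through dense TSV and triplets", {
  cm <- toy_matrix(12)
  f <- tempfile(fileext = ".tsv")
  write_contact_matrix(cm, f)
  cm2 <- read_contact_matrix(f)
  expect_equal(cm2$counts, cm$counts, tolerance = 1e-9)
  expect_equal(cm2$binsize, cm$binsize)
  expect_equal(cm2$chrom, cm$chrom)
  set.seed(1)
  sp <- cm$counts
  sp[sp < quantile(sp, 0.3)] <- 0  # sparse with genuine zeros
  cm3 <- contact_matrix(sp, "chrT", 0, 10)
  ft <- tempfile(fileext = ".txt")
  write_contact_triplets(cm3, ft)
  cm4 <- read_contact_triplets(ft)
  expect_equal(cm4$counts, cm3$counts, tolerance = 1e-9)
  expect_equal(cm4$end, cm3$end)
})
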