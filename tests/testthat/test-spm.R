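test_that("paired t-field matches the per-node textbook computation", {
  set.seed(1)
  a <- matrix(rnorm(32 * 101), 32)
  b <- matrix(rnorm(32 * 101), 32)
  ft <- paired_t_field(a, b)
  expect_equal(ft$df, 31L)
  ref <- vapply(1:101, function(q) t.test(a[, q], b[, q], paired = TRUE)$statistic, 0)
  expect_lt(max(abs(ft$t - ref)), 1e-10)
})

test_that("degenerate difference patterns are handled", {
  a <- matrix(rnorm(4 * 10), 4)
  expect_equal(paired_t_field(a, a)$t, rep(0, 10))
  # alternating +/- differences have zero mean: t = 0
  d <- matrix(rep(c(1, -1), 5 * 4), 4, 10, byrow = FALSE)
  ft <- paired_t_field(d, matrix(0, 4, 10))
  expect_equal(ft$t[1], 0)
  # zero variance, nonzero mean: capped with warning
  expect_warning(ftc <- paired_t_field(matrix(1, 4, 3), matrix(0, 4, 3)),
                 "capped")
  expect_true(all(ftc$t == 1e6))
  expect_error(paired_t_field(matrix(1, 2, 3), matrix(0, 2, 3)), "at least 3")
  expect_error(paired_t_field(matrix(1, 4, 3), matrix(0, 5, 3)), "identical dim")
})

test_that("the t-field is antisymmetric and shift-invariant", {
  set.seed(2)
  a <- gen_smooth_fields(12); b <- gen_smooth_fields(12)
  expect_equal(paired_t_field(a, b)$t, -paired_t_field(b, a)$t)
  shift <- matrix(rep(sin(seq(0, 3, length.out = 101)), each = 12), 12)
  expect_equal(paired_t_field(a + shift, b + shift)$t, paired_t_field(a, b)$t,
               tolerance = 1e-9)
})

test_that("FWHM estimation tracks known smoothness and flags degeneracy", {
  set.seed(3)
  # white residuals: very rough fields
  est_w <- mean(replicate(300, estimate_fwhm(matrix(rnorm(32 * 101), 32))))
  expect_lt(est_w, 3)
  # Gaussian-smoothed residuals of known kernel FWHM 15: within 20%
  est_s <- mean(replicate(300, estimate_fwhm(gen_smooth_fields(32))))
  expect_equal(est_s, 15, tolerance = 0.2)
  # constant-per-row residuals clamp at 3 * node_count
  r <- matrix(rep(c(1, -1, 0.5), 101), 3, 101)
  fw <- estimate_fwhm(r)
  expect_equal(as.numeric(fw), 303)
  expect_true(attr(fw, "clamped"))
  expect_error(estimate_fwhm(matrix(0, 3, 101)), "all-zero")
})

test_that("the RFT threshold has the right limits and monotonicity", {
  # zero-resel limit: the ordinary two-tailed critical t
  expect_equal(rft_threshold(31, fwhm = 1e9, 101, 0.05),
               qt(0.975, 31), tolerance = 1e-6)
  # smaller alpha, larger threshold
  t1 <- rft_threshold(31, 15, 101, 0.05)
  t2 <- rft_threshold(31, 15, 101, 0.01)
  expect_gt(t2, t1)
  # more resels (rougher field), larger threshold
  expect_gt(rft_threshold(31, 5, 101, 0.05), t1)
})

test_that("cluster geometry follows the threshold crossings", {
  t_field <- rep(1, 101)
  expect_equal(nrow(cluster_inference(t_field, 3.5, 10, 31)), 0L)
  t_field[21:35] <- 5
  cl <- cluster_inference(t_field, 3.5, 10, 31)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start, 20L)
  expect_equal(cl$end, 34L)
  expect_equal(cl$extent, 15L)
  expect_equal(cl$max_t, 5)
  expect_lte(cl$p, 0.05)
  # negative excursions cluster too, and p floors at the reporting threshold
  t_field[60:90] <- -12
  cl2 <- cluster_inference(t_field, 3.5, 10, 31)
  expect_equal(nrow(cl2), 2L)
  expect_equal(cl2$p_label[2], "<0.001")
})

test_that("permutation oracle is deterministic and enumerates small samples", {
  set.seed(4)
  a <- gen_smooth_fields(8); b <- gen_smooth_fields(8)
  p1 <- permutation_oracle(a, b, 500, seed = 3)
  p2 <- permutation_oracle(a, b, 500, seed = 3)
  expect_identical(p1$max_t, p2$max_t)
  p3 <- permutation_oracle(a[1:3, ], b[1:3, ], 1000, seed = 1)
  expect_true(p3$exhaustive)
  expect_equal(length(p3$max_t), 8L)
})

test_that("RFT cluster p agrees with the permutation oracle within a factor of 2 (median)", {
  set.seed(11)
  ratios <- c()
  shift <- c(rep(0, 30), rep(0.55, 25), rep(0, 46))  # boxcar mean shift
  for (r in 1:80) {
    a <- gen_smooth_fields(32) + matrix(rep(shift, each = 32), 32)
    b <- gen_smooth_fields(32)
    ft <- paired_t_field(a, b)
    fw <- estimate_fwhm(ft$residuals)
    ts <- rft_threshold(ft$df, fw, 101, 0.05)
    cl <- cluster_inference(ft$t, ts, fw, ft$df, alpha = 1, two_tailed = TRUE)
    if (!nrow(cl)) next
    i <- which.max(cl$extent)
    po <- permutation_oracle(a, b, 500, seed = r, t_star = ts)
    pp <- po$cluster_p(cl$extent[i])
    if (pp == 0 || cl$p[i] >= 1) next
    ratios <- c(ratios, cl$p[i] / pp)
  }
  expect_gt(length(ratios), 15)
  expect_gt(median(ratios), 0.5)
  expect_lt(median(ratios), 2)
})

test_that("spm_t assembles a full result object with tidy/glance methods", {
  set.seed(6)
  a <- stride_matrix(gen_smooth_fields(32) +
                       matrix(rep(c(rep(0, 40), rep(2, 20), rep(0, 41)),
                                  each = 32), 32), "BF", "WT80")
  b <- stride_matrix(gen_smooth_fields(32), "BF", "OG")
  res <- spm_t(a, b)
  expect_s3_class(res, "spm_t")
  expect_true(res$significant)
  expect_true(any(res$clusters$start <= 60 & res$clusters$end >= 40))
  td <- tidy(res)
  expect_equal(nrow(td), 101L)
  expect_true(any(td$significant))
  g <- glance(res)
  expect_equal(g$n_clusters, nrow(res$clusters))
  # unpaired variant runs with pooled degrees of freedom
  res2 <- spm_t(a, b, paired = FALSE)
  expect_equal(res2$df, 62L)
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
})
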