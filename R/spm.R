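#' Paired t-field over the stride domain
#'
#' Node-wise paired t statistic between two stride matrices whose rows are
#' paired by rank order of occurrence: at node q with paired differences
#' `d_i(q)`, `t(q) = mean(d(q)) / (sd(d(q)) / sqrt(n))` with `n - 1` degrees
#' of freedom. Residuals `d_i(q) - mean(d(q))` are returned for smoothness
#' estimation. Zero-variance nodes give t = 0 when the mean difference is
#' also 0, otherwise t is capped at `cap` with a warning flag.
#'
#' @param a,b Stride matrices (or plain matrices) with equal dimensions.
#' @param cap Magnitude assigned to zero-variance nonzero-mean nodes.
#' @return List with `t` (length-Q t-field), `df`, `residuals` (n x Q), and
#'   `capped` (nodes where a zero-variance nonzero-mean t was capped).
#' @export
paired_t_field <- function(a, b, cap = 1e6) {
  a <- unclass(a); b <- unclass(b)
  if (!all(dim(a) == dim(b)))
    abort("stride matrices must have identical dimensions for a paired test")
  n <- nrow(a)
  if (n < 3L) abort("at least 3 stride pairs are required")
  d <- a - b
  m <- colMeans(d)
  r <- sweep(d, 2, m)
  s <- sqrt(colSums(r^2) / (n - 1))
  t <- m / (s / sqrt(n))
  capped <- which(s == 0 & m != 0)
  t[s == 0] <- 0
  if (length(capped)) {
    warn(sprintf("%d zero-variance node(s) with nonzero mean; t capped", length(capped)))
    t[capped] <- sign(m[capped]) * cap
  }
  list(t = t, df = n - 1L, residuals = r, capped = capped)
}

#' Two-sample t-field (unpaired alternative)
#'
#' Pooled-variance two-sample t at each node, `n_a + n_b - 2` degrees of
#' freedom; residuals are the group-mean-centred rows of both matrices.
#'
#' @param a,b Stride matrices with equal node counts.
#' @return As [paired_t_field()].
#' @export
two_sample_t_field <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  if (ncol(a) != ncol(b)) abort("matrices must share the node grid")
  na <- nrow(a); nb <- nrow(b)
  if (na < 2L || nb < 2L) abort("at least 2 strides per condition are required")
  ra <- sweep(a, 2, colMeans(a)); rb <- sweep(b, 2, colMeans(b))
  sp2 <- (colSums(ra^2) + colSums(rb^2)) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  t <- (colMeans(a) - colMeans(b)) / se
  t[se == 0] <- 0
  list(t = t, df = na + nb - 2L, residuals = rbind(ra, rb), capped = integer())
}

#' Estimate field smoothness (FWHM) from residuals
#'
#' Standard one-dimensional random-field estimator: each residual curve is
#' normalised by the pointwise standard deviation across curves, node-to-node
#' gradients are formed, and `fwhm = sqrt(4 * log(2) / mean(gradient^2))` in
#' node units. The estimate is clamped to `[1, 3 * node_count]`; hitting the
#' upper clamp (constant residuals) sets the `clamped` attribute.
#'
#' @param residuals n x Q residual matrix from a t-field computation.
#' @return FWHM in nodes (attribute `clamped` when the clamp engaged).
#' @export
estimate_fwhm <- function(residuals) {
  r <- as.matrix(residuals)
  if (nrow(r) < 3L) abort("at least 3 residual curves are required")
  s <- sqrt(colMeans(r^2))
  if (all(s == 0)) abort("all-zero residuals: smoothness undefined")
  ok <- s > 0
  v <- sweep(r[, ok, drop = FALSE], 2, s[ok], "/")
  g <- t(diff(t(v)))
  msg <- mean(g^2)
  q <- ncol(r)
  if (msg <= 0) return(structure(3 * q, clamped = TRUE))
  fwhm <- sqrt(4 * log(2) / msg)
  clamped <- fwhm < 1 || fwhm > 3 * q
  structure(min(max(fwhm, 1), 3 * q), clamped = clamped)
}

# 1D Euler-characteristic tail for a t-field: P(max T > u) approximated by
# the 0-dimensional tail plus resels times the 1-dimensional EC density
rft_tail <- function(u, df, resels) {
  (1 - pt(u, df)) +
    resels * sqrt(4 * log(2)) / (2 * pi) * (1 + u^2 / df)^(-(df - 1) / 2)
}

#' Random-field-theory critical threshold for a 1D t-field
#'
#' Solves `P(max |T| > t*) = alpha` under the smooth-Gaussian-field null
#' using the standard one-dimensional Euler-characteristic expectation
#' (0-dimensional tail plus EC density times resels). Two-tailed inference
#' splits alpha between the tails. In the zero-resel limit (very smooth
#' fields) the threshold reduces to the ordinary critical t.
#'
#' @param df Degrees of freedom (>= 2).
#' @param fwhm Field smoothness in nodes.
#' @param node_count Nodes in the field.
#' @param alpha Family-wise significance level.
#' @param two_tailed Split alpha across both tails (default `TRUE`).
#' @return Critical threshold `t*` (> 0), solved to 1e-8.
#' @export
rft_threshold <- function(df, fwhm, node_count, alpha = 0.05,
                          two_tailed = TRUE) {
  stopifnot(df >= 2, fwhm > 0, alpha > 0, alpha < 1)
  resels <- (node_count - 1) / fwhm
  target <- if (two_tailed) alpha / 2 else alpha
  f <- function(u) rft_tail(u, df, resels) - target
  if (f(100) > 0 || f(1e-4) < 0)
    abort("no RFT threshold in (0, 100) for these parameters")
  uniroot(f, c(1e-4, 100), tol = 1e-8)$root
}

#' Supra-threshold cluster inference
#'
#' Maximal runs of `|t| > t*` become clusters. Each receives a cluster-level
#' p-value from the standard random-field expected-cluster-extent
#' approximation: with expected cluster count `E[m]` (the EC expectation at
#' the threshold) and expected extent `E[S]` in resel units, cluster extent is
#' taken exponential and `p = 1 - exp(-E[m] * exp(-k / E[S]))` for observed
#' resel extent `k`, doubled for two-tailed inference and capped at `alpha`.
#'
#' @param t_field Numeric t-field.
#' @param t_star Threshold from [rft_threshold()].
#' @param fwhm Smoothness in nodes.
#' @param df Degrees of freedom.
#' @param alpha Significance level (cap for reported p).
#' @param two_tailed Doubles the cluster p for two-tailed inference.
#' @return Tibble with `start`, `end` (0-based node indices, inclusive),
#'   `extent` (nodes), `max_t`, `p`, `p_label` (3-decimal with the
#'   "<0.001" reporting floor).
#' @export
cluster_inference <- function(t_field, t_star, fwhm, df, alpha = 0.05,
                              two_tailed = TRUE) {
  supra <- abs(t_field) > t_star
  empty <- tibble(start = integer(), end = integer(), extent = integer(),
                  max_t = numeric(), p = numeric(), p_label = character())
  if (!any(supra)) return(empty)
  r <- rle(supra)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  q <- length(t_field)
  resels <- (q - 1) / fwhm
  e_m <- rft_tail(t_star, df, resels)
  p0 <- 1 - pt(t_star, df)
  e_s <- (p0 * q / fwhm) / e_m  # expected extent, resel units
  out <- map(runs, function(i) {
    a <- starts[i]; b <- ends[i]
    k <- (b - a + 1L) / fwhm
    p <- 1 - exp(-e_m * exp(-k / e_s))
    if (two_tailed) p <- 2 * p
    tibble(start = a - 1L, end = b - 1L, extent = b - a + 1L,
           max_t = max(abs(t_field[a:b])), p = min(p, alpha))
  })
  out <- bind_rows(out)
  out$p_label <- ifelse(out$p < 0.001, "<0.001", sprintf("%.3f", out$p))
  out
}

#' One-dimensional SPM t-test between two conditions
#'
#' Full inference pipeline for one comparison: t-field (paired by default,
#' with an unpaired pooled-variance option), residual-based smoothness
#' estimate, random-field critical threshold and supra-threshold cluster
#' p-values.
#'
#' @param a,b Stride matrices with equal node counts (equal row counts when
#'   paired).
#' @param alpha Significance level.
#' @param paired Pair rows by rank order (default) or use a two-sample test.
#' @param two_tailed Two-tailed inference with alpha split across tails.
#' @param variable,comparison Labels carried into the result.
#' @return Object of class `spm_t`: `t` (t-field), `df`, `fwhm`, `resels`,
#'   `t_star`, `alpha`, `clusters`, `significant`, plus labels and the means
#'   and SDs of both conditions for plotting.
#' @export
spm_t <- function(a, b, alpha = 0.05, paired = TRUE, two_tailed = TRUE,
                  variable = attr(a, "variable") %||% "variable",
                  comparison = paste(attr(a, "condition") %||% "A",
                                     attr(b, "condition") %||% "B",
                                     sep = " vs ")) {
  ft <- if (paired) paired_t_field(a, b) else two_sample_t_field(a, b)
  fwhm <- estimate_fwhm(ft$residuals)
  q <- length(ft$t)
  t_star <- rft_threshold(ft$df, fwhm, q, alpha, two_tailed)
  clusters <- cluster_inference(ft$t, t_star, fwhm, ft$df, alpha, two_tailed)
  structure(list(
    t = ft$t, df = ft$df, fwhm = as.numeric(fwhm),
    resels = (q - 1) / as.numeric(fwhm), t_star = t_star, alpha = alpha,
    two_tailed = two_tailed, paired = paired,
    clusters = clusters, significant = nrow(clusters) > 0,
    variable = variable, comparison = comparison,
    node = seq_len(q) - 1L,
    mean_a = colMeans(unclass(a)), sd_a = apply(unclass(a), 2, sd),
    mean_b = colMeans(unclass(b)), sd_b = apply(unclass(b), 2, sd),
    label_a = attr(a, "condition") %||% "A",
    label_b = attr(b, "condition") %||% "B"),
    class = "spm_t")
}

#' @export
print.spm_t <- function(x, ...) {
  cat(sprintf("<spm_t> %s, %s: df = %d, FWHM = %.1f nodes, t* = %.3f\n",
              x$variable, x$comparison, x$df, x$fwhm, x$t_star))
  if (nrow(x$clusters)) {
    cat(sprintf("  %d significant cluster(s):\n", nrow(x$clusters)))
    for (i in seq_len(nrow(x$clusters)))
      cat(sprintf("    %d-%d%% stride, max |t| = %.2f, p %s\n",
                  x$clusters$start[i], x$clusters$end[i],
                  x$clusters$max_t[i],
                  ifelse(startsWith(x$clusters$p_label[i], "<"),
                         x$clusters$p_label[i],
                         paste("=", x$clusters$p_label[i]))))
  } else cat("  no supra-threshold clusters\n")
  invisible(x)
}

#' Permutation (sign-flip) oracle for paired SPM inference
#'
#' Non-parametric validation of the random-field threshold: paired
#' differences are sign-flipped, the max-|t| and max-cluster-extent null
#' distributions rebuilt, and empirical critical values returned. When the
#' full sign-flip space is no larger than `n_perm` it is enumerated
#' exhaustively.
#'
#' @param a,b Paired stride matrices.
#' @param n_perm Number of permutations (>= 100 unless exhaustive).
#' @param seed Integer seed.
#' @param alpha Level for the empirical critical value.
#' @param t_star Optional threshold at which max-cluster extents are
#'   collected (defaults to the empirical critical value).
#' @return List: `t_star_emp` (empirical critical max-|t|), `max_t`
#'   (permutation distribution), `max_extent` (nodes), `exhaustive`,
#'   `cluster_p` function mapping an observed extent (nodes) to an empirical
#'   cluster p-value.
#' @export
permutation_oracle <- function(a, b, n_perm = 1000L, seed = 1L, alpha = 0.05,
                               t_star = NULL) {
  d <- unclass(a) - unclass(b)
  n <- nrow(d)
  exhaustive <- 2^n <= n_perm
  if (!exhaustive && n_perm < 100L) abort("n_perm must be at least 100")
  set.seed(as.integer(seed))
  S <- if (exhaustive) {
    as.matrix(do.call(expand.grid, rep(list(c(-1, 1)), n)))
  } else {
    matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), ncol = n)
  }
  m <- S %*% d / n
  css <- matrix(colSums(d^2), nrow = nrow(S), ncol = ncol(d), byrow = TRUE)
  s2 <- (css - n * m^2) / (n - 1)
  s2[s2 < 0] <- 0
  tmat <- m / sqrt(s2 / n)
  tmat[!is.finite(tmat)] <- 0
  max_t <- apply(abs(tmat), 1, max)
  t_star_emp <- as.numeric(quantile(max_t, 1 - alpha, type = 8))
  u <- t_star %||% t_star_emp
  max_extent <- apply(abs(tmat) > u, 1, function(z) {
    if (!any(z)) return(0L)
    r <- rle(z); max(r$lengths[r$values])
  })
  list(t_star_emp = t_star_emp, max_t = max_t, max_extent = max_extent,
       exhaustive = exhaustive,
       cluster_p = function(extent) mean(max_extent >= extent))
}
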