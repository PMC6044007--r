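test_that("size factors are totals over their geometric mean", {
  m <- cbind(c(10, 30, 60), c(40, 120, 240))  # totals 100, 400
  norm <- normalize_matrix(make_count_set(m))
  expect_equal(unname(norm$size_factors), c(0.5, 2.0))
  expect_equal(unname(colSums(norm$values)), c(200, 200))
  # equal totals leave the matrix unchanged
  m2 <- cbind(c(10, 30, 60), c(20, 20, 60))
  norm2 <- normalize_matrix(make_count_set(m2))
  expect_equal(unname(norm2$size_factors), c(1, 1))
  expect_equal(unname(norm2$values), unname(m2))
  # normalized column sums match the geometric mean for every sample
  set.seed(5)
  m3 <- matrix(rpois(60, 40), ncol = 4)
  norm3 <- normalize_matrix(make_count_set(m3))
  gm <- exp(mean(log(colSums(m3))))
  expect_true(all(abs(colSums(norm3$values) - gm) / gm < 1e-6))
  zero <- make_count_set(cbind(c(1, 2, 3), c(0, 0, 0)))
  expect_error(normalize_matrix(zero), class = "meripqc_empty_sample")
})

test_that("bins with zero counts everywhere are dropped", {
  m <- cbind(c(5, 0, 10), c(7, 0, 3))
  norm <- normalize_matrix(make_count_set(m))
  expect_equal(nrow(norm$values), 2L)
})

test_that("depth rescaling does not change distance ratios or topology", {
  set.seed(8)
  base <- matrix(rpois(200, 30), ncol = 4)
  base[, 4] <- base[, 4] + rpois(50, 40)  # distinct sample
  counts <- make_count_set(base)
  norm1 <- normalize_matrix(counts)
  scaled <- base
  scaled[, 2] <- scaled[, 2] * 10
  norm2 <- normalize_matrix(make_count_set(scaled))
  d1 <- as.vector(stats::dist(t(norm1$values)))
  d2 <- as.vector(stats::dist(t(norm2$values)))
  ratio <- d2 / d1
  expect_lt(diff(range(ratio)), 1e-8)
  hc1 <- cluster_samples(norm1)
  hc2 <- cluster_samples(norm2)
  expect_equal(hc1$merge, hc2$merge)
  expect_type(attr(hc1, "newick"), "character")
})

test_that("identical samples merge at height zero; outliers join last", {
  m <- cbind(c(5, 6, 7), c(5, 6, 7))
  hc <- cluster_samples(normalize_matrix(make_count_set(m)))
  expect_equal(hc$height, 0)
  set.seed(21)
  lam <- c(rep(20, 30), rep(160, 10))        # IP-like profile
  ips <- sapply(1:3, function(i) rpois(40, lam))
  outl <- rpois(40, rep(60, 40))             # flat Input-like outlier
  counts <- make_count_set(cbind(ips, outl),
                           ids = c("ip1", "ip2", "ip3", "outlier"))
  hc <- cluster_samples(normalize_matrix(counts))
  # the singleton joining at the final merge is the outlier
  last <- hc$merge[nrow(hc$merge), ]
  singles <- last[last < 0]
  expect_true(length(singles) >= 1)
  expect_true("outlier" %in% hc$labels[-singles])
})

test_that("sample PCA is centered, unscaled, and flags degeneracy", {
  m <- cbind(c(5, 6, 7), c(9, 2, 4))
  pca <- pca_samples(normalize_matrix(make_count_set(m)))
  expect_false(pca$degenerate)
  expect_equal(sum(pca$explained), 1)
  expect_equal(pca$explained[1], 1)  # two samples: one nonzero component
  same <- cbind(c(5, 6, 7), c(5, 6, 7))
  pca2 <- pca_samples(normalize_matrix(make_count_set(same)))
  expect_true(pca2$degenerate)
  set.seed(22)
  lam <- c(rep(20, 30), rep(160, 10))
  ips <- sapply(1:3, function(i) rpois(40, lam))
  outl <- rpois(40, rep(60, 40))
  counts <- make_count_set(cbind(ips, outl),
                           ids = c("ip1", "ip2", "ip3", "outlier"))
  pca3 <- pca_samples(normalize_matrix(counts))
  top <- pca3$scores$sample_id[which.max(abs(pca3$scores$PC1))]
  expect_equal(top, "outlier")
})

test_that("gene-level mean and SD follow their definitions", {
  sk <- make_bin_skeleton(sprintf("g%02d", 1:12), n_bins = 3L)
  counts <- make_counts(sk |> dplyr::mutate(
    none = c(5L, 5L, 5L, as.integer(rep(c(2L, 4L, 6L), 11)))
  ))
  msd <- gene_mean_sd(counts)
  g1 <- msd$points[msd$points$gene_id == "g01", ]
  expect_equal(g1$mean, 5)
  expect_equal(g1$sd, 0)
  expect_true(all(is.finite(msd$curve$sd_fit)))
  few <- make_counts(make_bin_skeleton("g", n_bins = 3L))
  expect_error(gene_mean_sd(few), class = "meripqc_insufficient_genes")
})

test_that("fitted mean-SD curve tracks sqrt(mean) for Poisson counts", {
  set.seed(13)
  n_genes <- 200L
  lam <- exp(runif(n_genes, log(10), log(1000)))
  sk <- make_bin_skeleton(sprintf("g%03d", seq_len(n_genes)), n_bins = 10L)
  counts <- make_counts(sk |> dplyr::mutate(
    none = as.integer(rpois(dplyr::n(), rep(lam, each = 10L)))
  ))
  msd <- gene_mean_sd(counts)
  mid <- msd$curve[msd$curve$mean > 50 & msd$curve$mean < 500, ]
  rel <- abs(mid$sd_fit - sqrt(mid$mean)) / sqrt(mid$mean)
  expect_lt(max(rel), 0.15)
})

test_that("replicate consistency uses the sqrt(J-1) divisor", {
  # equal totals keep size factors at 1, so normalized counts = raw counts
  m <- cbind(c(2, 5, 9), c(4, 5, 7))
  norm <- normalize_matrix(make_count_set(m))
  cons <- replicate_consistency(norm)
  expect_equal(cons$points$mu[1], 3)
  expect_equal(cons$points$s[1], sqrt(2))
  expect_equal(cons$points$s[2], 0)
  ident <- normalize_matrix(make_count_set(cbind(c(3, 4, 5), c(3, 4, 5))))
  cons0 <- replicate_consistency(ident)
  expect_equal(cons0$points$s, rep(0, 3))
  expect_error(replicate_consistency(norm, samples = "s1"),
               class = "meripqc_group_error")
  expect_error(replicate_consistency(norm, samples = c("s1", "zz")),
               class = "meripqc_group_error")
})

test_that("noisier replicate groups sit above cleaner ones", {
  set.seed(30)
  n <- 300L
  mu <- exp(runif(n, log(10), log(200)))
  clean <- sapply(1:3, function(i) rpois(n, mu))
  noisy <- sapply(1:3, function(i) {
    as.integer(round(mu + rnorm(n, 0, 2 * sqrt(mu))))
  })
  noisy[noisy < 0] <- 0L
  counts <- make_count_set(cbind(clean, noisy),
                           ids = c("c1", "c2", "c3", "n1", "n2", "n3"))
  norm <- normalize_matrix(counts)
  cc <- replicate_consistency(norm, c("c1", "c2", "c3"))
  cn <- replicate_consistency(norm, c("n1", "n2", "n3"))
  shared <- range(cc$curve$mu)
  grid <- seq(shared[1], shared[2], length.out = 20)
  fit_at <- function(curve, x) stats::approx(curve$mu, curve$s_fit, x,
                                             rule = 2)$y
  frac_above <- mean(fit_at(cn$curve, grid) > fit_at(cc$curve, grid))
  expect_gt(frac_above, 0.9)
})
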