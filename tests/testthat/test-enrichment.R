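# Build a normalized_gene_bins tibble directly from normalized signals.
make_norm <- function(yhat_ip, yhat_input, gene_id = "g") {
  df <- tibble::tibble(
    gene_id = gene_id, bin = seq_along(yhat_ip),
    y_ip = NA_integer_, y_input = NA_integer_,
    yhat_ip = yhat_ip, yhat_input = yhat_input
  )
  class(df) <- c("normalized_gene_bins", class(tibble::tibble()))
  df
}

test_that("per-gene normalization divides by the gene's mean reads per bin", {
  sk <- make_bin_skeleton(c("g1", "g2"), n_bins = 3L)
  ip <- make_counts(sk |> dplyr::mutate(
    none = c(2L, 4L, 6L, 3L, 3L, 3L)
  ), sample_id = "ip", role = "IP")
  input <- make_counts(sk |> dplyr::mutate(
    none = c(10L, 10L, 10L, 4L, 4L, 4L)
  ), sample_id = "in", role = "Input")
  nb <- normalize_gene_bins(ip, input)
  g1 <- nb[nb$gene_id == "g1", ]
  expect_equal(g1$yhat_ip, c(0.5, 1.0, 1.5))
  expect_equal(g1$yhat_input, c(1, 1, 1))
  # mean of the normalized signal is 1 for every retained gene
  means <- nb |> dplyr::group_by(gene_id) |>
    dplyr::summarise(m_ip = mean(yhat_ip), m_in = mean(yhat_input))
  expect_equal(means$m_ip, rep(1, nrow(means)))
  expect_equal(means$m_in, rep(1, nrow(means)))
})

test_that("genes under the detection threshold are dropped on either side", {
  sk <- make_bin_skeleton(c("g1", "g2", "g3"), n_bins = 3L)
  ip <- make_counts(sk |> dplyr::mutate(
    none = c(3L, 3L, 3L,   20L, 20L, 20L,  20L, 20L, 20L)
  ), role = "IP")                      # g1 has 9 IP reads
  input <- make_counts(sk |> dplyr::mutate(
    none = c(20L, 20L, 20L,  20L, 20L, 20L,  3L, 3L, 3L)
  ), role = "Input")                   # g3 has 9 Input reads
  nb <- normalize_gene_bins(ip, input)
  expect_setequal(unique(nb$gene_id), "g2")
  low <- make_counts(sk |> dplyr::mutate(none = 1L), role = "IP")
  expect_error(normalize_gene_bins(low, low),
               class = "meripqc_filter_error")
})

test_that("ESES reproduces the cumulative-sum worked example", {
  nb <- make_norm(c(0.5, 0.8, 1.2, 1.5), rep(1, 4))
  e <- compute_eses(nb)
  expect_equal(e$curves$p, c(0.125, 0.325, 0.625, 1.0))
  expect_equal(e$curves$q, c(0.25, 0.5, 0.75, 1.0))
  expect_equal(e$scale_factor, 0.175)
  expect_equal(e$k, 2L)
  expect_equal(e$enriched_fraction, 0.5)
  expect_equal(e$signal_read_fraction, 0.675)
  g <- glance(e)
  expect_equal(g$scale_factor, 0.175)
  expect_equal(tidy(e), e$curves)
})

test_that("identical IP and Input collapse to the degenerate ESES result", {
  y <- c(0.4, 0.9, 1.1, 1.6)
  e <- compute_eses(make_norm(y, y))
  expect_equal(e$scale_factor, 0)
  expect_equal(e$k, 4L)
  expect_equal(e$enriched_fraction, 0)
  expect_error(compute_eses(make_norm(rep(0, 4), rep(1, 4))),
               class = "meripqc_degenerate_signal")
})

test_that("ESES curves are monotone with unit endpoints on random input", {
  set.seed(7)
  for (i in seq_len(25L)) {
    n <- sample(5:200, 1)
    e <- compute_eses(make_norm(rgamma(n, 2), rgamma(n, 2)))
    expect_true(all(diff(e$curves$p) >= -1e-12))
    expect_true(all(diff(e$curves$q) >= -1e-12))
    expect_equal(e$curves$p[n], 1)
    expect_equal(e$curves$q[n], 1)
    expect_true(e$scale_factor >= 0 && e$scale_factor <= 1)
    expect_true(e$k >= 1 && e$k <= n)
    expect_equal(e$scale_factor,
                 abs(e$curves$q[e$k] - e$curves$p[e$k]))
  }
})

test_that("ESES is invariant to per-gene expression rescaling", {
  cc <- sim_clean_counts()
  merged <- merge_inputs(list(cc$input))
  e1 <- compute_eses(normalize_gene_bins(cc$ip, merged))
  ip2 <- cc$ip
  input2 <- merged
  # multiply one gene's IP and Input counts by different constants
  g <- unique(ip2$bins$gene_id)[3]
  scale_gene <- function(x, g, f) {
    sel <- x$bins$gene_id == g
    x$bins[sel, c("utr5", "cds", "utr3", "none", "count")] <-
      x$bins[sel, c("utr5", "cds", "utr3", "none", "count")] * f
    x
  }
  e2 <- compute_eses(normalize_gene_bins(scale_gene(ip2, g, 5L),
                                         scale_gene(input2, g, 3L)))
  expect_equal(glance(e1), glance(e2))
  expect_equal(e1$curves, e2$curves)
})

test_that("C-test equals the exact binomial tail", {
  expect_equal(c_test(0, 5), 1)
  expect_equal(c_test(0, 0), 1)
  expect_equal(c_test(10, 1), 12 / 2048)
  # brute-force enumeration oracle over small totals
  brute <- function(x_ip, x_in, d, cc) {
    total <- x_ip + x_in
    pi0 <- cc * d / (1 + cc * d)
    sum(dbinom(x_ip:total, total, pi0))
  }
  set.seed(3)
  for (i in seq_len(50L)) {
    total <- sample(1:30, 1)
    x_ip <- sample(0:total, 1)
    d <- sample(c(0.5, 1, 2), 1)
    cc <- sample(c(1, 2, 4), 1)
    expect_equal(c_test(x_ip, total - x_ip, d, cc),
                 brute(x_ip, total - x_ip, d, cc), tolerance = 1e-12)
  }
  expect_error(c_test(-1, 3), class = "meripqc_domain_error")
})

test_that("C-test p-values are monotone in the count and the threshold", {
  p_by_x <- c_test(0:20, 20:0, depth_ratio = 1, fold = 1)
  expect_true(all(diff(p_by_x) <= 1e-12))
  folds <- c(1, 1.5, 2, 3, 4)
  p_by_c <- vapply(folds, function(cc) c_test(15, 5, 1, cc), numeric(1))
  expect_true(all(diff(p_by_c) >= -1e-12))
})

test_that("C-test profiles separate enriched from null data", {
  sk <- make_bin_skeleton(sprintf("g%02d", 1:20), n_bins = 5L)
  set.seed(11)
  meth <- runif(nrow(sk)) < 0.1
  null_ip <- make_counts(sk |> dplyr::mutate(none = rpois(nrow(sk), 50)),
                         role = "IP")
  null_in <- make_counts(sk |> dplyr::mutate(none = rpois(nrow(sk), 50)),
                         role = "Input")
  enr_ip <- make_counts(
    sk |> dplyr::mutate(none = rpois(nrow(sk), 50 * ifelse(meth, 8, 1))),
    role = "IP"
  )
  p_null <- ctest_profile(null_ip, null_in)
  p_enr <- ctest_profile(enr_ip, null_in)
  expect_true(all(diff(p_null$proportion) <= 1e-12))
  expect_true(all(diff(p_enr$proportion) <= 1e-12))
  expect_gt(p_enr$proportion[p_enr$fold == 2],
            p_null$proportion[p_null$fold == 2])
  # bins at or below 10 combined reads are excluded
  tiny <- make_counts(sk |> dplyr::mutate(none = 2L), role = "IP")
  tiny_in <- make_counts(sk |> dplyr::mutate(none = 2L), role = "Input")
  expect_error(ctest_profile(tiny, tiny_in),
               class = "meripqc_filter_error")
  expect_equal(attr(p_null, "n_bins_tested"),
               sum(null_ip$bins$count + null_in$bins$count > 10))
})
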