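#' Expression-normalized per-gene bin signals
#'
#' Prepares the input to the ESES analysis. Genes with fewer than
#' \code{min_gene_reads} exonic reads in either the IP sample or the merged
#' Input are treated as not reliably detected and dropped (the Input-side
#' filter also guarantees a non-zero normalizer). Each retained gene's bin
#' counts are divided by that gene's mean reads per bin, separately in IP
#' and Input, so that differences in gene expression and sequencing depth
#' cancel: the mean of the normalized signal over every gene's bins is 1.
#'
#' @param ip A \code{sample_counts} for the IP sample.
#' @param merged_input A \code{sample_counts} for the (merged) Input.
#' @param min_gene_reads Per-gene read threshold (default 10).
#' @return A tibble of class \code{normalized_gene_bins} with columns
#'   \code{gene_id}, \code{bin}, \code{y_ip}, \code{y_input} (raw counts),
#'   \code{yhat_ip}, \code{yhat_input} (normalized signals).
#' @export
normalize_gene_bins <- function(ip, merged_input, min_gene_reads = 10L) {
  stopifnot(inherits(ip, "sample_counts"),
            inherits(merged_input, "sample_counts"))
  key <- c("gene_id", "bin", "tx_start", "tx_end")
  if (!identical(as_tibble(ip$bins[, key]),
                 as_tibble(merged_input$bins[, key]))) {
    qc_stop("IP and Input were counted against different bin indexes",
            "shape_error")
  }
  df <- tibble(
    gene_id = ip$bins$gene_id, bin = ip$bins$bin,
    y_ip = ip$bins$count, y_input = merged_input$bins$count
  ) |>
    group_by(.data$gene_id) |>
    mutate(gene_ip = sum(.data$y_ip), gene_input = sum(.data$y_input)) |>
    ungroup() |>
    filter(.data$gene_ip >= min_gene_reads,
           .data$gene_input >= min_gene_reads) |>
    group_by(.data$gene_id) |>
    mutate(yhat_ip = .data$y_ip / mean(.data$y_ip),
           yhat_input = .data$y_input / mean(.data$y_input)) |>
    ungroup() |>
    select("gene_id", "bin", "y_ip", "y_input", "yhat_ip", "yhat_input")
  if (nrow(df) == 0L) {
    qc_stop(sprintf("no gene has >= %d reads in both IP and Input",
                    min_gene_reads), "filter_error")
  }
  attr(df, "sample_id") <- ip$sample_id
  class(df) <- c("normalized_gene_bins", class(tibble()))
  df
}

#' Exome signal extraction scaling (ESES)
#'
#' Quantifies immunoprecipitation efficiency by comparing the cumulative
#' allocation of expression-normalized signal between an IP sample and the
#' merged Input background. All normalized IP bin signals are pooled and
#' sorted in increasing order (ties broken by gene then bin for
#' determinism); the Input signals are reordered to match. Writing p_j and
#' q_j for the cumulative fractions of IP and Input signal over the first j
#' sorted bins, the background cut is the (largest) index k maximizing
#' |q_j - p_j|: the first k bins are background and the bins after k are
#' the regions enriched with immunoprecipitation signal. Reported metrics:
#' \itemize{
#'   \item \code{scale_factor} = max_j |q_j - p_j|,
#'   \item \code{enriched_fraction} = (N - k) / N, the fraction of bins in
#'     the enriched region,
#'   \item \code{signal_read_fraction} = 1 - p_k, the fraction of
#'     cumulated normalized IP signal captured by the enriched bins.
#' }
#'
#' @param norm A \code{normalized_gene_bins} tibble from
#'   [normalize_gene_bins()].
#' @return An object of class \code{eses_result}: list with \code{n_bins},
#'   \code{k}, \code{scale_factor}, \code{enriched_fraction},
#'   \code{signal_read_fraction}, \code{curves} (tibble \code{j},
#'   \code{p}, \code{q}) and \code{sort_order} (tibble \code{rank},
#'   \code{gene_id}, \code{bin}).
#' @export
compute_eses <- function(norm) {
  stopifnot(inherits(norm, "normalized_gene_bins"))
  if (nrow(norm) < 2L) qc_stop("need at least 2 bins", "degenerate_signal")
  if (sum(norm$yhat_ip) <= 0) {
    qc_stop("IP signal is identically zero", "degenerate_signal")
  }
  # sort key rounded to 12 significant digits so that values tied in exact
  # arithmetic stay tied under floating-point rescaling, keeping the
  # (gene_id, bin) tie-break deterministic
  ord <- order(signif(norm$yhat_ip, 12), norm$gene_id, norm$bin)
  yt <- norm$yhat_ip[ord]
  yc <- norm$yhat_input[ord]
  N <- length(yt)
  p <- cumsum(yt) / sum(yt)
  q <- cumsum(yc) / sum(yc)
  d <- abs(q - p)
  k <- max(which(d == max(d)))
  res <- list(
    sample_id = attr(norm, "sample_id"),
    n_bins = N, k = k,
    scale_factor = max(d),
    enriched_fraction = (N - k) / N,
    signal_read_fraction = 1 - p[k],
    curves = tibble(j = seq_len(N), p = p, q = q),
    sort_order = tibble(rank = seq_len(N),
                        gene_id = norm$gene_id[ord], bin = norm$bin[ord])
  )
  class(res) <- "eses_result"
  res
}

#' @export
print.eses_result <- function(x, ...) {
  cat(sprintf(
    paste0("<eses_result> N = %d bins | background cut k = %d\n",
           "  scale factor %.4f | enriched region %.2f%% | ",
           "signal reads %.2f%%\n"),
    x$n_bins, x$k, x$scale_factor, 100 * x$enriched_fraction,
    100 * x$signal_read_fraction
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname compute_eses
#' @param x An \code{eses_result}.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.eses_result <- function(x, ...) x$curves

#' @rdname compute_eses
#' @exportS3Method generics::glance
glance.eses_result <- function(x, ...) {
  tibble(
    n_bins = x$n_bins, k = x$k, scale_factor = x$scale_factor,
    enriched_fraction = x$enriched_fraction,
    signal_read_fraction = x$signal_read_fraction
  )
}

#' @rdname compute_eses
#' @param object An \code{eses_result}.
#' @exportS3Method ggplot2::autoplot
autoplot.eses_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curves, c("p", "q"),
                              names_to = "curve", values_to = "fraction") |>
    mutate(curve = dplyr::recode(.data$curve, p = "IP", q = "Input"))
  ggplot2::ggplot(long, ggplot2::aes(.data$j, .data$fraction,
                                     colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$k, colour = "black") +
    ggplot2::labs(
      title = sprintf(
        "ESES: scale factor %.3f, enriched region %.1f%%",
        object$scale_factor, 100 * object$enriched_fraction
      ),
      x = "bins (sorted by normalized IP signal)",
      y = "fraction of cumulated signal", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Exact conditional test of two Poisson means (C-test)
#'
#' Tests whether the IP count of a bin exceeds \code{fold} times its
#' depth-adjusted Input count, assuming both are Poisson. Conditional on
#' the total T = x_ip + x_in, x_ip is Binomial(T, pi0) under the null
#' H0: lambda_ip <= fold * depth_ratio * lambda_in, with
#' pi0 = fold * depth_ratio / (1 + fold * depth_ratio); the p-value is the
#' exact upper tail P(X >= x_ip).
#'
#' @param x_ip,x_in Non-negative integer read counts (vectorized).
#' @param depth_ratio Ratio of IP to Input sequencing depth.
#' @param fold Fold-enrichment threshold (>= 1).
#' @return P-value(s) in [0, 1].
#' @export
c_test <- function(x_ip, x_in, depth_ratio = 1, fold = 1) {
  if (any(x_ip < 0) || any(x_in < 0)) {
    qc_stop("read counts must be non-negative", "domain_error")
  }
  stopifnot(depth_ratio > 0, fold >= 1)
  total <- x_ip + x_in
  pi0 <- fold * depth_ratio / (1 + fold * depth_ratio)
  stats::pbinom(x_ip - 1, total, pi0, lower.tail = FALSE)
}

#' C-test enrichment profile over a grid of fold thresholds
#'
#' Applies the [c_test()] to every bin with more than \code{min_bin_reads}
#' combined IP + Input reads, at each fold threshold of \code{fold_grid},
#' and reports the proportion of tested bins significant at level
#' \code{alpha}. The depth ratio is the ratio of total exonic bin counts
#' (IP over Input). Proportions are non-increasing in the fold threshold.
#'
#' @param ip,merged_input \code{sample_counts} objects on a shared bin
#'   index.
#' @param fold_grid Fold-enrichment thresholds.
#' @param alpha Significance level (default 0.05).
#' @param min_bin_reads Bins must exceed this many combined reads
#'   (default 10).
#' @return A tibble of class \code{ctest_profile} with columns \code{fold}
#'   and \code{proportion}; attributes \code{alpha} and
#'   \code{n_bins_tested}.
#' @export
ctest_profile <- function(ip, merged_input,
                          fold_grid = c(1, 1.5, 2, 2.5, 3, 3.5, 4),
                          alpha = 0.05, min_bin_reads = 10L) {
  stopifnot(inherits(ip, "sample_counts"),
            inherits(merged_input, "sample_counts"))
  x_ip <- ip$bins$count
  x_in <- merged_input$bins$count
  keep <- (x_ip + x_in) > min_bin_reads
  if (!any(keep)) {
    qc_stop(sprintf("no bin has more than %d combined reads",
                    min_bin_reads), "filter_error")
  }
  x_ip <- x_ip[keep]
  x_in <- x_in[keep]
  d <- sum(ip$bins$count) / sum(merged_input$bins$count)
  prop <- vapply(fold_grid, function(cc) {
    mean(c_test(x_ip, x_in, depth_ratio = d, fold = cc) < alpha)
  }, numeric(1))
  out <- tibble(fold = fold_grid, proportion = prop)
  attr(out, "alpha") <- alpha
  attr(out, "n_bins_tested") <- sum(keep)
  attr(out, "depth_ratio") <- d
  attr(out, "sample_id") <- ip$sample_id
  class(out) <- c("ctest_profile", class(tibble()))
  out
}

#' @rdname ctest_profile
#' @param object A \code{ctest_profile}.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.ctest_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$fold, 100 * .data$proportion)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = sprintf("C-test enrichment profile: %s",
                      attr(object, "sample_id") %||% ""),
      x = "fold-enrichment threshold",
      y = sprintf("%% of bins enriched (alpha = %.2f)",
                  attr(object, "alpha"))
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
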