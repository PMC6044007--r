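#' Size-factor normalization of a bin count matrix
#'
#' Assembles the bins-by-samples count matrix from several counted samples
#' and removes sequencing-depth differences with per-sample size factors:
#' s_j = y_j / exp(mean(log y)), where y_j is the total exonic bin count of
#' sample j, so each normalized column sums to the geometric mean of the
#' raw totals. Bins with zero counts in every sample carry no information
#' and are dropped.
#'
#' @param counts A list of \code{sample_counts} on a shared bin index
#'   (at least 2).
#' @return An object of class \code{normalized_matrix}: list with
#'   \code{values} (bins x samples matrix of normalized counts, rownames
#'   \code{gene:bin}), \code{size_factors}, \code{raw_totals},
#'   \code{roles} and \code{bins} (the retained bin skeleton).
#' @export
normalize_matrix <- function(counts) {
  stopifnot(is.list(counts), length(counts) >= 2L)
  ids <- vapply(counts, function(x) x$sample_id, character(1))
  ref <- counts[[1]]$bins[, c("gene_id", "bin", "tx_start", "tx_end")]
  for (x in counts[-1]) {
    if (!identical(ref, x$bins[, c("gene_id", "bin", "tx_start", "tx_end")])) {
      qc_stop("samples were counted against different bin indexes",
              "shape_error")
    }
  }
  mat <- vapply(counts, function(x) as.numeric(x$bins$count),
                numeric(nrow(ref)))
  colnames(mat) <- ids
  rownames(mat) <- paste0(ref$gene_id, ":", counts[[1]]$bins$bin)
  totals <- colSums(mat)
  if (any(totals <= 0)) {
    qc_stop(sprintf("sample(s) with zero exonic reads: %s",
                    paste(ids[totals <= 0], collapse = ", ")),
            "empty_sample")
  }
  sf <- totals / exp(mean(log(totals)))
  norm <- sweep(mat, 2, sf, "/")
  keep <- rowSums(mat) > 0
  res <- list(
    values = norm[keep, , drop = FALSE],
    size_factors = stats::setNames(sf, ids),
    raw_totals = stats::setNames(totals, ids),
    roles = stats::setNames(vapply(counts, function(x) x$role,
                                   character(1)), ids),
    bins = ref[keep, ]
  )
  class(res) <- "normalized_matrix"
  res
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> %d bins x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("  size factors:",
      paste(sprintf("%s=%.3f", names(x$size_factors), x$size_factors),
            collapse = ", "), "\n")
  invisible(x)
}

#' Hierarchical clustering of samples
#'
#' Agglomerative (complete-linkage) clustering of the samples on the
#' Euclidean distances between their normalized bin-count columns. Columns
#' are ordered by sample id before clustering so tied merges resolve
#' deterministically. Outlying or swapped samples join the tree last.
#'
#' @param norm A \code{normalized_matrix}.
#' @return An \code{hclust} object; the equivalent Newick string is stored
#'   in the \code{"newick"} attribute.
#' @export
cluster_samples <- function(norm) {
  stopifnot(inherits(norm, "normalized_matrix"))
  m <- norm$values[, order(colnames(norm$values)), drop = FALSE]
  hc <- stats::hclust(stats::dist(t(m), method = "euclidean"),
                      method = "complete")
  phy <- ape::as.phylo(hc)
  attr(hc, "newick") <- ape::write.tree(phy)
  hc
}

#' Principal component analysis of samples
#'
#' Centered (not variance-scaled) PCA of the samples-as-observations
#' normalized matrix, summarizing relative sample similarity; a swapped or
#' failed sample separates on the leading component.
#'
#' @param norm A \code{normalized_matrix}.
#' @return A list of class \code{sample_pca}: \code{scores} tibble
#'   (sample_id, role, PC columns), \code{explained} (variance fractions)
#'   and \code{degenerate} (TRUE when all samples are identical).
#' @export
pca_samples <- function(norm) {
  stopifnot(inherits(norm, "normalized_matrix"))
  x <- t(norm$values)
  vars <- apply(x, 2, stats::var)
  degenerate <- sum(vars) == 0
  if (degenerate) {
    scores <- tibble(sample_id = rownames(x),
                     role = unname(norm$roles[rownames(x)]),
                     PC1 = 0, PC2 = 0)
    res <- list(scores = scores, explained = numeric(0),
                degenerate = TRUE)
  } else {
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    sc <- as_tibble(pc$x[, seq_len(min(4L, ncol(pc$x))), drop = FALSE])
    scores <- bind_cols(
      tibble(sample_id = rownames(x),
             role = unname(norm$roles[rownames(x)])),
      sc
    )
    res <- list(scores = scores,
                explained = pc$sdev^2 / sum(pc$sdev^2),
                degenerate = FALSE)
  }
  class(res) <- "sample_pca"
  res
}

#' @rdname pca_samples
#' @param object A \code{sample_pca}.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.sample_pca <- function(object, ...) {
  sc <- object$scores
  if (!"PC2" %in% names(sc)) sc$PC2 <- 0
  lab <- function(i) {
    if (length(object$explained) >= i) {
      sprintf("PC%d (%.1f%%)", i, 100 * object$explained[i])
    } else {
      sprintf("PC%d", i)
    }
  }
  ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2,
                                   colour = .data$role,
                                   label = .data$sample_id)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_text(vjust = -1, show.legend = FALSE) +
    ggplot2::labs(x = lab(1), y = lab(2), colour = NULL) +
    ggplot2::theme_minimal()
}

# Tri-cube weighted local linear smoother on a 100-point grid (loess
# defaults: degree 1 forced, span as given).
fit_local_curve <- function(x, y, span = 0.75, grid_points = 100L) {
  # loess emits numerical chatter (pseudoinverse / zero-width neighborhood)
  # on heavily tied abscissae; the fit itself is still usable
  fit <- suppressWarnings(
    stats::loess(y ~ x, span = span, degree = 1, family = "gaussian",
                 control = stats::loess.control(surface = "direct"))
  )
  grid <- seq(min(x), max(x), length.out = grid_points)
  tibble(x = grid,
         y = as.numeric(suppressWarnings(stats::predict(fit,
                                                        newdata = grid))))
}

#' Gene-specific heterogeneity of read coverage
#'
#' For every gene with at least two bins, computes the mean and standard
#' deviation of that gene's bin counts in one sample, then fits a local
#' (tri-cube weighted, degree-1, span 0.75) regression of SD on mean. IP
#' samples carry enrichment signal and therefore run above the Input curve;
#' PCR artifacts push the curve up further at high means.
#'
#' @param counts A \code{sample_counts}.
#' @param span Local-regression span.
#' @param min_genes Minimum usable genes (default 10).
#' @return A list of class \code{mean_sd_curve}: \code{points} tibble
#'   (gene_id, mean, sd) and \code{curve} tibble (mean, sd_fit), plus the
#'   span used.
#' @export
gene_mean_sd <- function(counts, span = 0.75, min_genes = 10L) {
  stopifnot(inherits(counts, "sample_counts"))
  pts <- counts$bins |>
    group_by(.data$gene_id) |>
    filter(dplyr::n() >= 2L) |>
    summarise(mean = mean(.data$count), sd = stats::sd(.data$count),
              .groups = "drop")
  if (nrow(pts) < min_genes) {
    qc_stop(sprintf("only %d genes with >= 2 bins (need >= %d)",
                    nrow(pts), min_genes), "insufficient_genes")
  }
  cv <- fit_local_curve(pts$mean, pts$sd, span = span)
  res <- list(points = pts,
              curve = tibble(mean = cv$x, sd_fit = cv$y),
              span = span, sample_id = counts$sample_id)
  class(res) <- "mean_sd_curve"
  res
}

#' Cross-replicate consistency of normalized bin counts
#'
#' For each bin, computes the mean and standard deviation (divisor
#' sqrt(J - 1)) of the size-factor normalized counts across the J selected
#' replicate samples, and fits a local regression of SD on mean. Lower
#' curves indicate more reproducible replicate groups.
#'
#' @param norm A \code{normalized_matrix}.
#' @param samples Character vector of sample ids forming the replicate
#'   group (default: all samples in \code{norm}).
#' @param span Local-regression span.
#' @return A list of class \code{consistency_curve}: \code{points} tibble
#'   (gene_id, bin, mu, s) and \code{curve} tibble (mu, s_fit).
#' @export
replicate_consistency <- function(norm, samples = colnames(norm$values),
                                  span = 0.75) {
  stopifnot(inherits(norm, "normalized_matrix"))
  missing <- setdiff(samples, colnames(norm$values))
  if (length(missing) > 0L) {
    qc_stop(sprintf("unknown sample(s): %s",
                    paste(missing, collapse = ", ")), "group_error")
  }
  if (length(samples) < 2L) {
    qc_stop("a replicate group needs at least 2 samples", "group_error")
  }
  m <- norm$values[, samples, drop = FALSE]
  mu <- unname(rowMeans(m))
  s <- unname(apply(m, 1, stats::sd))
  pts <- tibble(gene_id = norm$bins$gene_id, bin = norm$bins$bin,
                mu = mu, s = s)
  cv <- fit_local_curve(mu, s, span = span)
  res <- list(points = pts, curve = tibble(mu = cv$x, s_fit = cv$y),
              span = span, samples = samples)
  class(res) <- "consistency_curve"
  res
}

#' Plot one or more fitted mean-SD / consistency curves
#'
#' @param curves A named list of \code{mean_sd_curve} or
#'   \code{consistency_curve} objects.
#' @return A ggplot object.
#' @export
plot_fitted_curves <- function(curves) {
  df <- purrr::imap(curves, function(cv, nm) {
    cc <- cv$curve
    names(cc) <- c("x", "y")
    cc$sample <- nm
    cc
  }) |> bind_rows()
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   colour = .data$sample)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "mean", y = "fitted SD", colour = NULL) +
    ggplot2::theme_minimal()
}
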