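#' Summarize read counts over genomic regions
#'
#' Tabulates, per sample, the number and percentage of reads assigned to
#' exonic, intronic and non-genic space, and the split of mRNA reads over
#' 5'UTR / CDS / 3'UTR. Exon, intron and non-genic percentages are taken
#' over the sample total; the three mRNA sub-region percentages are taken
#' over the sum of reads in the three sub-regions (reads in non-coding
#' genes carry no sub-region and are excluded from that denominator).
#'
#' @param counts A \code{sample_counts} object or a list of them.
#' @return A tibble with one row per sample: counts and percentages for
#'   each region.
#' @export
region_stats <- function(counts) {
  if (inherits(counts, "sample_counts")) counts <- list(counts)
  purrr::map(counts, function(x) {
    rc <- x$region_counts
    total <- x$total_reads
    if (total == 0L) {
      qc_stop(sprintf("sample %s has no reads", x$sample_id), "empty_sample")
    }
    mrna <- rc[["utr5"]] + rc[["cds"]] + rc[["utr3"]]
    pct <- function(n, d) if (d > 0) 100 * n / d else NA_real_
    tibble(
      sample_id = x$sample_id, role = x$role, total = total,
      exon = rc[["exon"]], exon_pct = pct(rc[["exon"]], total),
      intron = rc[["intron"]], intron_pct = pct(rc[["intron"]], total),
      nongenic = rc[["nongenic"]], nongenic_pct = pct(rc[["nongenic"]], total),
      utr5 = rc[["utr5"]], utr5_pct = pct(rc[["utr5"]], mrna),
      cds = rc[["cds"]], cds_pct = pct(rc[["cds"]], mrna),
      utr3 = rc[["utr3"]], utr3_pct = pct(rc[["utr3"]], mrna)
    )
  }) |> bind_rows()
}

coverage_classes <- c("0", "1-10", "10-10^2", "10^2-10^3",
                      "10^3-10^4", "10^4-10^5", ">10^5")

#' Exonic coverage-class histogram
#'
#' Classifies every mRNA bin of a sample by its read count into half-open
#' decade classes (0; 1-10; then (10^k, 10^(k+1)] up to 10^5; >10^5) and
#' reports the fraction of bins per class. Comparisons across samples are
#' only meaningful at a common depth; a warning is emitted when the sample
#' was not produced by down-sampling.
#'
#' @param counts A \code{sample_counts} object.
#' @param warn_depth Warn when the sample carries no down-sampling record.
#' @return A tibble with columns \code{sample_id}, \code{class} (ordered
#'   factor) and \code{fraction}; fractions sum to 1.
#' @export
coverage_histogram <- function(counts, warn_depth = TRUE) {
  stopifnot(inherits(counts, "sample_counts"))
  if (warn_depth && is.null(attr(counts, "down_to"))) {
    rlang::warn(paste0(
      "sample '", counts$sample_id, "' was not down-sampled; ",
      "coverage classes are only comparable at a common depth"
    ))
  }
  cnt <- counts$bins$count
  cls <- cut(cnt, breaks = c(-Inf, 0, 10, 1e2, 1e3, 1e4, 1e5, Inf),
             labels = coverage_classes, right = TRUE)
  frac <- as.vector(table(cls)) / length(cnt)
  tibble(sample_id = counts$sample_id,
         class = factor(coverage_classes, levels = coverage_classes),
         fraction = frac)
}

#' Quantile metagene profile over 5'UTR / CDS / 3'UTR
#'
#' Computes the gene-averaged coverage profile along length-standardized
#' mRNA coordinates. Coding genes with at least \code{min_reads} exonic
#' reads and non-empty 5'UTR, CDS and 3'UTR are used; each gene's per-nt
#' coverage (bin counts placed at bin midpoints and linearly interpolated)
#' is divided by its mean over the mRNA, so every gene carries the same
#' weight regardless of expression. Each region is rescaled to
#' \code{grid_points} positions, and the 25/50/75% quantiles across genes
#' are reported at every position. In a well-behaved IP sample the profile
#' rises sharply near the CDS/3'UTR boundary, the stop-codon enrichment
#' characteristic of m6A.
#'
#' @param counts A \code{sample_counts} object.
#' @param models The \code{gene_models} used for counting.
#' @param min_reads Minimum exonic reads for a gene to enter (default 10;
#'   genes below the threshold are treated as not reliably detected).
#' @param grid_points Grid positions per region (default 100).
#' @return A tibble of class \code{metagene_profile} with columns
#'   \code{position} (1 .. 3*grid_points), \code{region}, \code{q25},
#'   \code{q50}, \code{q75}; attributes \code{n_genes_used} and
#'   \code{region_median_lengths}.
#' @export
metagene_profile <- function(counts, models, min_reads = 10L,
                             grid_points = 100L) {
  stopifnot(inherits(counts, "sample_counts"))
  info <- models |> as_tibble() |>
    select("gene_id", "mrna_length", "cds_start", "cds_end", "coding")
  gene_tot <- counts$bins |>
    group_by(.data$gene_id) |>
    summarise(total = sum(.data$count), .groups = "drop")
  use <- info |>
    left_join(gene_tot, by = "gene_id") |>
    mutate(total = tidyr::replace_na(.data$total, 0L)) |>
    filter(.data$coding,
           .data$cds_start > 0L,
           .data$cds_end > .data$cds_start,
           .data$mrna_length > .data$cds_end,
           .data$total >= min_reads)
  if (nrow(use) == 0L) {
    qc_stop(sprintf("no coding gene has >= %d reads", min_reads),
            "filter_error")
  }

  bins_by_gene <- split(counts$bins, counts$bins$gene_id)
  curves <- purrr::pmap(
    list(use$gene_id, use$mrna_length, use$cds_start, use$cds_end,
         use$total),
    function(gid, len, cs, ce, tot) {
      b <- bins_by_gene[[gid]]
      mids <- (b$tx_start + b$tx_end) / 2
      val <- (b$count / b$width) / (tot / len)
      interp <- function(a, bnd) {
        xout <- a + (bnd - a) * (seq_len(grid_points) - 0.5) / grid_points
        if (length(mids) == 1L) return(rep(val, grid_points))
        stats::approx(mids, val, xout = xout, rule = 2)$y
      }
      c(interp(0, cs), interp(cs, ce), interp(ce, len))
    }
  )
  mat <- do.call(rbind, curves)
  qs <- apply(mat, 2, stats::quantile, probs = c(0.25, 0.5, 0.75),
              names = FALSE)
  out <- tibble(
    position = seq_len(3L * grid_points),
    region = factor(rep(c("utr5", "cds", "utr3"), each = grid_points),
                    levels = c("utr5", "cds", "utr3")),
    q25 = qs[1, ], q50 = qs[2, ], q75 = qs[3, ]
  )
  attr(out, "n_genes_used") <- nrow(use)
  attr(out, "region_median_lengths") <- c(
    utr5 = stats::median(use$cds_start),
    cds = stats::median(use$cds_end - use$cds_start),
    utr3 = stats::median(use$mrna_length - use$cds_end)
  )
  attr(out, "sample_id") <- counts$sample_id
  class(out) <- c("metagene_profile", class(tibble()))
  out
}

#' @rdname metagene_profile
#' @param object A \code{metagene_profile}.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.metagene_profile <- function(object, ...) {
  grid_points <- nrow(object) / 3L
  long <- tidyr::pivot_longer(as_tibble(object), c("q25", "q50", "q75"),
                              names_to = "quantile", values_to = "coverage")
  ggplot2::ggplot(long, ggplot2::aes(.data$position, .data$coverage,
                                     colour = .data$quantile)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(grid_points, 2 * grid_points) + 0.5,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_x_continuous(
      breaks = grid_points * c(0.5, 1.5, 2.5),
      labels = c("5'UTR", "CDS", "3'UTR")
    ) +
    ggplot2::labs(
      title = sprintf("Metagene profile: %s",
                      attr(object, "sample_id") %||% ""),
      x = NULL, y = "standardized coverage", colour = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot coverage-class histograms for several samples
#'
#' @param histograms A tibble from [coverage_histogram()] (rows from several
#'   samples may be bound together).
#' @return A ggplot object.
#' @export
plot_coverage_histogram <- function(histograms) {
  ggplot2::ggplot(histograms,
                  ggplot2::aes(.data$class, .data$fraction,
                               fill = .data$sample_id)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "reads per bin", y = "fraction of bins",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
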