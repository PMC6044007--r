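#' Reference ranges for good-quality m6A-seq samples
#'
#' Closed intervals of the three headline ESES metrics observed on a
#' published survey of 61 good-quality m6A-seq IP samples (with matched
#' Inputs) from high-impact studies: enriched region 12--25% of bins, scale
#' factor 0.08--0.3, signal read count 87--95%. Samples outside these
#' ranges are not necessarily broken -- other modifications (e.g. m1A)
#' legitimately fall outside the m6A regime -- but deserve inspection.
#' Users may supply their own ranges to [assess_quality()].
#'
#' @format A tibble with columns \code{metric}, \code{lower}, \code{upper}
#'   and \code{unit}.
#' @export
qc_reference_ranges <- tibble::tibble(
  metric = c("enriched_region_pct", "scale_factor", "signal_read_pct"),
  lower = c(12, 0.08, 87),
  upper = c(25, 0.3, 95),
  unit = c("percent of bins", "max |q - p|",
           "percent of cumulated IP signal")
)

#' Compare ESES metrics against reference ranges
#'
#' Converts per-sample ESES metrics to their reporting units (percentages
#' for enriched region and signal reads) and flags each metric as within,
#' below or above its reference interval. Interval membership is closed:
#' boundary values count as within.
#'
#' @param metrics A tibble with columns \code{sample_id},
#'   \code{enriched_fraction}, \code{scale_factor} and
#'   \code{signal_read_fraction} (fractions in [0, 1]), e.g. bound
#'   [glance()] rows of [compute_eses()] results.
#' @param ranges Reference ranges (default [qc_reference_ranges]).
#' @return A tibble with one row per sample and metric: \code{sample_id},
#'   \code{metric}, \code{value}, \code{lower}, \code{upper},
#'   \code{status} (within/below/above) and \code{overall} (TRUE when all
#'   of the sample's metrics are within range).
#' @export
assess_quality <- function(metrics, ranges = qc_reference_ranges) {
  stopifnot(all(c("sample_id", "enriched_fraction", "scale_factor",
                  "signal_read_fraction") %in% names(metrics)))
  long <- metrics |>
    transmute(
      sample_id = .data$sample_id,
      enriched_region_pct = 100 * .data$enriched_fraction,
      scale_factor = .data$scale_factor,
      signal_read_pct = 100 * .data$signal_read_fraction
    ) |>
    tidyr::pivot_longer(-"sample_id", names_to = "metric",
                        values_to = "value") |>
    left_join(ranges[, c("metric", "lower", "upper")], by = "metric") |>
    mutate(status = dplyr::case_when(
      .data$value < .data$lower ~ "below",
      .data$value > .data$upper ~ "above",
      TRUE ~ "within"
    )) |>
    group_by(.data$sample_id) |>
    mutate(overall = all(.data$status == "within")) |>
    ungroup()
  long
}

# Run one report section, either strictly (errors propagate with section
# context) or leniently (failed sections are recorded and skipped).
run_section <- function(name, expr, strict, skipped) {
  tryCatch(
    list(value = force(expr), skipped = skipped),
    error = function(e) {
      if (strict) {
        qc_stop(sprintf("section '%s' failed: %s", name,
                        conditionMessage(e)), "section_error")
      }
      skipped[[name]] <- conditionMessage(e)
      list(value = NULL, skipped = skipped)
    }
  )
}

#' Run the full quality-assessment pipeline
#'
#' Executes annotation parsing, read counting (with optional down-sampling),
#' region/coverage/metagene statistics, per-IP ESES and C-test enrichment
#' analyses against the merged Input, multi-sample normalization with
#' hierarchical clustering, PCA, mean-SD heterogeneity and replicate
#' consistency, and verdicts against the packaged reference ranges. Writes
#' a self-contained HTML report, a machine-readable JSON summary whose
#' numbers agree with the HTML tables, tab-separated metric tables, figures
#' and a Newick dendrogram into \code{out_dir}. Fully deterministic for a
#' fixed seed and configuration.
#'
#' @param ip_bams,input_bams Character vectors of BAM paths (each with
#'   index); at least one of each.
#' @param gtf Path to the GTF annotation.
#' @param out_dir Output directory (created if needed).
#' @param bin_width mRNA bin width in nt (default 200).
#' @param downsample Optional common depth; each sample is down-sampled to
#'   it before assignment.
#' @param seed Integer seed for all random draws.
#' @param alpha,fold_grid C-test parameters.
#' @param mapq Minimum mapping quality.
#' @param min_gene_reads Per-gene detection threshold for ESES/metagene.
#' @param strict When TRUE (default) any section error aborts the run;
#'   when FALSE failed non-fatal sections are marked skipped with their
#'   reason.
#' @param ranges Reference ranges for verdicts.
#' @return Invisibly, a list of class \code{qc_report} with every computed
#'   object, the skipped-section record and the output paths.
#' @export
run_pipeline <- function(ip_bams, input_bams, gtf, out_dir,
                         bin_width = 200L, downsample = NULL, seed = 1L,
                         alpha = 0.05,
                         fold_grid = c(1, 1.5, 2, 2.5, 3, 3.5, 4),
                         mapq = 0L, min_gene_reads = 10L, strict = TRUE,
                         ranges = qc_reference_ranges) {
  if (length(ip_bams) < 1L || length(input_bams) < 1L) {
    qc_stop("need at least one IP and one Input BAM", "config_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fig_dir <- file.path(out_dir, "figures")
  dir.create(fig_dir, showWarnings = FALSE)
  skipped <- list()

  models <- read_gene_models(gtf)
  bins <- build_bins(models, bin_width)

  bams <- c(ip_bams, input_bams)
  roles <- c(rep("IP", length(ip_bams)), rep("Input", length(input_bams)))
  counts <- vector("list", length(bams))
  for (i in seq_along(bams)) {
    counts[[i]] <- count_reads(bams[i], models, bins, role = roles[i],
                               down_to = downsample, seed = seed + i,
                               mapq = mapq)
  }
  ids <- vapply(counts, function(x) x$sample_id, character(1))
  names(counts) <- ids
  ip_ids <- ids[roles == "IP"]
  input_ids <- ids[roles == "Input"]

  stats_tbl <- region_stats(counts)

  # coverage histogram at a common depth
  sec <- run_section("coverage_histogram", {
    common <- min(vapply(counts, function(x) x$total_reads, integer(1)))
    purrr::imap(counts, function(x, nm) {
      eq <- downsample_counts(x, common, seed = seed)
      coverage_histogram(eq, warn_depth = FALSE)
    }) |> bind_rows()
  }, strict, skipped)
  hist_tbl <- sec$value
  skipped <- sec$skipped

  merged <- merge_inputs(counts[input_ids])

  sec <- run_section("eses", {
    purrr::map(counts[ip_ids], function(x) {
      compute_eses(normalize_gene_bins(x, merged,
                                       min_gene_reads = min_gene_reads))
    })
  }, strict, skipped)
  eses <- sec$value
  skipped <- sec$skipped

  sec <- run_section("ctest", {
    purrr::map(counts[ip_ids], function(x) {
      ctest_profile(x, merged, fold_grid = fold_grid, alpha = alpha)
    })
  }, strict, skipped)
  ctests <- sec$value
  skipped <- sec$skipped

  sec <- run_section("metagene", {
    purrr::map(counts, function(x) {
      metagene_profile(x, models, min_reads = min_gene_reads)
    })
  }, strict, skipped)
  metagenes <- sec$value
  skipped <- sec$skipped

  sec <- run_section("multisample", {
    norm <- normalize_matrix(counts)
    hc <- cluster_samples(norm)
    pca <- pca_samples(norm)
    msd <- purrr::map(counts, gene_mean_sd)
    cons <- list()
    if (length(ip_ids) >= 2L) {
      cons$IP <- replicate_consistency(norm, ip_ids)
    }
    if (length(input_ids) >= 2L) {
      cons$Input <- replicate_consistency(norm, input_ids)
    }
    list(norm = norm, hc = hc, pca = pca, mean_sd = msd,
         consistency = cons)
  }, strict, skipped)
  multi <- sec$value
  skipped <- sec$skipped

  verdicts <- NULL
  if (!is.null(eses)) {
    metrics <- purrr::imap(eses, function(e, nm) {
      bind_cols(tibble(sample_id = nm), glance(e))
    }) |> bind_rows()
    verdicts <- assess_quality(metrics, ranges = ranges)
  }

  report <- structure(
    list(
      params = list(
        ip_bams = ip_bams, input_bams = input_bams, gtf = gtf,
        bin_width = bin_width, downsample = downsample, seed = seed,
        alpha = alpha, fold_grid = fold_grid, mapq = mapq,
        min_gene_reads = min_gene_reads,
        package_version = as.character(utils::packageVersion("meripqc"))
      ),
      counts = counts, region_stats = stats_tbl,
      coverage_histogram = hist_tbl, eses = eses, ctest = ctests,
      metagene = metagenes, multisample = multi, verdicts = verdicts,
      skipped = skipped, out_dir = out_dir
    ),
    class = "qc_report"
  )
  write_report_outputs(report)
  invisible(report)
}

# Serialize tables, figures, JSON and HTML for a qc_report.
write_report_outputs <- function(report) {
  out_dir <- report$out_dir
  fig_dir <- file.path(out_dir, "figures")
  wt <- function(df, name) {
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  wt(report$region_stats, "region_stats.tsv")
  if (!is.null(report$coverage_histogram)) {
    wt(report$coverage_histogram, "coverage_histogram.tsv")
  }
  eses_tbl <- NULL
  if (!is.null(report$eses)) {
    eses_tbl <- purrr::imap(report$eses, function(e, nm) {
      bind_cols(tibble(sample_id = nm), glance(e))
    }) |> bind_rows()
    wt(eses_tbl, "eses_metrics.tsv")
  }
  ctest_tbl <- NULL
  if (!is.null(report$ctest)) {
    ctest_tbl <- purrr::imap(report$ctest, function(p, nm) {
      bind_cols(tibble(sample_id = nm), as_tibble(p))
    }) |> bind_rows()
    wt(ctest_tbl, "ctest_profile.tsv")
  }
  if (!is.null(report$verdicts)) wt(report$verdicts, "verdicts.tsv")
  if (!is.null(report$multisample)) {
    wt(report$multisample$pca$scores, "pca_scores.tsv")
    writeLines(attr(report$multisample$hc, "newick"),
               file.path(out_dir, "dendrogram.nwk"))
  }

  figures <- character(0)
  save_fig <- function(plot_obj, name, base = FALSE, width = 7,
                       height = 4.5) {
    path <- file.path(fig_dir, name)
    ok <- tryCatch({
      if (base) {
        grDevices::png(path, width = width * 100, height = height * 100,
                       res = 100)
        plot_obj()
        grDevices::dev.off()
      } else {
        ggplot2::ggsave(path, plot_obj, width = width, height = height,
                        dpi = 100)
      }
      TRUE
    }, error = function(e) FALSE)
    if (ok) figures[[name]] <<- path
    invisible(ok)
  }
  if (!is.null(report$eses)) {
    for (nm in names(report$eses)) {
      save_fig(autoplot(report$eses[[nm]]) +
                 ggplot2::ggtitle(sprintf("ESES: %s", nm)),
               sprintf("eses_%s.png", nm))
    }
  }
  if (!is.null(report$ctest) && length(report$ctest) > 0) {
    ct <- purrr::imap(report$ctest, function(p, nm) {
      bind_cols(tibble(sample_id = nm), as_tibble(p))
    }) |> bind_rows()
    pl <- ggplot2::ggplot(ct, ggplot2::aes(.data$fold,
                                           100 * .data$proportion,
                                           colour = .data$sample_id)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "fold-enrichment threshold",
                    y = "% of bins enriched", colour = NULL) +
      ggplot2::theme_minimal()
    save_fig(pl, "ctest_profile.png")
  }
  if (!is.null(report$metagene)) {
    for (nm in names(report$metagene)) {
      save_fig(autoplot(report$metagene[[nm]]) +
                 ggplot2::ggtitle(sprintf("Metagene: %s", nm)),
               sprintf("metagene_%s.png", nm))
    }
  }
  if (!is.null(report$coverage_histogram)) {
    save_fig(plot_coverage_histogram(report$coverage_histogram),
             "coverage_histogram.png")
  }
  if (!is.null(report$multisample)) {
    hc <- report$multisample$hc
    save_fig(function() plot(hc, main = "Sample clustering",
                             xlab = "", sub = ""),
             "dendrogram.png", base = TRUE)
    save_fig(autoplot(report$multisample$pca), "pca.png")
    save_fig(plot_fitted_curves(report$multisample$mean_sd) +
               ggplot2::labs(title = "Gene-level mean-SD heterogeneity"),
             "mean_sd.png")
    if (length(report$multisample$consistency) > 0) {
      save_fig(plot_fitted_curves(report$multisample$consistency) +
                 ggplot2::labs(title = "Replicate consistency"),
               "consistency.png")
    }
  }

  summary <- list(
    parameters = report$params,
    skipped_sections = report$skipped,
    region_stats = report$region_stats,
    coverage_histogram = report$coverage_histogram,
    eses = eses_tbl,
    ctest = ctest_tbl,
    size_factors = if (!is.null(report$multisample)) {
      as.list(report$multisample$norm$size_factors)
    },
    pca = if (!is.null(report$multisample)) {
      list(scores = report$multisample$pca$scores,
           explained = report$multisample$pca$explained)
    },
    metagene = if (!is.null(report$metagene)) {
      purrr::imap(report$metagene, function(m, nm) {
        list(n_genes_used = attr(m, "n_genes_used"),
             q75_peak_position = as.integer(which.max(m$q75)))
      })
    },
    verdicts = report$verdicts
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  render_html_report(report, eses_tbl, ctest_tbl, figures,
                     file.path(out_dir, "report.html"))
  invisible(report)
}

# Minimal self-contained HTML writer: metric tables plus base64-embedded
# figures. Numbers are printed at full precision so that the HTML tables
# and summary.json agree exactly.
render_html_report <- function(report, eses_tbl, ctest_tbl, figures,
                               path) {
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  fmt <- function(x) {
    if (is.numeric(x)) {
      vapply(x, function(v) {
        if (is.na(v)) "NA" else format(v, digits = 15, scientific = FALSE)
      }, character(1))
    } else {
      esc(as.character(x))
    }
  }
  html_table <- function(df) {
    head <- paste0("<tr>", paste0("<th>", esc(names(df)), "</th>",
                                  collapse = ""), "</tr>")
    body <- apply(as.data.frame(lapply(df, fmt)), 1, function(r) {
      paste0("<tr>", paste0("<td>", r, "</td>", collapse = ""), "</tr>")
    })
    paste0("<table>", head, paste(body, collapse = ""), "</table>")
  }
  img <- function(name) {
    if (!name %in% names(figures)) return("")
    uri <- base64enc::dataURI(file = figures[[name]], mime = "image/png")
    sprintf("<img src=\"%s\" alt=\"%s\"/>", uri, name)
  }
  section <- function(title, ...) {
    paste0("<h2>", esc(title), "</h2>", paste0(..., collapse = ""))
  }
  p <- report$params
  parts <- c(
    "<!DOCTYPE html><html><head><meta charset=\"utf-8\"/>",
    "<title>MeRIP-seq quality assessment</title>",
    "<style>body{font-family:sans-serif;max-width:1100px;margin:auto}",
    "table{border-collapse:collapse;margin:1em 0}",
    "td,th{border:1px solid #999;padding:3px 8px;font-size:13px}",
    "img{max-width:100%}</style></head><body>",
    "<h1>MeRIP-seq quality assessment report</h1>",
    section("Run configuration", html_table(tibble(
      parameter = c("IP BAMs", "Input BAMs", "GTF", "bin width (nt)",
                    "down-sampling depth", "seed", "alpha", "fold grid",
                    "min MAPQ", "min gene reads", "package version"),
      value = c(paste(basename(p$ip_bams), collapse = ", "),
                paste(basename(p$input_bams), collapse = ", "),
                basename(p$gtf), as.character(p$bin_width),
                if (is.null(p$downsample)) "none"
                else as.character(p$downsample),
                as.character(p$seed), as.character(p$alpha),
                paste(p$fold_grid, collapse = ", "),
                as.character(p$mapq), as.character(p$min_gene_reads),
                p$package_version)
    )))
  )
  if (length(report$skipped) > 0) {
    parts <- c(parts, section("Skipped sections", html_table(tibble(
      section = names(report$skipped),
      reason = unlist(report$skipped)
    ))))
  }
  parts <- c(parts, section("Reads by genomic region",
                            html_table(report$region_stats)))
  if (!is.null(report$coverage_histogram)) {
    wide <- tidyr::pivot_wider(report$coverage_histogram,
                               names_from = "class",
                               values_from = "fraction")
    parts <- c(parts, section("Exonic coverage classes",
                              html_table(wide),
                              img("coverage_histogram.png")))
  }
  if (!is.null(eses_tbl)) {
    parts <- c(parts, section(
      "Immunoprecipitation efficiency (ESES)", html_table(eses_tbl),
      paste0(vapply(rownames_or(report$eses), function(nm) {
        img(sprintf("eses_%s.png", nm))
      }, character(1)), collapse = "")
    ))
  }
  if (!is.null(ctest_tbl)) {
    parts <- c(parts, section("C-test enrichment profile",
                              html_table(ctest_tbl),
                              img("ctest_profile.png")))
  }
  if (!is.null(report$metagene)) {
    parts <- c(parts, section(
      "Metagene profiles",
      paste0(vapply(rownames_or(report$metagene), function(nm) {
        img(sprintf("metagene_%s.png", nm))
      }, character(1)), collapse = "")
    ))
  }
  if (!is.null(report$multisample)) {
    parts <- c(parts, section(
      "Multi-sample comparison",
      html_table(tibble(
        sample_id = names(report$multisample$norm$size_factors),
        size_factor = unname(report$multisample$norm$size_factors),
        raw_total = unname(report$multisample$norm$raw_totals)
      )),
      img("dendrogram.png"), img("pca.png"), img("mean_sd.png"),
      img("consistency.png")
    ))
  }
  if (!is.null(report$verdicts)) {
    parts <- c(parts, section("Verdicts against reference ranges",
                              html_table(report$verdicts)))
  }
  parts <- c(parts, "</body></html>")
  writeLines(paste0(parts, collapse = "\n"), path)
  invisible(path)
}

rownames_or <- function(x) if (is.null(names(x))) character(0) else names(x)

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d samples | output: %s\n",
              length(x$counts), x$out_dir))
  if (!is.null(x$verdicts)) {
    bad <- unique(x$verdicts$sample_id[!x$verdicts$overall])
    if (length(bad) > 0) {
      cat("  flagged samples:", paste(bad, collapse = ", "), "\n")
    } else {
      cat("  all IP samples within reference ranges\n")
    }
  }
  if (length(x$skipped) > 0) {
    cat("  skipped sections:", paste(names(x$skipped), collapse = ", "),
        "\n")
  }
  invisible(x)
}
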