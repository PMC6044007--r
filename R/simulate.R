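#' Describe a synthetic MeRIP-seq experiment
#'
#' Builds the parameter object for the synthetic-data generator. The
#' generator emits a toy transcriptome (GTF), per-sample coordinate-sorted
#' and indexed BAM files, and truth tables, with methylation peaks planted
#' near stop codons so every quality metric can be evaluated against known
#' ground truth.
#'
#' IP reads over-sample methylated bins by \code{peak_fold}; Input reads
#' follow gene abundance alone. Reads are single-end, ungapped, fixed length
#' \code{read_length}, MAPQ 60. Artifact modes emulate common failure cases:
#' \code{"pcr_dup"} duplicates a small subset of reads with geometric
#' (jackpot-like) copy counts,
#' \code{"three_prime_bias"} tilts within-gene sampling toward 3' ends, and
#' \code{"swap"} exchanges the IP and Input roles.
#'
#' @param n_genes Number of genes (default 50).
#' @param utr5_range,cds_range,utr3_range Length ranges (nt) for each mRNA
#'   segment; CDS lengths are rounded to codon multiples.
#' @param frac_noncoding Fraction of genes emitted without CDS records.
#' @param n_introns_range,intron_range Number and length ranges of introns.
#' @param expr_meanlog,expr_sdlog Log-normal gene-abundance parameters.
#' @param peak_fraction Fraction of mRNA bins carrying methylation.
#' @param peak_fold IP enrichment multiplier on methylated bins (>= 1).
#' @param peak_offset_bins Peaks are placed within this many bins of the
#'   bin containing the stop codon (0 = exactly that bin).
#' @param depth Reads per sample.
#' @param bin_width Bin width (nt) used to plant per-bin methylation.
#' @param read_length Read length (nt).
#' @param ip_intron_rate,ip_nongenic_rate Background read rates for IP
#'   samples (remainder is exonic).
#' @param input_intron_rate,input_nongenic_rate Background rates for Input.
#' @param artifact_mode One of \code{"none"}, \code{"pcr_dup"},
#'   \code{"three_prime_bias"}, \code{"swap"}.
#' @param dup_fraction,dup_geom_prob PCR-duplication parameters.
#' @param bias_strength Exponential 3'-bias strength.
#' @param n_ip,n_input Number of IP and Input samples.
#' @param seed Integer seed; the whole dataset is deterministic given it.
#' @return A list of class \code{simulation_spec}.
#' @export
simulation_spec <- function(n_genes = 50L,
                            utr5_range = c(100L, 300L),
                            cds_range = c(600L, 1500L),
                            utr3_range = c(300L, 800L),
                            frac_noncoding = 0.1,
                            n_introns_range = c(0L, 3L),
                            intron_range = c(200L, 2000L),
                            expr_meanlog = log(50),
                            expr_sdlog = 1,
                            peak_fraction = 0.1,
                            peak_fold = 8,
                            peak_offset_bins = 2L,
                            depth = 50000L,
                            bin_width = 200L,
                            read_length = 50L,
                            ip_intron_rate = 0.05,
                            ip_nongenic_rate = 0.46,
                            input_intron_rate = 0.03,
                            input_nongenic_rate = 0.55,
                            artifact_mode = c("none", "pcr_dup",
                                              "three_prime_bias", "swap"),
                            dup_fraction = 0.05,
                            dup_geom_prob = 0.05,
                            bias_strength = 2,
                            n_ip = 1L,
                            n_input = 1L,
                            seed = 1L) {
  artifact_mode <- match.arg(artifact_mode)
  spec <- list(
    n_genes = as.integer(n_genes), utr5_range = utr5_range,
    cds_range = cds_range, utr3_range = utr3_range,
    frac_noncoding = frac_noncoding,
    n_introns_range = n_introns_range, intron_range = intron_range,
    expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
    peak_fraction = peak_fraction, peak_fold = peak_fold,
    peak_offset_bins = as.integer(peak_offset_bins),
    depth = as.integer(depth), bin_width = as.integer(bin_width),
    read_length = as.integer(read_length),
    ip_intron_rate = ip_intron_rate, ip_nongenic_rate = ip_nongenic_rate,
    input_intron_rate = input_intron_rate,
    input_nongenic_rate = input_nongenic_rate,
    artifact_mode = artifact_mode, dup_fraction = dup_fraction,
    dup_geom_prob = dup_geom_prob, bias_strength = bias_strength,
    n_ip = as.integer(n_ip), n_input = as.integer(n_input),
    seed = as.integer(seed)
  )
  validate_simulation_spec(spec)
  class(spec) <- "simulation_spec"
  spec
}

validate_simulation_spec <- function(spec) {
  fr <- c(spec$peak_fraction, spec$frac_noncoding, spec$dup_fraction,
          spec$ip_intron_rate, spec$ip_nongenic_rate,
          spec$input_intron_rate, spec$input_nongenic_rate)
  if (any(fr < 0 | fr > 1)) qc_stop("fractions must lie in [0, 1]", "spec_error")
  if (spec$peak_fold < 1) qc_stop("peak_fold must be >= 1", "spec_error")
  if (spec$depth < 1) qc_stop("depth must be >= 1", "spec_error")
  if (min(spec$cds_range) < 3) qc_stop("CDS shorter than a codon", "spec_error")
  if (spec$ip_intron_rate + spec$ip_nongenic_rate >= 1 ||
      spec$input_intron_rate + spec$input_nongenic_rate >= 1) {
    qc_stop("background rates leave no exonic reads", "spec_error")
  }
  invisible(spec)
}

# Uniform integer draw(s) on [lo, hi]; safe when lo == hi (unlike sample()).
runif_int <- function(lo, hi, n = 1L) {
  lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

# Map transcript single-base positions to genomic positions for one gene.
tx_pos_to_genome <- function(exons, strand, txpos) {
  widths <- exons$end - exons$start
  L <- sum(widths)
  p <- if (identical(strand, "-")) L - 1L - txpos else txpos
  offs <- cumsum(c(0L, widths))[seq_len(nrow(exons))]
  idx <- findInterval(p, offs)
  as.integer(exons$start[idx] + (p - offs[idx]))
}

# Build the toy transcriptome: gene models on one chromosome, gene
# abundances, planted methylated bins. Deterministic given spec$seed.
simulate_transcriptome <- function(spec) {
  withr::with_seed(spec$seed, {
    margin <- 2000L
    cursor <- margin
    rows <- vector("list", spec$n_genes)
    for (g in seq_len(spec$n_genes)) {
      gid <- sprintf("g%03d", g)
      u5 <- runif_int(spec$utr5_range[1], spec$utr5_range[2])
      cds <- runif_int(spec$cds_range[1], spec$cds_range[2])
      cds <- cds - cds %% 3L
      u3 <- runif_int(spec$utr3_range[1], spec$utr3_range[2])
      L <- u5 + cds + u3
      strand <- sample(c("+", "-"), 1L)
      coding <- stats::runif(1) >= spec$frac_noncoding
      n_int <- runif_int(spec$n_introns_range[1], spec$n_introns_range[2])
      n_int <- min(n_int, L - 1L)
      cuts <- if (n_int > 0L) sort(sample(seq_len(L - 1L), n_int)) else integer(0)
      piece_len <- diff(c(0L, cuts, L))
      introns <- if (n_int > 0L) {
        runif_int(spec$intron_range[1], spec$intron_range[2], n_int)
      } else integer(0)
      # genomic layout: tx pieces left-to-right on '+', reversed on '-'
      glens <- if (strand == "-") rev(piece_len) else piece_len
      gints <- if (strand == "-") rev(introns) else introns
      starts <- cursor + cumsum(c(0L, glens[-length(glens)] +
                                    if (n_int > 0L) gints else integer(0)))
      exons <- tibble(start = as.integer(starts),
                      end = as.integer(starts + glens))
      gene_end <- max(exons$end)
      cursor <- gene_end + runif_int(2000L, 5000L)
      rows[[g]] <- tibble(
        gene_id = gid, chrom = "chrS", strand = strand,
        n_exons = nrow(exons), exons = list(exons),
        mrna_length = as.integer(L),
        cds_start = if (coding) as.integer(u5) else NA_integer_,
        cds_end = if (coding) as.integer(u5 + cds) else NA_integer_,
        coding = coding
      )
    }
    models <- bind_rows(rows)
    class(models) <- c("gene_models", class(tibble()))
    chrom_len <- cursor + margin

    abundance <- stats::rlnorm(spec$n_genes, spec$expr_meanlog, spec$expr_sdlog)
    genes <- tibble(gene_id = models$gene_id, abundance = abundance,
                    coding = models$coding)

    bins <- build_bins(models, spec$bin_width)
    bins_truth <- as_tibble(bins) |>
      left_join(models |> as_tibble() |>
                  select("gene_id", "cds_end", "coding"),
                by = "gene_id")
    # candidate peak bins: within peak_offset_bins of the stop-codon bin
    bins_truth <- bins_truth |>
      group_by(.data$gene_id) |>
      mutate(stop_bin = if (.data$coding[1]) {
        which(.data$tx_start <= .data$cds_end[1] - 1L &
                .data$cds_end[1] - 1L < .data$tx_end)[1]
      } else NA_integer_) |>
      ungroup() |>
      mutate(candidate = .data$coding & !is.na(.data$stop_bin) &
               abs(.data$bin - .data$stop_bin) <= spec$peak_offset_bins)
    n_peak <- round(spec$peak_fraction * nrow(bins_truth))
    cand_idx <- which(bins_truth$candidate)
    n_peak <- min(n_peak, length(cand_idx))
    # round-robin across genes: every coding gene receives its stop-codon
    # proximal peak before any gene receives a second one (m6A methylation
    # is a gene-level phenomenon, not i.i.d. over bins)
    peak_idx <- if (n_peak > 0L) {
      cand <- tibble(idx = cand_idx,
                     gene_id = bins_truth$gene_id[cand_idx])
      cand <- cand[sample.int(nrow(cand)), ]
      cand <- cand |>
        group_by(.data$gene_id) |>
        mutate(round = dplyr::row_number()) |>
        ungroup()
      gene_order <- sample(unique(cand$gene_id))
      cand <- cand[order(cand$round, match(cand$gene_id, gene_order)), ]
      cand$idx[seq_len(n_peak)]
    } else {
      integer(0)
    }
    bins_truth$methylated <- FALSE
    bins_truth$methylated[peak_idx] <- TRUE
    bins_truth$true_fold <- ifelse(bins_truth$methylated, spec$peak_fold, 1)
    bins_truth <- bins_truth |>
      select("gene_id", "bin", "tx_start", "tx_end", "width",
             "methylated", "true_fold")

    list(models = models, genes = genes, bins = bins,
         bins_truth = bins_truth, chrom_len = as.integer(chrom_len))
  })
}

# Simulate the reads of one sample. `distribution_role` picks the sampling
# model (IP vs Input); the emitted role label may differ under swap.
simulate_sample_reads <- function(tx, spec, sample_id, distribution_role,
                                  seed, artifact_mode = "none") {
  withr::with_seed(seed, {
    models <- tx$models
    rl <- spec$read_length
    half <- rl %/% 2L
    is_ip <- identical(distribution_role, "IP")
    intron_rate <- if (is_ip) spec$ip_intron_rate else spec$input_intron_rate
    nongenic_rate <- if (is_ip) spec$ip_nongenic_rate else spec$input_nongenic_rate

    n_region <- as.vector(stats::rmultinom(
      1, spec$depth,
      c(exon = 1 - intron_rate - nongenic_rate,
        intron = intron_rate, nongenic = nongenic_rate)
    ))
    names(n_region) <- c("exon", "intron", "nongenic")

    # exonic reads: multinomial over bins
    bt <- tx$bins_truth |>
      left_join(tx$genes, by = "gene_id") |>
      left_join(models |> as_tibble() |>
                  select("gene_id", "mrna_length", "cds_start", "cds_end"),
                by = "gene_id")
    w <- bt$abundance * bt$width
    if (is_ip) w <- w * bt$true_fold
    if (identical(artifact_mode, "three_prime_bias")) {
      rel <- (bt$tx_start + bt$tx_end) / 2 / bt$mrna_length
      w <- w * exp(spec$bias_strength * rel)
    }
    bin_draw <- as.vector(stats::rmultinom(1, n_region[["exon"]], w))
    exon_rows <- rep.int(seq_len(nrow(bt)), bin_draw)
    tx_mid <- bt$tx_start[exon_rows] +
      floor(stats::runif(length(exon_rows)) *
              (bt$tx_end[exon_rows] - bt$tx_start[exon_rows]))
    gidx <- match(bt$gene_id[exon_rows], models$gene_id)
    gmid <- integer(length(exon_rows))
    for (gi in unique(gidx)) {
      sel <- gidx == gi
      gmid[sel] <- tx_pos_to_genome(models$exons[[gi]], models$strand[[gi]],
                                    tx_mid[sel])
    }
    subregion <- rep("none", length(exon_rows))
    cs <- bt$cds_start[exon_rows]
    ce <- bt$cds_end[exon_rows]
    cod <- !is.na(cs)
    subregion[cod & tx_mid < cs] <- "utr5"
    subregion[cod & tx_mid >= cs & tx_mid < ce] <- "cds"
    subregion[cod & tx_mid >= ce] <- "utr3"
    exon_reads <- tibble(
      region = "exon", gene_id = bt$gene_id[exon_rows],
      bin = bt$bin[exon_rows], subregion = subregion,
      mid = gmid
    )

    # intron reads: uniform over the pooled intronic space
    intr <- purrr::pmap(
      list(models$gene_id, models$exons),
      function(gid, ex) {
        if (nrow(ex) < 2L) return(NULL)
        tibble(gene_id = gid, start = ex$end[-nrow(ex)], end = ex$start[-1])
      }
    ) |> bind_rows()
    if (!is.null(intr) && nrow(intr) > 0L && n_region[["intron"]] > 0L) {
      pick <- sample.int(nrow(intr), n_region[["intron"]], replace = TRUE,
                         prob = intr$end - intr$start)
      imid <- intr$start[pick] +
        floor(stats::runif(n_region[["intron"]]) *
                (intr$end[pick] - intr$start[pick]))
      intron_reads <- tibble(region = "intron", gene_id = intr$gene_id[pick],
                             bin = NA_integer_, subregion = NA_character_,
                             mid = as.integer(imid))
    } else {
      n_region[["nongenic"]] <- n_region[["nongenic"]] + n_region[["intron"]]
      intron_reads <- tibble(region = character(), gene_id = character(),
                             bin = integer(), subregion = character(),
                             mid = integer())
    }

    # nongenic reads: uniform over intergenic gaps (away from chrom ends)
    bodies <- models |> as_tibble() |>
      mutate(b_start = purrr::map_int(.data$exons, ~ min(.x$start)),
             b_end = purrr::map_int(.data$exons, ~ max(.x$end))) |>
      arrange(.data$b_start)
    gap_start <- c(rl, bodies$b_end + 1L)
    gap_end <- c(bodies$b_start - 1L, tx$chrom_len - rl)
    gaps <- tibble(start = gap_start, end = gap_end) |>
      filter(.data$end - .data$start > 2L * rl)
    pick <- sample.int(nrow(gaps), n_region[["nongenic"]], replace = TRUE,
                       prob = gaps$end - gaps$start)
    nmid <- gaps$start[pick] +
      floor(stats::runif(n_region[["nongenic"]]) *
              (gaps$end[pick] - gaps$start[pick]))
    nongenic_reads <- tibble(region = "nongenic", gene_id = NA_character_,
                             bin = NA_integer_, subregion = NA_character_,
                             mid = as.integer(nmid))

    reads <- bind_rows(exon_reads, intron_reads, nongenic_reads)

    if (identical(artifact_mode, "pcr_dup") && nrow(reads) > 0L) {
      sel <- which(stats::runif(nrow(reads)) < spec$dup_fraction)
      copies <- stats::rgeom(length(sel), spec$dup_geom_prob)
      dup_rows <- rep.int(sel, copies)
      reads <- bind_rows(reads, reads[dup_rows, ])
    }

    reads <- reads[sample.int(nrow(reads)), ]
    reads$sample_id <- sample_id
    reads$read_id <- sprintf("%s_r%07d", sample_id, seq_len(nrow(reads)))
    reads$chrom <- "chrS"
    reads$pos0 <- reads$mid - half
    reads |>
      select("read_id", "sample_id", "chrom", "pos0", "region",
             "gene_id", "bin", "subregion", "mid")
  })
}

# Write reads as SAM text and convert to a coordinate-sorted, indexed BAM.
write_reads_bam <- function(reads, chrom_len, bam_path, read_length) {
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:chrS\tLN:%d", chrom_len))
  seq <- strrep("A", read_length)
  qual <- strrep("I", read_length)
  lines <- sprintf("%s\t0\tchrS\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                   reads$read_id, reads$pos0 + 1L, read_length, seq, qual)
  writeLines(c(header, lines), sam)
  dest <- sub("\\.bam$", "", bam_path)
  Rsamtools::asBam(sam, dest, overwrite = TRUE, indexDestination = TRUE)
  bam_path
}

# Write the transcriptome as a GTF file (one transcript per gene).
write_models_gtf <- function(models, path) {
  recs <- purrr::pmap(
    list(models$gene_id, models$chrom, models$strand, models$exons,
         models$cds_start, models$cds_end, models$coding),
    function(gid, chrom, strand, exons, cs, ce, coding) {
      ex <- tibble(chrom = chrom, start = exons$start, end = exons$end,
                   strand = strand, type = "exon", gene_id = gid,
                   phase = NA_integer_)
      if (coding) {
        cds_g <- tx_to_genome(exons, strand, cs, ce)
        w <- cds_g$end - cds_g$start
        if (identical(strand, "-")) w <- rev(w)
        before <- cumsum(c(0L, w))[seq_along(w)]
        phase <- (3L - before %% 3L) %% 3L
        if (identical(strand, "-")) phase <- rev(phase)
        ex <- bind_rows(ex, tibble(chrom = chrom, start = cds_g$start,
                                   end = cds_g$end, strand = strand,
                                   type = "CDS", gene_id = gid,
                                   phase = phase))
      }
      ex
    }
  ) |> bind_rows()
  gr <- GenomicRanges::GRanges(
    seqnames = recs$chrom,
    ranges = IRanges::IRanges(start = recs$start + 1L, end = recs$end),
    strand = recs$strand
  )
  gr$type <- recs$type
  gr$source <- "meripqc_sim"
  gr$phase <- recs$phase
  gr$gene_id <- recs$gene_id
  gr$transcript_id <- paste0(recs$gene_id, ".t1")
  rtracklayer::export(gr, path, format = "gtf")
  path
}

#' Simulate a synthetic MeRIP-seq dataset
#'
#' Generates a toy transcriptome plus IP and Input samples according to a
#' [simulation_spec()], writing a GTF, one coordinate-sorted indexed BAM per
#' sample, and tab-separated truth tables (per-read labels, per-bin
#' methylation status, per-gene abundance) into \code{dir}. Fully
#' deterministic for a fixed spec seed.
#'
#' @param spec A [simulation_spec()].
#' @param dir Output directory (created if needed).
#' @return A list with elements \code{gtf} (path), \code{samples} (tibble:
#'   \code{sample_id}, \code{role}, \code{path}, \code{distribution_role},
#'   \code{artifact_mode}), \code{truth} (list of tibbles \code{reads},
#'   \code{bins}, \code{genes}), \code{models}, \code{bin_index},
#'   \code{chrom_len} and \code{spec}.
#' @export
simulate_dataset <- function(spec, dir = tempfile("meripqc_sim_")) {
  validate_simulation_spec(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tx <- simulate_transcriptome(spec)
  gtf <- file.path(dir, "annotation.gtf")
  write_models_gtf(tx$models, gtf)

  ids <- c(sprintf("IP%d", seq_len(spec$n_ip)),
           sprintf("Input%d", seq_len(spec$n_input)))
  roles <- c(rep("IP", spec$n_ip), rep("Input", spec$n_input))
  dist_roles <- roles
  if (identical(spec$artifact_mode, "swap")) {
    dist_roles <- ifelse(roles == "IP", "Input", "IP")
  }
  mode <- if (spec$artifact_mode %in% c("pcr_dup", "three_prime_bias")) {
    spec$artifact_mode
  } else {
    "none"
  }

  all_reads <- vector("list", length(ids))
  paths <- character(length(ids))
  for (i in seq_along(ids)) {
    reads <- simulate_sample_reads(tx, spec, ids[i], dist_roles[i],
                                   seed = spec$seed + i, artifact_mode = mode)
    paths[i] <- file.path(dir, paste0(ids[i], ".bam"))
    write_reads_bam(reads, tx$chrom_len, paths[i], spec$read_length)
    all_reads[[i]] <- reads
  }
  truth_reads <- bind_rows(all_reads)

  utils::write.table(truth_reads, file.path(dir, "truth_reads.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tx$bins_truth, file.path(dir, "truth_bins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tx$genes, file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  list(
    gtf = gtf,
    samples = tibble(sample_id = ids, role = roles, path = paths,
                     distribution_role = dist_roles, artifact_mode = mode),
    truth = list(reads = truth_reads, bins = tx$bins_truth, genes = tx$genes),
    models = tx$models, bin_index = tx$bins, chrom_len = tx$chrom_len,
    spec = spec
  )
}

#' Emit the canonical synthetic fixture set
#'
#' Writes a small, fully deterministic collection of samples that exercises
#' every quality metric: three clean IP and three clean Input replicates, an
#' outlier "IP" drawn from the Input distribution, a swapped IP/Input pair,
#' and PCR-duplication and 3'-bias twins of the first IP replicate (same
#' seed, artifact mode switched on). All samples share one toy transcriptome
#' of \code{n_genes} genes; total reads stay under 200k at the default
#' depth.
#'
#' @param out_dir Output directory.
#' @param seed Master seed.
#' @param n_genes Genes in the shared transcriptome.
#' @param depth Reads per sample.
#' @return A list with \code{gtf}, \code{manifest} (tibble: sample_id, role,
#'   path, distribution_role, artifact_mode, seed), \code{truth},
#'   \code{models}, \code{bin_index} and \code{spec}.
#' @export
make_default_fixtures <- function(out_dir, seed = 1L, n_genes = 50L,
                                  depth = 15000L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- simulation_spec(n_genes = n_genes, depth = depth, seed = seed)
  tx <- simulate_transcriptome(spec)
  gtf <- file.path(out_dir, "annotation.gtf")
  write_models_gtf(tx$models, gtf)

  plan <- tibble(
    sample_id = c("IP1", "IP2", "IP3", "Input1", "Input2", "Input3",
                  "IP_outlier", "IP_swap", "Input_swap", "IP_dup", "IP_bias"),
    role = c("IP", "IP", "IP", "Input", "Input", "Input",
             "IP", "IP", "Input", "IP", "IP"),
    distribution_role = c("IP", "IP", "IP", "Input", "Input", "Input",
                          "Input", "Input", "IP", "IP", "IP"),
    artifact_mode = c(rep("none", 7), "swap", "swap",
                      "pcr_dup", "three_prime_bias"),
    seed = seed + c(1:7, 8L, 9L, 1L, 1L)
  )
  all_reads <- vector("list", nrow(plan))
  paths <- character(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    mode <- plan$artifact_mode[i]
    if (mode == "swap") mode <- "none"
    reads <- simulate_sample_reads(tx, spec, plan$sample_id[i],
                                   plan$distribution_role[i],
                                   seed = plan$seed[i], artifact_mode = mode)
    paths[i] <- file.path(out_dir, paste0(plan$sample_id[i], ".bam"))
    write_reads_bam(reads, tx$chrom_len, paths[i], spec$read_length)
    all_reads[[i]] <- reads
  }
  plan$path <- paths
  truth_reads <- bind_rows(all_reads)
  utils::write.table(plan, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth_reads, file.path(out_dir, "truth_reads.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tx$bins_truth, file.path(out_dir, "truth_bins.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(tx$genes, file.path(out_dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  list(gtf = gtf, manifest = plan,
       truth = list(reads = truth_reads, bins = tx$bins_truth,
                    genes = tx$genes),
       models = tx$models, bin_index = tx$bins, chrom_len = tx$chrom_len,
       spec = spec)
}
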