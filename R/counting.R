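#' Count reads of one sample into genomic regions and mRNA bins
#'
#' Reads primary, mapped alignments from a coordinate-sorted, indexed BAM
#' file and assigns each read to a genomic region by the midpoint of its
#' aligned genomic span: a midpoint inside any union exon is an exon read
#' (further classified into 5'UTR/CDS/3'UTR by transcript position for
#' coding genes, and incrementing the containing mRNA bin); a midpoint
#' inside a gene body but not in an exon is intronic; anything else is
#' non-genic. When pairing flags are present, properly-paired fragments are
#' counted once via the midpoint of the full template span.
#'
#' @param bam_file Path to a BAM file with a \code{.bai} index.
#' @param models A \code{gene_models} tibble from [read_gene_models()].
#' @param bin_index A \code{bin_index} from [build_bins()].
#' @param sample_id Sample label (default: BAM file name).
#' @param role \code{"IP"} or \code{"Input"}.
#' @param down_to Optional depth: exactly this many reads are retained by
#'   seeded uniform sampling without replacement before assignment.
#' @param seed Seed for the down-sampling draw.
#' @param mapq Minimum mapping quality (default 0 = no filter).
#' @return A \code{sample_counts} object: a list with \code{sample_id},
#'   \code{role}, \code{total_reads}, \code{region_counts} (named integer
#'   vector over exon/intron/nongenic/utr5/cds/utr3) and \code{bins}, a
#'   tibble with one row per mRNA bin carrying the per-subregion and total
#'   read counts.
#' @export
count_reads <- function(bam_file, models, bin_index,
                        sample_id = sub("\\.bam$", "", basename(bam_file)),
                        role = c("IP", "Input"),
                        down_to = NULL, seed = NULL, mapq = 0L) {
  role <- match.arg(role)
  if (!file.exists(bam_file)) {
    qc_stop(sprintf("BAM file not found: %s", bam_file), "io_error")
  }
  bai <- c(paste0(bam_file, ".bai"), sub("\\.bam$", ".bai", bam_file))
  if (!any(file.exists(bai))) {
    qc_stop(sprintf("BAM index (.bai) not found for %s", bam_file),
            "index_error")
  }

  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = "flag",
                                   mapqFilter = as.integer(mapq))
  aln <- GenomicAlignments::readGAlignments(bam_file, param = param)
  paired <- length(aln) > 0L &&
    mean(bitwAnd(S4Vectors::mcols(aln)$flag, 1L) > 0L) > 0.5
  if (paired) {
    pflag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                    isSecondaryAlignment = FALSE,
                                    isSupplementaryAlignment = FALSE,
                                    isProperPair = TRUE)
    pairs <- GenomicAlignments::readGAlignmentPairs(
      bam_file,
      param = Rsamtools::ScanBamParam(flag = pflag,
                                      mapqFilter = as.integer(mapq))
    )
    span <- GenomicRanges::granges(pairs)
  } else {
    span <- GenomicRanges::granges(aln)
  }

  chroms <- as.character(GenomicRanges::seqnames(span))
  if (length(span) > 0L &&
      mean(!chroms %in% unique(models$chrom)) > 0.5) {
    qc_stop(
      "chromosome names disagree with the annotation for >50% of reads",
      "contig_mismatch"
    )
  }

  n <- length(span)
  if (!is.null(down_to)) {
    down_to <- as.integer(down_to)
    if (down_to > n) {
      qc_stop(sprintf("down_to (%d) exceeds available reads (%d)",
                      down_to, n), "depth_error")
    }
    idx <- withr::with_seed(seed %||% 1L, sample.int(n, down_to))
    span <- span[sort(idx)]
    n <- down_to
  }

  # 0-based midpoint of the aligned genomic span
  mid0 <- (GenomicRanges::start(span) - 1L) +
    GenomicRanges::width(span) %/% 2L
  assign_midpoints(mid0, as.character(GenomicRanges::seqnames(span)),
                   models, bin_index, sample_id, role,
                   down_to = down_to, seed = seed)
}

# Core midpoint-assignment shared by count_reads; builds the sample_counts.
assign_midpoints <- function(mid0, chroms, models, bin_index, sample_id,
                             role, down_to = NULL, seed = NULL) {
  pieces <- exon_piece_table(models) |>
    arrange(.data$gene_id, .data$start)
  piece_gr <- GenomicRanges::GRanges(
    seqnames = pieces$chrom,
    ranges = IRanges::IRanges(start = pieces$start + 1L, end = pieces$end)
  )
  mid_gr <- GenomicRanges::GRanges(
    seqnames = chroms,
    ranges = IRanges::IRanges(start = mid0 + 1L, width = 1L)
  )
  suppressWarnings({
    hit <- GenomicRanges::findOverlaps(mid_gr, piece_gr, select = "first")
  })

  in_exon <- !is.na(hit)
  pidx <- hit[in_exon]
  plus_tx <- pieces$plus_off[pidx] + (mid0[in_exon] - pieces$start[pidx])
  neg <- pieces$strand[pidx] == "-"
  tx <- ifelse(neg, pieces$mrna_length[pidx] - 1L - plus_tx, plus_tx)
  gene <- pieces$gene_id[pidx]
  cs <- pieces$cds_start[pidx]
  ce <- pieces$cds_end[pidx]
  subregion <- rep("none", length(tx))
  cod <- !is.na(cs)
  subregion[cod & tx < cs] <- "utr5"
  subregion[cod & tx >= cs & tx < ce] <- "cds"
  subregion[cod & tx >= ce] <- "utr3"

  # bin lookup: per-gene findInterval over that gene's bin starts
  bin_starts <- split(bin_index$tx_start, bin_index$gene_id)
  bin_no <- integer(length(tx))
  for (g in unique(gene)) {
    sel <- gene == g
    bin_no[sel] <- findInterval(tx[sel], bin_starts[[g]])
  }

  # intron vs nongenic for midpoints outside exons
  bodies <- models |> as_tibble() |>
    mutate(b_start = purrr::map_int(.data$exons, ~ min(.x$start)),
           b_end = purrr::map_int(.data$exons, ~ max(.x$end)))
  body_gr <- GenomicRanges::GRanges(
    seqnames = bodies$chrom,
    ranges = IRanges::IRanges(start = bodies$b_start + 1L,
                              end = bodies$b_end)
  )
  suppressWarnings({
    body_hit <- GenomicRanges::findOverlaps(mid_gr[!in_exon], body_gr,
                                            select = "first")
  })
  n_intron <- sum(!is.na(body_hit))
  n_nongenic <- sum(is.na(body_hit))

  # per-(bin, subregion) tallies
  bins <- as_tibble(bin_index)
  key <- paste(gene, bin_no, subregion, sep = "\r")
  tab <- table(key)
  if (length(tab) > 0L) {
    parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
    tal <- tibble(gene_id = parts[, 1], bin = as.integer(parts[, 2]),
                  subregion = parts[, 3], n = as.integer(tab)) |>
      tidyr::pivot_wider(names_from = "subregion", values_from = "n",
                         values_fill = 0L)
  } else {
    tal <- tibble(gene_id = character(), bin = integer())
  }
  for (col in c("utr5", "cds", "utr3", "none")) {
    if (!col %in% names(tal)) tal[[col]] <- integer(nrow(tal))
  }
  bins <- bins |>
    left_join(tal[, c("gene_id", "bin", "utr5", "cds", "utr3", "none")],
              by = c("gene_id", "bin")) |>
    mutate(across(c("utr5", "cds", "utr3", "none"),
                  ~ as.integer(tidyr::replace_na(.x, 0L)))) |>
    mutate(count = .data$utr5 + .data$cds + .data$utr3 + .data$none)

  region_counts <- c(
    exon = sum(bins$count), intron = n_intron, nongenic = n_nongenic,
    utr5 = sum(bins$utr5), cds = sum(bins$cds), utr3 = sum(bins$utr3)
  )
  new_sample_counts(sample_id, role, total_reads = length(mid0),
                    region_counts = region_counts, bins = bins,
                    down_to = down_to, seed = seed)
}

new_sample_counts <- function(sample_id, role, total_reads, region_counts,
                              bins, down_to = NULL, seed = NULL) {
  structure(
    list(sample_id = sample_id, role = role,
         total_reads = as.integer(total_reads),
         region_counts = vapply(region_counts, as.integer, integer(1)),
         bins = bins),
    class = "sample_counts", down_to = down_to, seed = seed
  )
}

#' @export
print.sample_counts <- function(x, ...) {
  cat(sprintf("<sample_counts> %s (%s): %d reads\n",
              x$sample_id, x$role, x$total_reads))
  rc <- x$region_counts
  cat(sprintf("  exon %d | intron %d | nongenic %d (utr5 %d, cds %d, utr3 %d)\n",
              rc[["exon"]], rc[["intron"]], rc[["nongenic"]],
              rc[["utr5"]], rc[["cds"]], rc[["utr3"]]))
  invisible(x)
}

#' Down-sample a counted sample to a target depth
#'
#' Thins all counters of a \code{sample_counts} object to exactly
#' \code{down_to} reads by multivariate-hypergeometric sampling over the
#' finest recorded partition (per-bin per-subregion cells plus intron and
#' non-genic pools), which is distributionally identical to removing reads
#' uniformly at random without replacement. Deterministic for a fixed seed.
#'
#' @param counts A \code{sample_counts} object.
#' @param down_to Target read count (must not exceed \code{total_reads}).
#' @param seed Integer seed.
#' @return A \code{sample_counts} object with \code{total_reads == down_to}.
#' @export
downsample_counts <- function(counts, down_to, seed = 1L) {
  stopifnot(inherits(counts, "sample_counts"))
  down_to <- as.integer(down_to)
  if (down_to > counts$total_reads) {
    qc_stop(sprintf("down_to (%d) exceeds total reads (%d)",
                    down_to, counts$total_reads), "depth_error")
  }
  bins <- counts$bins
  cells <- c(bins$utr5, bins$cds, bins$utr3, bins$none,
             counts$region_counts[["intron"]],
             counts$region_counts[["nongenic"]])
  unassigned <- counts$total_reads - sum(cells)
  cells <- c(cells, unassigned)
  kept <- withr::with_seed(seed, rmvhyper(cells, down_to))
  nb <- nrow(bins)
  bins$utr5 <- kept[seq_len(nb)]
  bins$cds <- kept[nb + seq_len(nb)]
  bins$utr3 <- kept[2L * nb + seq_len(nb)]
  bins$none <- kept[3L * nb + seq_len(nb)]
  bins$count <- bins$utr5 + bins$cds + bins$utr3 + bins$none
  region_counts <- c(
    exon = sum(bins$count), intron = kept[4L * nb + 1L],
    nongenic = kept[4L * nb + 2L],
    utr5 = sum(bins$utr5), cds = sum(bins$cds), utr3 = sum(bins$utr3)
  )
  new_sample_counts(counts$sample_id, counts$role, down_to,
                    region_counts, bins, down_to = down_to, seed = seed)
}

# Multivariate hypergeometric draw: sample k balls without replacement from
# urns with counts `m`. Sequential conditional rhyper draws.
rmvhyper <- function(m, k) {
  m <- as.integer(m)
  out <- integer(length(m))
  remaining <- sum(m)
  for (i in seq_along(m)) {
    if (k <= 0L) break
    remaining <- remaining - m[i]
    if (remaining <= 0L) {
      out[i] <- k
      k <- 0L
      break
    }
    x <- stats::rhyper(1L, m[i], remaining, k)
    out[i] <- x
    k <- k - x
  }
  out
}

#' Merge Input samples into a unified background sample
#'
#' Element-wise sums the bin and region counters of several Input-role
#' samples counted against the same bin index, producing the unified Input
#' background used by the enrichment analyses.
#'
#' @param inputs A list of \code{sample_counts} objects, all with role
#'   \code{"Input"}.
#' @return A \code{sample_counts} with \code{sample_id = "merged_input"}.
#' @export
merge_inputs <- function(inputs) {
  if (inherits(inputs, "sample_counts")) inputs <- list(inputs)
  stopifnot(length(inputs) >= 1L)
  roles <- vapply(inputs, function(x) x$role, character(1))
  if (any(roles != "Input")) {
    qc_stop("merge_inputs requires Input-role samples only", "role_error")
  }
  ref <- inputs[[1]]$bins[, c("gene_id", "bin", "tx_start", "tx_end")]
  for (x in inputs[-1]) {
    if (!identical(ref, x$bins[, c("gene_id", "bin", "tx_start", "tx_end")])) {
      qc_stop("samples were counted against different bin indexes",
              "shape_error")
    }
  }
  bins <- inputs[[1]]$bins
  for (col in c("utr5", "cds", "utr3", "none", "count")) {
    bins[[col]] <- Reduce(`+`, lapply(inputs, function(x) x$bins[[col]]))
  }
  region_counts <- Reduce(`+`, lapply(inputs, function(x) x$region_counts))
  total <- sum(vapply(inputs, function(x) x$total_reads, integer(1)))
  new_sample_counts("merged_input", "Input", total, region_counts, bins)
}
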