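#' Build union-exon gene models from a GTF annotation
#'
#' Parses a GTF file (plain or gzip) and collapses all isoforms of each gene
#' into a single union-exon model: the disjoint union of all exon intervals,
#' defining a per-gene mRNA coordinate system (5' to 3'). When CDS features
#' are present, the union CDS footprint is projected into transcript
#' coordinates and splits the mRNA into 5'UTR / CDS / 3'UTR segments; genes
#' without CDS records are retained but flagged non-coding.
#'
#' Coordinates are converted from GTF 1-based closed to 0-based half-open.
#' Strand \code{"."} is treated as \code{"+"}.
#'
#' @param gtf_file Path to a GTF file (optionally gzip-compressed).
#' @return A tibble of class \code{gene_models} with one row per gene:
#'   \code{gene_id}, \code{chrom}, \code{strand}, \code{exons} (list-column
#'   of 0-based half-open interval tibbles, sorted and disjoint),
#'   \code{n_exons}, \code{mrna_length}, \code{cds_start}, \code{cds_end}
#'   (transcript coordinates, \code{NA} for non-coding genes) and
#'   \code{coding}.
#' @examples
#' gtf <- system.file("extdata", "toy.gtf", package = "meripqc")
#' models <- read_gene_models(gtf)
#' models
#' @export
read_gene_models <- function(gtf_file) {
  if (!file.exists(gtf_file)) {
    qc_stop(sprintf("GTF file not found: %s", gtf_file), "io_error")
  }
  gr <- tryCatch(
    rtracklayer::import(gtf_file, format = "gtf"),
    error = function(e) {
      bad <- find_malformed_gtf_line(gtf_file)
      if (!is.na(bad)) {
        qc_stop(
          sprintf("malformed GTF record at line %d of %s", bad, gtf_file),
          "parse_error"
        )
      }
      qc_stop(sprintf("failed to parse GTF %s: %s", gtf_file,
                      conditionMessage(e)), "parse_error")
    }
  )
  feat <- as.character(gr$type)
  exon_gr <- gr[feat == "exon"]
  if (length(exon_gr) == 0L) {
    qc_stop("annotation contains no exon records", "empty_annotation")
  }
  cds_gr <- gr[feat == "CDS"]

  exon_tbl <- tibble(
    gene_id = as.character(exon_gr$gene_id),
    chrom = as.character(GenomicRanges::seqnames(exon_gr)),
    strand = as.character(GenomicRanges::strand(exon_gr)),
    start = GenomicRanges::start(exon_gr) - 1L,
    end = GenomicRanges::end(exon_gr)
  )
  exon_tbl$strand[exon_tbl$strand %in% c(".", "*")] <- "+"
  if (anyNA(exon_tbl$gene_id)) {
    qc_stop("exon record without gene_id attribute", "parse_error")
  }

  cds_tbl <- if (length(cds_gr) > 0L) {
    tibble(
      gene_id = as.character(cds_gr$gene_id),
      start = GenomicRanges::start(cds_gr) - 1L,
      end = GenomicRanges::end(cds_gr)
    )
  } else {
    tibble(gene_id = character(), start = integer(), end = integer())
  }

  models <- exon_tbl |>
    group_by(.data$gene_id) |>
    group_map(function(df, key) {
      gid <- key$gene_id[[1]]
      chrom <- df$chrom[[1]]
      strand <- df$strand[[1]]
      exons <- merge_intervals(df[, c("start", "end")])
      mrna_length <- sum(exons$end - exons$start)
      cds <- cds_tbl[cds_tbl$gene_id == gid, c("start", "end")]
      if (nrow(cds) > 0L) {
        cds <- merge_intervals(cds)
        tx_lo <- genome_to_tx(exons, strand, cds$start)
        tx_hi <- genome_to_tx(exons, strand, cds$end - 1L)
        txs <- c(tx_lo, tx_hi)
        txs <- txs[!is.na(txs)]
        if (length(txs) == 0L) {
          cds_start <- NA_integer_
          cds_end <- NA_integer_
          coding <- FALSE
        } else {
          cds_start <- min(txs)
          cds_end <- max(txs) + 1L
          coding <- TRUE
        }
      } else {
        cds_start <- NA_integer_
        cds_end <- NA_integer_
        coding <- FALSE
      }
      tibble(
        gene_id = gid, chrom = chrom, strand = strand,
        n_exons = nrow(exons), exons = list(exons),
        mrna_length = as.integer(mrna_length),
        cds_start = cds_start, cds_end = cds_end, coding = coding
      )
    }) |>
    bind_rows() |>
    arrange(.data$gene_id)

  class(models) <- c("gene_models", class(tibble()))
  models
}

# Locate the first structurally malformed line (wrong field count) of a GTF.
find_malformed_gtf_line <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  i <- 0L
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) return(NA_integer_)
    i <- i + 1L
    if (grepl("^#", line) || !nzchar(trimws(line))) next
    nfield <- length(strsplit(line, "\t", fixed = TRUE)[[1]])
    if (nfield < 9L) return(i)
  }
}

#' Tile gene models into fixed-width mRNA bins
#'
#' Each gene's mRNA coordinate system \code{[0, mrna_length)} is tiled 5' to
#' 3' with bins of \code{bin_width} nucleotides. A final partial bin is kept
#' when its length is at least a quarter of \code{bin_width} and merged into
#' the previous bin otherwise; genes shorter than \code{bin_width} form a
#' single bin.
#'
#' @param models A \code{gene_models} tibble from [read_gene_models()].
#' @param bin_width Bin width in nucleotides (>= 10; default 200).
#' @return A tibble of class \code{bin_index} with columns \code{gene_id},
#'   \code{bin} (1-based index within the gene), \code{tx_start},
#'   \code{tx_end} and \code{width}; the bin width is kept in the
#'   \code{"bin_width"} attribute.
#' @export
build_bins <- function(models, bin_width = 200L) {
  stopifnot(bin_width >= 10)
  if (!inherits(models, "gene_models") || nrow(models) == 0L) {
    qc_stop("no gene models supplied", "empty_annotation")
  }
  bin_width <- as.integer(bin_width)
  bins <- purrr::map2(models$gene_id, models$mrna_length, function(gid, len) {
    edges <- bin_edges(len, bin_width)
    tibble(
      gene_id = gid,
      bin = seq_len(length(edges) - 1L),
      tx_start = edges[-length(edges)],
      tx_end = edges[-1L]
    )
  }) |>
    bind_rows() |>
    mutate(width = .data$tx_end - .data$tx_start)
  attr(bins, "bin_width") <- bin_width
  class(bins) <- c("bin_index", class(tibble()))
  bins
}

# Bin edge positions for one gene: full-width bins plus the partial-bin rule.
bin_edges <- function(len, bin_width) {
  if (len <= bin_width) return(c(0L, as.integer(len)))
  n_full <- len %/% bin_width
  rem <- len - n_full * bin_width
  edges <- seq.int(0L, n_full * bin_width, by = bin_width)
  if (rem == 0L) {
    edges
  } else if (rem >= bin_width / 4) {
    c(edges, len)
  } else {
    edges[length(edges)] <- len
    edges
  }
}

#' Project a transcript-coordinate interval onto the genome
#'
#' Maps an interval of a gene's mRNA coordinate system through the union-exon
#' chain back to genomic intervals. Transcript position 0 is the 5' end of
#' the mRNA, which on the minus strand is the rightmost genomic exon base.
#' Output interval lengths always sum to \code{tx_end - tx_start}.
#'
#' @param models A \code{gene_models} tibble.
#' @param gene_id Gene identifier (must be present in \code{models}).
#' @param tx_start,tx_end Transcript interval, 0-based half-open.
#' @return A tibble with columns \code{chrom}, \code{start}, \code{end},
#'   \code{strand} (0-based half-open genomic intervals, sorted by start).
#' @export
project_to_genome <- function(models, gene_id, tx_start, tx_end) {
  i <- match(gene_id, models$gene_id)
  if (is.na(i)) {
    qc_stop(sprintf("unknown gene_id: %s", gene_id), "bounds_error")
  }
  g <- tx_to_genome(models$exons[[i]], models$strand[[i]],
                    as.integer(tx_start), as.integer(tx_end))
  tibble(
    chrom = models$chrom[[i]], start = g$start, end = g$end,
    strand = models$strand[[i]]
  )
}

# Internal: flat per-exon table with transcript offsets, used by counting.
# Columns: gene_id, chrom, strand, start, end, plus_off (tx offset of the
# exon's leftmost base in '+' orientation), mrna_length, cds_start, cds_end,
# coding.
exon_piece_table <- function(models) {
  purrr::pmap(
    list(models$gene_id, models$chrom, models$strand, models$exons,
         models$mrna_length, models$cds_start, models$cds_end,
         models$coding),
    function(gid, chrom, strand, exons, len, cs, ce, coding) {
      widths <- exons$end - exons$start
      tibble(
        gene_id = gid, chrom = chrom, strand = strand,
        start = exons$start, end = exons$end,
        plus_off = cumsum(c(0L, widths))[seq_len(nrow(exons))],
        mrna_length = len, cds_start = cs, cds_end = ce, coding = coding
      )
    }
  ) |> bind_rows()
}
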