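# Shared fixtures, built once per test run.

# Construct a sample_counts object directly from a bin table (counts given
# as subregion columns); used where a full BAM round-trip is unnecessary.
make_counts <- function(bins, sample_id = "S", role = "IP",
                        intron = 0L, nongenic = 0L, down_to = NULL) {
  for (col in c("utr5", "cds", "utr3", "none")) {
    if (!col %in% names(bins)) bins[[col]] <- 0L
  }
  bins$count <- bins$utr5 + bins$cds + bins$utr3 + bins$none
  region_counts <- c(
    exon = sum(bins$count), intron = intron, nongenic = nongenic,
    utr5 = sum(bins$utr5), cds = sum(bins$cds), utr3 = sum(bins$utr3)
  )
  meripqc:::new_sample_counts(sample_id, role,
                              sum(bins$count) + intron + nongenic,
                              region_counts, bins, down_to = down_to)
}

# Strip the bin_index class so the skeleton can be mutated freely.
as_tibble_bins <- function(b) tibble::as_tibble(b)

# A bin skeleton for synthetic counts: n_bins bins of `width` nt per gene.
make_bin_skeleton <- function(gene_ids, n_bins = 5L, width = 200L) {
  dplyr::bind_rows(lapply(gene_ids, function(g) {
    tibble::tibble(
      gene_id = g, bin = seq_len(n_bins),
      tx_start = (seq_len(n_bins) - 1L) * width,
      tx_end = seq_len(n_bins) * width,
      width = width
    )
  }))
}

# One simulated dataset (1 IP + 1 Input, clean), cached across test files.
sim_clean <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- simulation_spec(n_genes = 30L, depth = 20000L, seed = 42L)
      cache <<- simulate_dataset(spec, dir = file.path(tempdir(), "sim_clean"))
    }
    cache
  }
})

# Counted version of sim_clean, cached.
sim_clean_counts <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- sim_clean()
      models <- read_gene_models(ds$gtf)
      bins <- build_bins(models, ds$spec$bin_width)
      ip <- count_reads(ds$samples$path[1], models, bins, role = "IP")
      input <- count_reads(ds$samples$path[2], models, bins, role = "Input")
      cache <<- list(ds = ds, models = models, bins = bins,
                     ip = ip, input = input)
    }
    cache
  }
})

# Single-exon coding genes of identical geometry (for metagene tests).
uniform_models <- function(n_genes = 12L, utr5 = 200L, cds = 600L,
                           utr3 = 400L) {
  L <- utr5 + cds + utr3
  m <- tibble::tibble(
    gene_id = sprintf("g%02d", seq_len(n_genes)), chrom = "c",
    strand = "+", n_exons = 1L,
    exons = purrr::map(seq_len(n_genes),
                       ~ tibble::tibble(start = 0L, end = L)),
    mrna_length = L, cds_start = utr5, cds_end = utr5 + cds, coding = TRUE
  )
  class(m) <- c("gene_models", class(tibble::tibble()))
  m
}

# A list of sample_counts built from the columns of a count matrix.
make_count_set <- function(mat, roles = NULL, ids = NULL) {
  sk <- make_bin_skeleton("g", n_bins = nrow(mat))
  if (is.null(ids)) ids <- sprintf("s%d", seq_len(ncol(mat)))
  if (is.null(roles)) roles <- rep("IP", ncol(mat))
  lapply(seq_len(ncol(mat)), function(j) {
    make_counts(sk |> dplyr::mutate(none = as.integer(mat[, j])),
                sample_id = ids[j], role = roles[j])
  })
}
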