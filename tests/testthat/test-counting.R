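# Write a minimal single-chromosome SAM and convert it to an indexed BAM.
write_test_bam <- function(read_pos0, chrom_len = 5000L, read_len = 50L) {
  sam <- tempfile(fileext = ".sam")
  bam <- tempfile(fileext = ".bam")
  seq <- strrep("A", read_len)
  qual <- strrep("I", read_len)
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:chrT\tLN:%d", chrom_len),
    sprintf("r%03d\t0\tchrT\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
            seq_along(read_pos0), read_pos0 + 1L, read_len, seq, qual)
  ), sam)
  Rsamtools::asBam(sam, sub("\\.bam$", "", bam), overwrite = TRUE,
                   indexDestination = TRUE)
  bam
}

toy_models <- function() {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    "chrT\tsrc\texon\t101\t300\t.\t+\t.\tgene_id \"g1\"; transcript_id \"t\";",
    "chrT\tsrc\tCDS\t121\t280\t.\t+\t.\tgene_id \"g1\"; transcript_id \"t\";",
    "chrT\tsrc\texon\t2001\t2100\t.\t+\t.\tgene_id \"g2\"; transcript_id \"u\";",
    "chrT\tsrc\texon\t2501\t2600\t.\t+\t.\tgene_id \"g2\"; transcript_id \"u\";"
  ), gtf)
  read_gene_models(gtf)
}

test_that("reads are assigned by the midpoint of their genomic span", {
  models <- toy_models()
  bins <- build_bins(models, 200L)
  # read span [125, 175) 0-based: midpoint 150 -> inside g1 exon, tx 50,
  # cds tx-span [20, 180) -> cds; g1 has a single 200-nt bin
  bam <- write_test_bam(125L)
  x <- count_reads(bam, models, bins, role = "IP")
  expect_equal(unname(x$region_counts[c("exon", "intron", "nongenic")]),
               c(1L, 0L, 0L))
  expect_equal(unname(x$region_counts[["cds"]]), 1L)
  expect_equal(x$bins$count[x$bins$gene_id == "g1"], 1L)

  # midpoint 2200 falls between g2's exons -> intron
  bam <- write_test_bam(2175L)
  x <- count_reads(bam, models, bins, role = "IP")
  expect_equal(unname(x$region_counts[["intron"]]), 1L)
  expect_equal(sum(x$bins$count), 0L)

  # midpoint 1000 is between the genes -> nongenic
  bam <- write_test_bam(975L)
  x <- count_reads(bam, models, bins, role = "IP")
  expect_equal(unname(x$region_counts[["nongenic"]]), 1L)
})

test_that("simulated counts match the generator truth tables exactly", {
  cc <- sim_clean_counts()
  tr <- cc$ds$truth$reads
  for (sid in c("IP1", "Input1")) {
    x <- if (sid == "IP1") cc$ip else cc$input
    t_s <- tr[tr$sample_id == sid, ]
    expect_equal(x$total_reads, nrow(t_s))
    expect_equal(unname(x$region_counts[["exon"]]),
                 sum(t_s$region == "exon"))
    expect_equal(unname(x$region_counts[["intron"]]),
                 sum(t_s$region == "intron"))
    expect_equal(unname(x$region_counts[["nongenic"]]),
                 sum(t_s$region == "nongenic"))
    for (sr in c("utr5", "cds", "utr3")) {
      expect_equal(unname(x$region_counts[[sr]]),
                   sum(t_s$subregion == sr, na.rm = TRUE))
    }
    truth_bins <- dplyr::count(t_s[t_s$region == "exon", ],
                               gene_id, bin)
    merged <- dplyr::left_join(x$bins, truth_bins,
                               by = c("gene_id", "bin"))
    expect_equal(merged$count,
                 as.integer(tidyr::replace_na(merged$n, 0L)))
  }
})

test_that("count-level errors are informative", {
  cc <- sim_clean_counts()
  bam <- cc$ds$samples$path[1]
  expect_error(
    count_reads(bam, cc$models, cc$bins, role = "IP",
                down_to = cc$ip$total_reads + 1L, seed = 1),
    "exceeds available", class = "meripqc_depth_error"
  )
  noidx <- file.path(tempdir(), "noindex.bam")
  file.copy(bam, noidx, overwrite = TRUE)
  expect_error(count_reads(noidx, cc$models, cc$bins, role = "IP"),
               class = "meripqc_index_error")
})

test_that("down-sampling at count time is seeded and exact", {
  cc <- sim_clean_counts()
  bam <- cc$ds$samples$path[1]
  a <- count_reads(bam, cc$models, cc$bins, role = "IP",
                   down_to = 5000L, seed = 7)
  b <- count_reads(bam, cc$models, cc$bins, role = "IP",
                   down_to = 5000L, seed = 7)
  d <- count_reads(bam, cc$models, cc$bins, role = "IP",
                   down_to = 5000L, seed = 8)
  expect_equal(a$total_reads, 5000L)
  expect_equal(sum(a$region_counts[c("exon", "intron", "nongenic")]), 5000L)
  expect_identical(a$bins$count, b$bins$count)
  expect_false(identical(a$bins$count, d$bins$count))
})

test_that("counter thinning is deterministic, exact and mean-unbiased", {
  cc <- sim_clean_counts()
  same <- downsample_counts(cc$ip, cc$ip$total_reads, seed = 1)
  expect_equal(same$bins$count, cc$ip$bins$count)
  expect_equal(same$region_counts, cc$ip$region_counts)

  a <- downsample_counts(cc$ip, 4000L, seed = 3)
  b <- downsample_counts(cc$ip, 4000L, seed = 3)
  d <- downsample_counts(cc$ip, 4000L, seed = 4)
  expect_identical(a$bins$count, b$bins$count)
  expect_false(identical(a$bins$count, d$bins$count))
  expect_equal(a$total_reads, 4000L)
  expect_equal(sum(a$region_counts[c("exon", "intron", "nongenic")]), 4000L)
  expect_true(all(a$bins$count <= cc$ip$bins$count))
  expect_error(downsample_counts(cc$ip, cc$ip$total_reads + 1L),
               class = "meripqc_depth_error")

  # hypergeometric expectation on a 3-bin toy: mean retained fraction 1/2
  toy <- make_counts(make_bin_skeleton("g", n_bins = 3L) |>
                       dplyr::mutate(none = c(40L, 100L, 260L)))
  reps <- vapply(seq_len(1000L), function(s) {
    downsample_counts(toy, 200L, seed = s)$bins$count
  }, integer(3))
  frac <- rowMeans(reps) / c(40, 100, 260)
  se <- sqrt(0.25 / (c(40, 100, 260) * 1000))
  expect_true(all(abs(frac - 0.5) < 3 * se))
})

test_that("merging Input samples sums counters and is order-invariant", {
  sk <- make_bin_skeleton("g", n_bins = 3L)
  a <- make_counts(sk |> dplyr::mutate(none = c(1L, 2L, 3L)),
                   sample_id = "in1", role = "Input", intron = 2L)
  b <- make_counts(sk |> dplyr::mutate(none = c(4L, 5L, 6L)),
                   sample_id = "in2", role = "Input", nongenic = 5L)
  one <- merge_inputs(list(a))
  expect_equal(one$bins$count, a$bins$count)
  m <- merge_inputs(list(a, b))
  expect_equal(m$bins$count, c(5L, 7L, 9L))
  expect_equal(m$sample_id, "merged_input")
  expect_equal(m$role, "Input")
  expect_equal(unname(m$region_counts[["intron"]]), 2L)
  expect_equal(unname(m$region_counts[["nongenic"]]), 5L)
  m2 <- merge_inputs(list(b, a))
  expect_equal(m$bins$count, m2$bins$count)
  expect_equal(m$total_reads, m2$total_reads)

  ip <- make_counts(sk, sample_id = "x", role = "IP")
  expect_error(merge_inputs(list(a, ip)), class = "meripqc_role_error")
  other <- make_counts(make_bin_skeleton("h", n_bins = 3L),
                       sample_id = "in3", role = "Input")
  expect_error(merge_inputs(list(a, other)), class = "meripqc_shape_error")
})

test_that("gene bin totals equal the gene's exon-assigned reads", {
  cc <- sim_clean_counts()
  expect_equal(sum(cc$ip$bins$count),
               unname(cc$ip$region_counts[["exon"]]))
})
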