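#' @importFrom rlang %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map2 map_int map_dbl map_chr pmap imap
#' @importFrom tidyr unnest pivot_longer
NULL

# Internal: stop with a classed condition so callers/tests can match on class.
qc_stop <- function(msg, class) {
  rlang::abort(msg, class = paste0("meripqc_", class))
}

# Merge possibly-overlapping 0-based half-open intervals into a disjoint
# sorted set. `x` is a tibble/data.frame with columns start, end.
merge_intervals <- function(x) {
  if (nrow(x) == 0L) {
    return(tibble(start = integer(), end = integer()))
  }
  x <- x[order(x$start, x$end), , drop = FALSE]
  start <- x$start
  end <- x$end
  keep_start <- start[1]
  out_s <- integer(0)
  out_e <- integer(0)
  cur_s <- start[1]
  cur_e <- end[1]
  if (nrow(x) > 1L) {
    for (i in 2:nrow(x)) {
      if (start[i] <= cur_e) {
        cur_e <- max(cur_e, end[i])
      } else {
        out_s <- c(out_s, cur_s)
        out_e <- c(out_e, cur_e)
        cur_s <- start[i]
        cur_e <- end[i]
      }
    }
  }
  out_s <- c(out_s, cur_s)
  out_e <- c(out_e, cur_e)
  tibble(start = as.integer(out_s), end = as.integer(out_e))
}

# Map genomic positions (0-based) to transcript coordinates for one gene.
# Positions must fall inside the exons; NA is returned otherwise.
# Transcript position 0 is the 5' end (rightmost exonic base on '-' strand).
genome_to_tx <- function(exons, strand, gpos) {
  widths <- exons$end - exons$start
  offs <- cumsum(c(0L, widths))[seq_len(nrow(exons))]
  mrna_length <- sum(widths)
  idx <- findInterval(gpos, exons$start)
  ok <- idx >= 1L & idx <= nrow(exons)
  ok[ok] <- gpos[ok] < exons$end[idx[ok]]
  plus_tx <- rep(NA_integer_, length(gpos))
  plus_tx[ok] <- offs[idx[ok]] + (gpos[ok] - exons$start[idx[ok]])
  if (identical(strand, "-")) {
    tx <- mrna_length - 1L - plus_tx
  } else {
    tx <- plus_tx
  }
  as.integer(tx)
}

# Map a transcript-coordinate interval [tx_start, tx_end) back to genomic
# intervals (0-based half-open, sorted by genomic start). Strand-aware.
tx_to_genome <- function(exons, strand, tx_start, tx_end) {
  widths <- exons$end - exons$start
  mrna_length <- sum(widths)
  if (tx_start < 0 || tx_end > mrna_length || tx_start >= tx_end) {
    qc_stop(
      sprintf(
        "transcript interval [%d, %d) outside [0, %d)",
        tx_start, tx_end, mrna_length
      ),
      "bounds_error"
    )
  }
  if (identical(strand, "-")) {
    p_start <- mrna_length - tx_end
    p_end <- mrna_length - tx_start
  } else {
    p_start <- tx_start
    p_end <- tx_end
  }
  offs <- cumsum(c(0L, widths))
  out_s <- integer(0)
  out_e <- integer(0)
  for (i in seq_len(nrow(exons))) {
    a <- max(p_start, offs[i])
    b <- min(p_end, offs[i + 1L])
    if (a < b) {
      gs <- exons$start[i] + (a - offs[i])
      out_s <- c(out_s, gs)
      out_e <- c(out_e, gs + (b - a))
    }
  }
  tibble(start = as.integer(out_s), end = as.integer(out_e))
}
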