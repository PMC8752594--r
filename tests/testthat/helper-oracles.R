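# Brute-force reference implementations, independent of the package's
# IRanges-based code paths.

# Boolean-mask merge oracle: mark covered bases on a genome mask, close
# gaps of length <= max_gap between covered runs, report components.
mask_merge_oracle <- function(x, max_gap = 0, genome_len = 5000) {
  out <- lapply(sort(unique(x$chrom)), function(chr) {
    xi <- x[x$chrom == chr, , drop = FALSE]
    mask <- logical(genome_len)
    for (i in seq_len(nrow(xi))) mask[(xi$start[i] + 1):xi$end[i]] <- TRUE
    if (max_gap > 0) {
      r <- rle(mask)
      ends <- cumsum(r$lengths)
      for (j in seq_along(r$lengths)) {
        gap_inside <- j > 1 && j < length(r$lengths)
        if (!r$values[j] && gap_inside && r$lengths[j] <= max_gap)
          mask[(ends[j] - r$lengths[j] + 1):ends[j]] <- TRUE
      }
    }
    r <- rle(mask)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- which(r$values)
    data.frame(chrom = rep(chr, length(keep)), start = starts[keep] - 1,
               end = ends[keep], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# All-pairs overlap oracle (>= 1 bp).
quadratic_overlap_oracle <- function(query, reference) {
  vapply(seq_len(nrow(query)), function(i) {
    any(reference$chrom == query$chrom[i] &
          reference$start < query$end[i] &
          query$start[i] < reference$end)
  }, logical(1))
}

# Per-bin feature-count oracle.
bin_count_oracle <- function(features, bins) {
  vapply(seq_len(nrow(bins)), function(i) {
    sum(features$chrom == bins$chrom[i] &
          features$start < bins$end[i] &
          bins$start[i] < features$end)
  }, integer(1))
}

random_intervals <- function(n, chroms = c("chr1", "chr2"),
                             genome_len = 5000, max_width = 200) {
  start <- sample.int(genome_len - max_width, n, replace = TRUE) - 1
  width <- sample.int(max_width, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width, stringsAsFactors = FALSE)
}
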