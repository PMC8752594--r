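#' Genomic intervals as BED-style data frames
#'
#' Throughout the package a set of genomic intervals is a plain `data.frame`
#' with columns `chrom` (character), `start` and `end` (0-based half-open,
#' BED convention) and optionally `id` and `score`. [genomic_intervals()]
#' builds and validates such a frame; most other functions accept any data
#' frame with at least the three coordinate columns and validate it on entry.
#'
#' @param chrom character vector of chromosome names (non-empty strings).
#' @param start integer-ish vector, 0-based inclusive start (>= 0).
#' @param end integer-ish vector, 0-based exclusive end (> start).
#' @param id optional character labels.
#' @param score optional numeric scores.
#' @return A validated `data.frame` of intervals.
#' @examples
#' genomic_intervals("chr1", 100, 200, id = "a")
#' @export
genomic_intervals <- function(chrom, start, end, id = NULL, score = NULL) {
  x <- data.frame(chrom = as.character(chrom),
                  start = as.numeric(start),
                  end = as.numeric(end),
                  stringsAsFactors = FALSE)
  if (!is.null(id)) x$id <- as.character(id)
  if (!is.null(score)) x$score <- as.numeric(score)
  validate_intervals(x)
  x
}

#' @noRd
validate_intervals <- function(x, what = "intervals") {
  if (!is.data.frame(x))
    stop(what, " must be a data.frame")
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(what, " missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(x) == 0) return(invisible(x))
  if (any(is.na(x$chrom)) || any(!nzchar(x$chrom)))
    stop(what, ": chrom must be non-empty")
  if (any(x$start < 0)) stop(what, ": start must be >= 0")
  if (any(x$end <= x$start)) stop(what, ": end must be > start")
  invisible(x)
}

#' Sort intervals lexicographically
#'
#' Orders by chromosome name, then start, then end; ties keep input order
#' (stable sort).
#'
#' @param x interval data frame.
#' @return The sorted data frame (row names dropped).
#' @export
sort_intervals <- function(x) {
  validate_intervals(x)
  if (nrow(x) == 0) return(x)
  o <- order(x$chrom, x$start, x$end, method = "radix")
  out <- x[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Split an interval frame into per-chromosome IRanges (1-based closed,
## shifted from the 0-based half-open columns).
#' @noRd
iranges_by_chrom <- function(x) {
  sp <- split(seq_len(nrow(x)), x$chrom)
  lapply(sp, function(i)
    list(idx = i,
         ir = IRanges::IRanges(start = x$start[i] + 1L, end = x$end[i])))
}

#' Merge intervals within a gap
#'
#' Collapses intervals on the same chromosome whose gap is at most `max_gap`
#' base pairs into single spanning intervals. Intervals that exactly abut
#' (one's end equals the next's start) merge even at `max_gap = 0`, matching
#' boolean-mask semantics. With `max_gap = 0` the covered base pairs are
#' conserved exactly.
#'
#' @param x interval data frame.
#' @param max_gap non-negative integer gap (bp) bridged during merging.
#' @return Sorted, pairwise non-overlapping intervals, each pair separated by
#'   more than `max_gap` bp.
#' @examples
#' x <- genomic_intervals(c("chr1", "chr1"), c(100, 250), c(200, 300))
#' merge_intervals(x, max_gap = 100)  # one interval chr1:100-300
#' @export
merge_intervals <- function(x, max_gap = 0) {
  validate_intervals(x)
  if (length(max_gap) != 1 || is.na(max_gap) || max_gap < 0)
    stop("max_gap must be a single non-negative number")
  if (nrow(x) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  pieces <- lapply(iranges_by_chrom(x), function(p)
    IRanges::reduce(p$ir, min.gapwidth = max_gap + 1))
  out <- do.call(rbind, lapply(names(pieces), function(chr) {
    r <- pieces[[chr]]
    data.frame(chrom = rep(chr, length(r)),
               start = IRanges::start(r) - 1,
               end = as.numeric(IRanges::end(r)),
               stringsAsFactors = FALSE)
  }))
  sort_intervals(out)
}

#' Overlap selection and subtraction
#'
#' `intersect_any()` returns the query rows that overlap any reference
#' interval by at least 1 bp (BEDOPS `-e 1` semantics); rows are returned
#' unmodified. `subtract_overlapping()` returns the complementary rows
#' (BEDOPS `-n 1`); together the two results partition the query.
#'
#' @param query,reference interval data frames.
#' @return A subset of `query` rows.
#' @export
intersect_any <- function(query, reference) {
  query[overlaps_any(query, reference), , drop = FALSE]
}

#' @rdname intersect_any
#' @export
subtract_overlapping <- function(query, reference) {
  query[!overlaps_any(query, reference), , drop = FALSE]
}

#' @rdname intersect_any
#' @return `overlaps_any()` returns the logical overlap indicator itself,
#'   one value per query row.
#' @export
overlaps_any <- function(query, reference) {
  validate_intervals(query, "query")
  validate_intervals(reference, "reference")
  hit <- logical(nrow(query))
  if (nrow(query) == 0 || nrow(reference) == 0) return(hit)
  q <- iranges_by_chrom(query)
  r <- iranges_by_chrom(reference)
  for (chr in intersect(names(q), names(r))) {
    hit[q[[chr]]$idx] <- IRanges::overlapsAny(q[[chr]]$ir, r[[chr]]$ir)
  }
  hit
}

#' Count features per bin
#'
#' For each bin, counts the features overlapping it by at least 1 bp
#' (bedmap `--count --bp-ovr 1` semantics). A feature spanning k bins
#' contributes to all k.
#'
#' @param features interval data frame of features to count.
#' @param bins non-overlapping interval data frame of bins.
#' @return Integer vector of counts, one per row of `bins`.
#' @export
count_per_bin <- function(features, bins) {
  validate_intervals(features, "features")
  validate_intervals(bins, "bins")
  if (nrow(bins) > 1) {
    s <- sort_intervals(transform(bins, .row = seq_len(nrow(bins))))
    same <- s$chrom[-nrow(s)] == s$chrom[-1]
    if (any(same & s$end[-nrow(s)] > s$start[-1]))
      stop("bins must be non-overlapping")
  }
  counts <- integer(nrow(bins))
  if (nrow(features) == 0 || nrow(bins) == 0) return(counts)
  b <- iranges_by_chrom(bins)
  f <- iranges_by_chrom(features)
  for (chr in intersect(names(b), names(f))) {
    counts[b[[chr]]$idx] <- IRanges::countOverlaps(b[[chr]]$ir, f[[chr]]$ir)
  }
  counts
}

#' Genome layout: chromosome sizes and pericentromeric compartments
#'
#' Bundles chromosome lengths with configured pericentromere intervals and
#' derives the chromosome arms as their complement. The two compartments
#' tile each chromosome exactly. Pericentromere boundaries are configuration
#' input (as in published Arabidopsis designations), never hard-coded.
#'
#' @param chrom_sizes named numeric vector, chromosome name -> length (bp).
#' @param pericentromere interval data frame of pericentromeric spans; must
#'   lie within chromosome bounds and not overlap.
#' @return An object of class `genome_layout` with elements `chrom_sizes`,
#'   `pericentromere` and `arms`.
#' @export
genome_layout <- function(chrom_sizes, pericentromere) {
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chrom_sizes must be a named vector")
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be positive")
  validate_intervals(pericentromere, "pericentromere")
  if (nrow(pericentromere)) {
    unknown <- setdiff(pericentromere$chrom, names(chrom_sizes))
    if (length(unknown))
      stop("pericentromere on unknown chromosome(s): ",
           paste(unknown, collapse = ", "))
    if (any(pericentromere$end > chrom_sizes[pericentromere$chrom]))
      stop("pericentromere interval exceeds chromosome bounds")
    m <- merge_intervals(pericentromere, 0)
    if (nrow(m) != nrow(pericentromere))
      stop("pericentromere intervals must not overlap or abut")
  }
  peri <- sort_intervals(pericentromere[, c("chrom", "start", "end")])
  arms <- do.call(rbind, lapply(names(chrom_sizes), function(chr) {
    p <- peri[peri$chrom == chr, , drop = FALSE]
    edges <- c(0, rbind(p$start, p$end), chrom_sizes[[chr]])
    starts <- edges[seq(1, length(edges), by = 2)]
    ends <- edges[seq(2, length(edges), by = 2)]
    keep <- ends > starts
    data.frame(chrom = rep(chr, sum(keep)), start = starts[keep],
               end = ends[keep], stringsAsFactors = FALSE)
  }))
  rownames(arms) <- NULL
  structure(list(chrom_sizes = chrom_sizes, pericentromere = peri,
                 arms = arms),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x$chrom_sizes), "chromosome(s),",
      sum(x$chrom_sizes), "bp;",
      nrow(x$pericentromere), "pericentromeric interval(s) covering",
      sum(x$pericentromere$end - x$pericentromere$start), "bp\n")
  invisible(x)
}

#' Assign intervals to arm or pericentromere
#'
#' An interval is classed as pericentromeric when its midpoint falls inside
#' a configured pericentromere interval; otherwise it belongs to the arms.
#' The midpoint rule resolves intervals straddling a compartment boundary
#' deterministically.
#'
#' @param x interval data frame.
#' @param layout a [genome_layout()].
#' @return Character vector, `"arm"` or `"pericentromere"`, one per row.
#' @export
assign_compartment <- function(x, layout) {
  validate_intervals(x)
  stopifnot(inherits(layout, "genome_layout"))
  mid <- floor((x$start + x$end) / 2)
  mids <- data.frame(chrom = x$chrom, start = mid, end = mid + 1,
                     stringsAsFactors = FALSE)
  ifelse(overlaps_any(mids, layout$pericentromere), "pericentromere", "arm")
}

#' Tile a genome into fixed-width bins
#'
#' Bins are anchored at coordinate 0 on each chromosome; the final bin is
#' truncated at the chromosome end.
#'
#' @param layout a [genome_layout()].
#' @param bin_size bin width in bp.
#' @return Interval data frame of non-overlapping bins tiling every
#'   chromosome.
#' @export
make_bins <- function(layout, bin_size) {
  stopifnot(inherits(layout, "genome_layout"), bin_size >= 1)
  do.call(rbind, lapply(names(layout$chrom_sizes), function(chr) {
    len <- layout$chrom_sizes[[chr]]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = rep(chr, length(starts)), start = starts,
               end = pmin(starts + bin_size, len), stringsAsFactors = FALSE)
  }))
}

#' Read and write BED files
#'
#' Minimal BED3/BED6 I/O: tab-separated, no header, 0-based half-open
#' coordinates written back exactly as stored. Columns 4 and 5, when
#' present, become `id` and `score`.
#'
#' @param path file path.
#' @param x interval data frame (for writing).
#' @return `read_bed()` returns an interval data frame; `write_bed()`
#'   returns `path` invisibly.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         colClasses = "character",
                         col.names = paste0("V", 1:6), fill = TRUE)
  out <- data.frame(chrom = x$V1, start = as.numeric(x$V2),
                    end = as.numeric(x$V3), stringsAsFactors = FALSE)
  if (any(nzchar(x$V4) & !is.na(x$V4))) out$id <- x$V4
  if (any(nzchar(x$V5) & !is.na(x$V5))) out$score <- as.numeric(x$V5)
  validate_intervals(out)
  out
}

#' @rdname read_bed
#' @export
write_bed <- function(x, path) {
  validate_intervals(x)
  cols <- data.frame(x$chrom, format_coord(x$start), format_coord(x$end),
                     stringsAsFactors = FALSE)
  if (!is.null(x$score) && is.null(x$id)) x$id <- "."
  if (!is.null(x$id)) cols[[4]] <- x$id
  if (!is.null(x$score)) {
    cols[[5]] <- as.character(x$score)
    cols[[6]] <- "."
  }
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @noRd
format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a chrom-sizes table
#'
#' Two tab-separated columns: chromosome name and length in bp; no header.
#'
#' @param path file path.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE)
  stats::setNames(as.numeric(x[[2]]), x[[1]])
}

#' Write a bedGraph track
#'
#' @param x interval data frame with a `score` column.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  validate_intervals(x)
  if (is.null(x$score)) stop("bedGraph output needs a score column")
  utils::write.table(
    data.frame(x$chrom, format_coord(x$start), format_coord(x$end), x$score),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
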