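#' Call small-RNA clusters from read placements
#'
#' Re-implements the clustering stage of dicer-sized small-RNA cluster
#' calling: reads in the dicer size range whose placements lie within
#' `pad` bp of each other are merged into candidate islands, and islands
#' supported by at least `mincov` reads become clusters. Cluster boundaries
#' are the min/max coordinates of the contributing reads (the pad only
#' bridges gaps; it is not retained in the reported span). Defaults match
#' the standard settings `mincov 20, pad 100, dicermin 21, dicermax 24`.
#'
#' @param reads data frame of read placements with columns `chrom`,
#'   `start`, `end` (0-based half-open) and `length` (nt); if `length` is
#'   absent it is taken as `end - start`.
#' @param mincov minimum reads per cluster (>= 1).
#' @param pad maximum gap (bp) bridged when forming islands.
#' @param dicer_min,dicer_max read-length range (nt) admitted to island
#'   formation.
#' @return Interval data frame of clusters with columns `chrom`, `start`,
#'   `end`, `id`, `total_reads`, one `n<len>` count column per length in
#'   the dicer range, and `dominant_size` (argmax of the size histogram;
#'   ties go to the longer size).
#' @examples
#' reads <- data.frame(chrom = "chr1", start = rep(1000, 20),
#'                     end = rep(1024, 20), length = 24)
#' call_clusters(reads)
#' @export
call_clusters <- function(reads, mincov = 20, pad = 100,
                          dicer_min = 21, dicer_max = 24) {
  if (mincov < 1) stop("mincov must be >= 1")
  if (is.null(reads$length)) reads$length <- reads$end - reads$start
  validate_intervals(reads, "reads")
  if (nrow(reads) && (any(reads$length < 15) || any(reads$length > 35)))
    stop("read lengths must lie in [15, 35] nt")
  sizes <- dicer_min:dicer_max
  r <- reads[reads$length >= dicer_min & reads$length <= dicer_max, ,
             drop = FALSE]
  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), id = character(),
                      total_reads = integer(), stringsAsFactors = FALSE)
  for (s in sizes) empty[[paste0("n", s)]] <- integer()
  empty$dominant_size <- integer()
  if (nrow(r) == 0) return(empty)
  islands <- merge_intervals(r[, c("chrom", "start", "end")], max_gap = pad)
  islands$total_reads <- count_per_bin(r, islands)
  keep <- islands$total_reads >= mincov
  islands <- islands[keep, , drop = FALSE]
  if (nrow(islands) == 0) return(empty)
  ## size histogram and read-supported boundaries per island
  assignment <- integer(nrow(r))
  starts <- ends <- numeric(nrow(islands))
  hist <- matrix(0L, nrow(islands), length(sizes),
                 dimnames = list(NULL, paste0("n", sizes)))
  bi <- iranges_by_chrom(islands)
  ri <- iranges_by_chrom(r)
  for (chr in names(bi)) {
    h <- IRanges::findOverlaps(ri[[chr]]$ir, bi[[chr]]$ir)
    assignment[ri[[chr]]$idx[S4Vectors::queryHits(h)]] <-
      bi[[chr]]$idx[S4Vectors::subjectHits(h)]
  }
  keepr <- assignment > 0
  f <- factor(assignment[keepr], levels = seq_len(nrow(islands)))
  starts <- as.numeric(tapply(r$start[keepr], f, min))
  ends <- as.numeric(tapply(r$end[keepr], f, max))
  hist[, ] <- as.matrix(table(f, factor(r$length[keepr], levels = sizes)))
  out <- data.frame(chrom = islands$chrom, start = starts, end = ends,
                    id = sprintf("cluster%05d", seq_len(nrow(islands))),
                    total_reads = islands$total_reads,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(hist))
  ## ties toward the longer size: reverse argmax on the reversed histogram
  out$dominant_size <- sizes[length(sizes) + 1L -
                               apply(hist[, rev(seq_along(sizes)),
                                          drop = FALSE], 1, which.max)]
  sort_intervals(out)
}

#' Core clusters supported by all three replicates
#'
#' Pools the three replicate cluster sets, merges overlapping/abutting
#' calls, and keeps merged regions that overlap (>= 1 bp) at least one
#' cluster from every replicate; the reported span is the union span of
#' the contributing replicate clusters. The triplicate design is enforced.
#'
#' @param rep1,rep2,rep3 cluster interval data frames from one tissue's
#'   three replicates.
#' @return Interval data frame of core clusters with per-replicate support
#'   counts (`n_rep1`, `n_rep2`, `n_rep3`).
#' @export
core_clusters <- function(rep1, rep2, rep3) {
  if (missing(rep2) || missing(rep3) || is.null(rep2) || is.null(rep3))
    stop("core_clusters requires exactly three replicate sets")
  reps <- list(rep1, rep2, rep3)
  for (r in reps) validate_intervals(r, "replicate clusters")
  pool <- do.call(rbind, lapply(reps, function(r)
    r[, c("chrom", "start", "end")]))
  merged <- merge_intervals(pool, max_gap = 0)
  support <- vapply(reps, function(r) count_per_bin(r, merged),
                    integer(nrow(merged)))
  if (nrow(merged) == 1) support <- matrix(support, nrow = 1)
  keep <- rowSums(support >= 1) == 3
  out <- merged[keep, , drop = FALSE]
  colnames(support) <- paste0("n_rep", 1:3)
  out <- cbind(out, as.data.frame(support)[keep, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Master cluster list across tissues
#'
#' Collapses per-tissue core cluster sets into a non-redundant union:
#' overlapping or abutting clusters from different tissues merge into one
#' spanning interval, annotated with the contributing tissues.
#'
#' @param core_sets named list of per-tissue core cluster data frames.
#' @return Interval data frame with `id` and a comma-separated `tissues`
#'   column listing the contributing tissues per master cluster.
#' @export
master_clusters <- function(core_sets) {
  if (!length(core_sets)) stop("need at least one core set")
  if (is.null(names(core_sets)))
    names(core_sets) <- paste0("set", seq_along(core_sets))
  for (s in core_sets) validate_intervals(s, "core clusters")
  pool <- do.call(rbind, lapply(core_sets, function(s)
    s[, c("chrom", "start", "end")]))
  merged <- merge_intervals(pool, max_gap = 0)
  contrib <- vapply(core_sets, function(s)
    count_per_bin(s, merged) >= 1, logical(nrow(merged)))
  if (nrow(merged) == 1) contrib <- matrix(contrib, nrow = 1)
  merged$id <- sprintf("mc%05d", seq_len(nrow(merged)))
  merged$tissues <- apply(contrib, 1, function(z)
    paste(names(core_sets)[z], collapse = ","))
  merged
}
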