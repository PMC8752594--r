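#' Read a CGmap-style per-cytosine methylation table
#'
#' Expects six tab-separated columns without a header: chromosome,
#' position (1-based), strand (+/-), context (CG, CHG or CHH), methylated
#' read count, total coverage. Positions are converted to the package's
#' 0-based half-open convention only at binning time; the record keeps the
#' 1-based source position.
#'
#' @param path file path.
#' @return Data frame with columns `chrom`, `pos`, `strand`, `context`,
#'   `mc_count`, `coverage`.
#' @export
read_cgmap <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         stringsAsFactors = FALSE,
                         col.names = c("chrom", "pos", "strand", "context",
                                       "mc_count", "coverage"))
  validate_cytosines(x)
  x
}

#' @noRd
validate_cytosines <- function(x, what = "cytosine records") {
  need <- c("chrom", "pos", "strand", "context", "mc_count", "coverage")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop(what, " missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(x)) {
    if (any(x$mc_count < 0) || any(x$mc_count > x$coverage))
      stop(what, ": need 0 <= mc_count <= coverage")
    if (!all(x$context %in% c("CG", "CHG", "CHH")))
      stop(what, ": context must be CG, CHG or CHH")
  }
  invisible(x)
}

#' Pool cytosines into fixed 100-bp bins
#'
#' Bins tile each chromosome on a fixed grid anchored at coordinate 0;
#' both strands are pooled and methylated/total read counts are summed per
#' context. `n_cytosines` counts the context-matching cytosines with any
#' data in the bin.
#'
#' @param records cytosine records (see [read_cgmap()]).
#' @param layout a [genome_layout()]; positions outside chromosome bounds
#'   are an error.
#' @param bin_size bin width (bp), default 100.
#' @return Data frame of non-empty bins: `chrom`, `start`, `end`,
#'   `context`, `n_cytosines`, `mc`, `coverage`, `level`.
#' @export
bin_methylome <- function(records, layout, bin_size = 100) {
  validate_cytosines(records)
  stopifnot(inherits(layout, "genome_layout"))
  if (nrow(records)) {
    bad <- !(records$chrom %in% names(layout$chrom_sizes)) |
      records$pos < 1 | records$pos > layout$chrom_sizes[records$chrom]
    if (any(bad)) stop("cytosine position(s) outside chromosome bounds")
  }
  if (nrow(records) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), context = character(),
                      n_cytosines = integer(), mc = numeric(),
                      coverage = numeric(), level = numeric(),
                      stringsAsFactors = FALSE))
  bin <- floor((records$pos - 1) / bin_size)
  key <- paste(records$chrom, bin, records$context, sep = "\r")
  mc <- rowsum(records$mc_count, key)
  cov <- rowsum(records$coverage, key)
  n <- rowsum(rep(1L, nrow(records)), key)
  parts <- do.call(rbind, strsplit(rownames(mc), "\r", fixed = TRUE))
  out <- data.frame(chrom = parts[, 1],
                    start = as.numeric(parts[, 2]) * bin_size,
                    end = as.numeric(parts[, 2]) * bin_size + bin_size,
                    context = parts[, 3], n_cytosines = as.integer(n),
                    mc = as.numeric(mc), coverage = as.numeric(cov),
                    stringsAsFactors = FALSE)
  out$end <- pmin(out$end, layout$chrom_sizes[out$chrom])
  out$level <- ifelse(out$coverage > 0, out$mc / out$coverage, NA_real_)
  out <- out[order(out$chrom, out$start, out$context, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

## Vectorised two-sided Fisher's exact test for 2x2 tables
## (methylated/unmethylated x sample); matches stats::fisher.test's
## two-sided rule (sum of hypergeometric point probabilities not exceeding
## the observed one, with its 1e-7 relative tolerance).
#' @noRd
fisher_2x2_p <- function(mc_a, cov_a, mc_b, cov_b) {
  vapply(seq_along(mc_a), function(i) {
    m <- mc_a[i] + mc_b[i]
    n <- cov_a[i] + cov_b[i] - m
    k <- cov_a[i]
    lo <- max(0, k - n)
    hi <- min(k, m)
    d <- stats::dhyper(lo:hi, m, n, k)
    min(1, sum(d[d <= d[mc_a[i] - lo + 1] * (1 + 1e-7)]))
  }, numeric(1))
}

#' Pairwise DMR calling in fixed bins
#'
#' Calls differentially methylated 100-bp bins between two samples in one
#' context. Cytosines are matched by position and strand across the two
#' samples and dropped unless covered by at least `min_reads` reads in
#' both; candidate bins must then retain at least `min_cytosines` context
#' cytosines. Significance is a two-sided Fisher's exact test on the
#' pooled methylated/unmethylated counts, Benjamini-Hochberg adjusted
#' across the candidate bins of this comparison; a DMR additionally
#' requires an absolute methylation difference of at least the
#' context-specific threshold (defaults 40%/20%/10% for CG/CHG/CHH).
#' `direction` is `hypo` when sample A (the first argument, conventionally
#' the mutant) is lower.
#'
#' @param meth_a,meth_b cytosine record frames for the two samples.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param layout a [genome_layout()].
#' @param bin_size bin width (bp).
#' @param min_cytosines minimum matched context cytosines per bin.
#' @param min_reads minimum per-cytosine coverage in both samples.
#' @param delta_threshold named per-context absolute difference cutoffs.
#' @param alpha adjusted-p cutoff.
#' @param relative if `TRUE`, the difference filter is applied to the
#'   relative change `|level_a - level_b| / max(level_a, level_b)` instead
#'   of the absolute difference.
#' @return Data frame of DMRs (`chrom`, `start`, `end`, `context`,
#'   `n_cytosines`, `level_a`, `level_b`, `delta`, `pvalue`, `padj`,
#'   `direction`), with attributes `n_candidates` (bins entering BH) and
#'   `candidates` (the full candidate table).
#' @export
pairwise_dmrs <- function(meth_a, meth_b, context, layout, bin_size = 100,
                          min_cytosines = 4, min_reads = 4,
                          delta_threshold = c(CG = 0.40, CHG = 0.20,
                                              CHH = 0.10),
                          alpha = 0.01, relative = FALSE) {
  validate_cytosines(meth_a, "meth_a")
  validate_cytosines(meth_b, "meth_b")
  stopifnot(context %in% c("CG", "CHG", "CHH"))
  ## work on column vectors; row-subsetting large data frames is the
  ## dominant cost at genome scale
  sel_a <- which(meth_a$context == context)
  sel_b <- which(meth_b$context == context)
  key_a <- paste(meth_a$chrom[sel_a], meth_a$pos[sel_a],
                 meth_a$strand[sel_a], sep = "\r")
  key_b <- paste(meth_b$chrom[sel_b], meth_b$pos[sel_b],
                 meth_b$strand[sel_b], sep = "\r")
  ix <- match(key_a, key_b)
  ok <- which(!is.na(ix))
  ia <- sel_a[ok]
  ib <- sel_b[ix[ok]]
  keep <- meth_a$coverage[ia] >= min_reads & meth_b$coverage[ib] >= min_reads
  ia <- ia[keep]
  ib <- ib[keep]
  a <- list(chrom = meth_a$chrom[ia], pos = meth_a$pos[ia],
            mc_count = meth_a$mc_count[ia], coverage = meth_a$coverage[ia])
  b <- list(mc_count = meth_b$mc_count[ib], coverage = meth_b$coverage[ib])
  if (length(ia) == 0) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), context = character(),
                      n_cytosines = integer(), level_a = numeric(),
                      level_b = numeric(), delta = numeric(),
                      pvalue = numeric(), padj = numeric(),
                      direction = character(), stringsAsFactors = FALSE)
    attr(out, "n_candidates") <- 0L
    return(out)
  }
  bin <- floor((a$pos - 1) / bin_size)
  key <- paste(a$chrom, bin, sep = "\r")
  n_cyt <- rowsum(rep(1L, length(key)), key)
  parts <- do.call(rbind, strsplit(rownames(n_cyt), "\r", fixed = TRUE))
  agg <- function(v) as.numeric(rowsum(v, key))
  cand <- data.frame(chrom = parts[, 1],
                     start = as.numeric(parts[, 2]) * bin_size,
                     stringsAsFactors = FALSE)
  cand$end <- cand$start + bin_size
  cand$context <- context
  cand$n_cytosines <- as.integer(n_cyt)
  cand$mc_a <- agg(a$mc_count); cand$cov_a <- agg(a$coverage)
  cand$mc_b <- agg(b$mc_count); cand$cov_b <- agg(b$coverage)
  cand <- cand[cand$n_cytosines >= min_cytosines, , drop = FALSE]
  cand$level_a <- cand$mc_a / cand$cov_a
  cand$level_b <- cand$mc_b / cand$cov_b
  cand$delta <- cand$level_a - cand$level_b
  cand$pvalue <- fisher_2x2_p(cand$mc_a, cand$cov_a, cand$mc_b, cand$cov_b)
  cand$padj <- stats::p.adjust(cand$pvalue, method = "BH")
  effect <- if (relative) {
    abs(cand$delta) / pmax(cand$level_a, cand$level_b, 1e-12)
  } else abs(cand$delta)
  hit <- cand$padj <= alpha & effect >= delta_threshold[[context]]
  out <- cand[hit, , drop = FALSE]
  out$direction <- ifelse(out$delta < 0, "hypo", "hyper")
  out <- out[order(out$chrom, out$start, method = "radix"),
             c("chrom", "start", "end", "context", "n_cytosines",
               "level_a", "level_b", "delta", "pvalue", "padj",
               "direction"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_candidates") <- nrow(cand)
  attr(out, "candidates") <- cand
  out
}

#' Consensus DMRs across pairwise comparisons
#'
#' Keeps only the grid bins called, with the same direction and context,
#' in every one of the supplied pairwise DMR sets — the rule used both for
#' a mutant against its three wild-type controls (3/3) and for
#' tissue-vs-tissue comparisons over 3x3 replicates (9/9). Statistics are
#' retained from the first comparison; per-set deltas are kept in an audit
#' column.
#'
#' @param pairwise_sets list of [pairwise_dmrs()] results on the same grid
#'   and context.
#' @param mode consensus mode; only `"all"` (present in every set) is
#'   defined.
#' @return The consensus DMR data frame with an `all_deltas` audit column.
#' @export
consensus_dmrs <- function(pairwise_sets, mode = c("all")) {
  mode <- match.arg(mode)
  if (!length(pairwise_sets)) stop("need at least one pairwise DMR set")
  keys <- lapply(pairwise_sets, function(s)
    paste(s$chrom, s$start, s$context, s$direction, sep = "\r"))
  common <- Reduce(intersect, keys)
  first <- pairwise_sets[[1]]
  sel <- match(common, keys[[1]])
  out <- first[sel, , drop = FALSE]
  if (nrow(out)) {
    deltas <- vapply(seq_along(pairwise_sets), function(j)
      pairwise_sets[[j]]$delta[match(common, keys[[j]])],
      numeric(length(common)))
    if (length(common) == 1) deltas <- matrix(deltas, nrow = 1)
    out$all_deltas <- apply(deltas, 1, function(d)
      paste(sprintf("%.4f", d), collapse = ","))
  } else out$all_deltas <- character(0)
  out <- out[order(out$chrom, out$start, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate replicate pairings for a two-group consensus
#'
#' Lists every (replicate of group A) x (replicate of group B) comparison
#' feeding a consensus call: a mutant library against each of three
#' wild-type controls gives 1 x 3 = 3 comparisons, and a tissue-vs-tissue
#' contrast over triplicated wild types gives 3 x 3 = 9.
#'
#' @param reps_a,reps_b replicate labels (or counts) of the two groups.
#' @return Data frame with columns `a` and `b`, one row per comparison.
#' @export
replicate_pairings <- function(reps_a, reps_b) {
  if (length(reps_a) == 1 && is.numeric(reps_a))
    reps_a <- paste0("a", seq_len(reps_a))
  if (length(reps_b) == 1 && is.numeric(reps_b))
    reps_b <- paste0("b", seq_len(reps_b))
  if (!length(reps_a) || !length(reps_b))
    stop("both groups need at least one replicate")
  expand.grid(a = reps_a, b = reps_b, KEEP.OUT.ATTRS = FALSE,
              stringsAsFactors = FALSE)[, c("a", "b")]
}

#' Combine per-tissue-pair consensus DMRs into a unique list
#'
#' Unions consensus DMR sets from all tissue pairs by grid bin (and
#' direction), annotating each unique bin with the supporting pairs.
#'
#' @param consensus_sets named list of [consensus_dmrs()] results (one per
#'   tissue pair), same context.
#' @return Unique DMR data frame with a `supports` column naming the
#'   contributing tissue pairs.
#' @export
combine_tissue_dmrs <- function(consensus_sets) {
  if (is.null(names(consensus_sets)))
    names(consensus_sets) <- paste0("pair", seq_along(consensus_sets))
  all <- do.call(rbind, lapply(names(consensus_sets), function(nm) {
    s <- consensus_sets[[nm]]
    if (!nrow(s)) return(NULL)
    s$supports <- nm
    s
  }))
  if (is.null(all)) {
    out <- consensus_sets[[1]][0, , drop = FALSE]
    out$supports <- character(0)
    return(out)
  }
  key <- paste(all$chrom, all$start, all$context, all$direction, sep = "\r")
  supports <- tapply(all$supports, key, paste, collapse = ",")
  out <- all[!duplicated(key), , drop = FALSE]
  out$supports <- as.character(supports[paste(out$chrom, out$start,
                                              out$context, out$direction,
                                              sep = "\r")])
  out <- out[order(out$chrom, out$start, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write DMRs as a BED6+ TSV
#'
#' Tab-separated with header: coordinates, context, direction, delta,
#' adjusted p and any audit columns present.
#'
#' @param dmrs a DMR data frame.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_dmrs <- function(dmrs, path) {
  utils::write.table(dmrs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
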