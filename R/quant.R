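#' Quantify 24nt reads over master clusters
#'
#' Counts, per sample, the exactly-24nt reads overlapping each cluster by
#' at least 1 bp (raw counts, no library adjustment). Clusters must be
#' non-overlapping (master clusters are, by construction).
#'
#' @param clusters master cluster interval data frame with an `id` column.
#' @param read_sets named list of read data frames (columns `chrom`,
#'   `start`, `end`, `length`), one per sample.
#' @param total_mapped_reads named numeric vector of total mapped reads of
#'   all size classes, one per sample; defaults to `nrow()` of each read
#'   set.
#' @return A `count_matrix` list: `counts` (clusters x samples integer
#'   matrix), `total_mapped_reads`, and `widths` (bp per cluster).
#' @export
count_24nt <- function(clusters, read_sets, total_mapped_reads = NULL) {
  validate_intervals(clusters, "clusters")
  if (is.null(clusters$id)) clusters$id <- sprintf("mc%05d",
                                                   seq_len(nrow(clusters)))
  s <- sort_intervals(clusters)
  if (nrow(s) > 1) {
    same <- s$chrom[-nrow(s)] == s$chrom[-1]
    if (any(same & s$end[-nrow(s)] > s$start[-1]))
      stop("clusters must be non-overlapping")
  }
  if (is.null(names(read_sets)))
    names(read_sets) <- paste0("sample", seq_along(read_sets))
  if (is.null(total_mapped_reads))
    total_mapped_reads <- vapply(read_sets, nrow, numeric(1))
  counts <- vapply(read_sets, function(r) {
    if (is.null(r$length)) r$length <- r$end - r$start
    count_per_bin(r[r$length == 24, , drop = FALSE], clusters)
  }, integer(nrow(clusters)))
  if (nrow(clusters) == 1)
    counts <- matrix(counts, nrow = 1,
                     dimnames = list(NULL, names(read_sets)))
  rownames(counts) <- clusters$id
  structure(list(counts = counts,
                 total_mapped_reads = total_mapped_reads[names(read_sets)],
                 widths = stats::setNames(clusters$end - clusters$start,
                                          clusters$id)),
            class = "count_matrix")
}

#' Fpkm normalisation of a 24nt count matrix
#'
#' fpkm = count / (cluster length in kb x total mapped reads in millions),
#' using total mapped reads of all size classes.
#'
#' @param cm a [count_24nt()] result.
#' @return Numeric matrix of fpkm values, clusters x samples.
#' @export
fpkm_24nt <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  sweep(sweep(cm$counts, 1, cm$widths / 1000, "/"),
        2, cm$total_mapped_reads / 1e6, "/")
}

#' Wild-type-anchored size factors
#'
#' Size factors for the wild-type samples are the DESeq-style
#' median-of-ratios computed among the wild-type columns only. Each other
#' sample's factor is then anchored to sequencing depth rather than to its
#' (possibly globally collapsed) 24nt content:
#' `mean(WT factor / WT total mapped reads) x own total mapped reads`.
#' This keeps genuinely genome-wide losses of 24nt-siRNAs (as in a Pol-IV
#' null) visible as reductions instead of being normalised away.
#'
#' @param cm a [count_24nt()] result.
#' @param wt_samples character vector of wild-type sample names (>= 2).
#' @return Named numeric vector of size factors for every sample.
#' @export
wt_anchored_size_factors <- function(cm, wt_samples) {
  stopifnot(inherits(cm, "count_matrix"))
  if (length(wt_samples) < 2) stop("need at least 2 wild-type samples")
  if (!all(wt_samples %in% colnames(cm$counts)))
    stop("unknown wild-type sample name(s)")
  wt <- cm$counts[, wt_samples, drop = FALSE]
  loggeo <- rowMeans(log(wt))
  use <- is.finite(loggeo)
  if (!any(use))
    stop("no cluster has positive counts in all wild-type samples")
  wt_factors <- apply(wt[use, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - loggeo[use])))
  anchor <- mean(wt_factors / cm$total_mapped_reads[wt_samples])
  sf <- anchor * cm$total_mapped_reads
  sf[wt_samples] <- wt_factors
  sf[colnames(cm$counts)]
}

#' Differential 24nt-siRNA cluster test against wild-type controls
#'
#' Per-cluster negative-binomial two-group comparison on size-factor
#' normalised counts: dispersion by method of moments from the replicated
#' group(s), floored at `min_dispersion`; Wald test on the log2 fold
#' change; Benjamini-Hochberg adjustment across testable clusters.
#' Clusters with zero counts in every sample are `untestable`. Reduced
#' calls require `log2FC <= lfc_threshold` and `FDR <= fdr_threshold`
#' (symmetrically `increased` for the opposite sign). When a group's
#' normalised mean is zero, a pseudocount of one normalised read is used
#' for the reported fold change (flagged in `zero_mean`).
#'
#' @param cm a [count_24nt()] result.
#' @param size_factors named size factors (see
#'   [wt_anchored_size_factors()]).
#' @param groups named character vector mapping every sample to `"WT"` or
#'   a mutant label; exactly two levels, the WT side with >= 2 samples.
#' @param lfc_threshold log2 fold-change cutoff for a reduced call
#'   (default -1, i.e. at least a 2-fold reduction).
#' @param fdr_threshold FDR cutoff (default 0.01).
#' @param min_dispersion dispersion floor.
#' @return A data frame (one row per cluster): `id`, `base_mean_wt`,
#'   `base_mean_mut`, `log2fc`, `pvalue`, `padj`, `zero_mean`, and
#'   `status` in `reduced_DE`, `increased`, `unchanged`, `untestable`.
#' @export
differential_clusters <- function(cm, size_factors, groups,
                                  lfc_threshold = -1, fdr_threshold = 0.01,
                                  min_dispersion = 0.01) {
  stopifnot(inherits(cm, "count_matrix"))
  samples <- colnames(cm$counts)
  if (!all(samples %in% names(groups)) || !all(names(groups) %in% samples))
    stop("groups must name exactly the samples of the count matrix")
  if (!all(samples %in% names(size_factors)))
    stop("size_factors must cover all samples")
  groups <- groups[samples]
  lev <- unique(groups)
  if (length(lev) != 2 || !"WT" %in% lev)
    stop("groups must have exactly two levels, one of them 'WT'")
  mut <- setdiff(lev, "WT")
  wt_ix <- which(groups == "WT")
  mut_ix <- which(groups == mut)
  if (length(wt_ix) < 2) stop("the WT group needs >= 2 samples")
  sf <- size_factors[samples]
  norm <- sweep(cm$counts, 2, sf, "/")
  q_wt <- rowMeans(norm[, wt_ix, drop = FALSE])
  q_mut <- rowMeans(norm[, mut_ix, drop = FALSE])
  testable <- rowSums(cm$counts) > 0
  alpha <- mom_dispersion(norm, list(wt_ix, mut_ix), sf, min_dispersion)
  ## Wald statistic on log2(q_mut / q_wt); delta-method variance of the
  ## log of a group mean of NB counts rescaled by size factors
  var_log2_group <- function(q, ix) {
    q1 <- pmax(q, 1 / length(ix))           # guard for zero-mean groups
    v <- (q1 * sum(1 / sf[ix]) + alpha * q1^2 * length(ix)) / length(ix)^2
    v / (q1^2 * log(2)^2)
  }
  zero_mean <- testable & (q_wt == 0 | q_mut == 0)
  q_wt_eff <- ifelse(q_wt == 0, 1 / length(wt_ix), q_wt)
  q_mut_eff <- ifelse(q_mut == 0, 1 / length(mut_ix), q_mut)
  log2fc <- log2(q_mut_eff) - log2(q_wt_eff)
  se <- sqrt(var_log2_group(q_wt, wt_ix) + var_log2_group(q_mut, mut_ix))
  z <- log2fc / se
  pvalue <- 2 * stats::pnorm(-abs(z))
  pvalue[!testable] <- NA_real_
  log2fc[!testable] <- NA_real_
  padj <- rep(NA_real_, length(pvalue))
  padj[testable] <- stats::p.adjust(pvalue[testable], method = "BH")
  status <- rep("unchanged", nrow(cm$counts))
  status[!testable] <- "untestable"
  sig <- testable & !is.na(padj) & padj <= fdr_threshold
  status[sig & log2fc <= lfc_threshold] <- "reduced_DE"
  status[sig & log2fc >= -lfc_threshold] <- "increased"
  data.frame(id = rownames(cm$counts), base_mean_wt = q_wt,
             base_mean_mut = q_mut, log2fc = log2fc, pvalue = pvalue,
             padj = padj, zero_mean = zero_mean, status = status,
             stringsAsFactors = FALSE, row.names = NULL)
}

## Method-of-moments NB dispersion per cluster, pooled over groups with
## replicates: on the normalised scale Var(K/s) = mu * E[1/s] + alpha mu^2.
#' @noRd
mom_dispersion <- function(norm, group_idx, sf, min_dispersion) {
  num <- den <- rep(0, nrow(norm))
  for (ix in group_idx) {
    if (length(ix) < 2) next
    m <- rowMeans(norm[, ix, drop = FALSE])
    v <- apply(norm[, ix, drop = FALSE], 1, stats::var)
    a <- (v - m * mean(1 / sf[ix])) / m^2
    ok <- is.finite(a)
    w <- length(ix) - 1
    num[ok] <- num[ok] + w * a[ok]
    den[ok] <- den[ok] + w
  }
  alpha <- ifelse(den > 0, num / pmax(den, 1), min_dispersion)
  pmax(alpha, min_dispersion)
}

#' Rescue reduced clusters by hypo-CHH DMR overlap
#'
#' Adds clusters missed by the differential test but carrying independent
#' methylation evidence: hypo-CHH DMRs already overlapping `reduced_DE`
#' clusters are set aside, the remaining DMRs select master clusters
#' (>= 1 bp overlap), and among those, clusters reduced by at least ~25%
#' (`log2FC < rescue_lfc`, default -0.415 = log2(0.75)) gain the status
#' `reduced_rescued`. No existing status is ever removed.
#'
#' @param diff a [differential_clusters()] table.
#' @param hypo_chh_dmrs interval data frame of qualifying hypo-CHH DMRs
#'   (typically the mutant's consensus hypo-CHH DMRs intersected with the
#'   Pol-IV-dependent set).
#' @param clusters master cluster intervals matching `diff$id`.
#' @param rescue_lfc log2 fold-change cutoff for rescue.
#' @return The `diff` table with `status` updated to `reduced_rescued`
#'   where applicable.
#' @export
rescue_reduced_clusters <- function(diff, hypo_chh_dmrs, clusters,
                                    rescue_lfc = log2(0.75)) {
  validate_intervals(clusters, "clusters")
  if (!all(diff$id %in% clusters$id))
    stop("diff table and clusters must share ids")
  cl <- clusters[match(diff$id, clusters$id), , drop = FALSE]
  de_cl <- cl[diff$status == "reduced_DE", , drop = FALSE]
  free_dmrs <- subtract_overlapping(hypo_chh_dmrs, de_cl)
  hit <- overlaps_any(cl, free_dmrs)
  promote <- hit & diff$status != "reduced_DE" & !is.na(diff$log2fc) &
    diff$log2fc < rescue_lfc
  diff$status[promote] <- "reduced_rescued"
  diff
}

#' Reduced-cluster set from a differential table
#'
#' @param diff a [differential_clusters()] table, possibly after
#'   [rescue_reduced_clusters()].
#' @return Character vector of cluster ids with status `reduced_DE` or
#'   `reduced_rescued`.
#' @export
reduced_set <- function(diff) {
  diff$id[diff$status %in% c("reduced_DE", "reduced_rescued")]
}

#' CLSY-dependency categories and abundance fractions
#'
#' Within a panel of genotypes (the singles or the doubles), every
#' Pol-IV-dependent cluster is assigned a category: reduced in exactly one
#' panel genotype (`<genotype>-sp`), reduced in several (an intersection
#' label joined with `"∩"`), reduced in none of the panel but present in
#' the quadruple-mutant set (`quad-residual`, the "quad minus union"
#' slice), or in none of those (`poliv-specific`). Abundance fractions
#' weight each category by its clusters' wild-type 24nt read counts and
#' sum to one over the Pol-IV-dependent universe. Clusters reduced in a
#' panel genotype but absent from the quadruple set are retained and
#' flagged for audit.
#'
#' @param reduced_sets named list (panel genotype -> character vector of
#'   reduced cluster ids).
#' @param quad_set reduced cluster ids of the quadruple mutant.
#' @param poliv_set reduced cluster ids of the Pol-IV null (the universe).
#' @param wt_counts named numeric vector of wild-type 24nt counts per
#'   cluster id.
#' @return A list: `clusters` (data frame with id, category, audit flag)
#'   and `fractions` (named numeric vector summing to 1).
#' @export
dependency_categories <- function(reduced_sets, quad_set, poliv_set,
                                  wt_counts) {
  if (is.null(names(reduced_sets)))
    stop("reduced_sets must be a named list")
  universe <- unique(poliv_set)
  membership <- vapply(reduced_sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1)
    membership <- matrix(membership, nrow = 1,
                         dimnames = list(NULL, names(reduced_sets)))
  n_hit <- rowSums(membership)
  category <- character(length(universe))
  for (i in seq_along(universe)) {
    g <- names(reduced_sets)[membership[i, ]]
    category[i] <- if (n_hit[i] == 1) paste0(g, "-sp")
      else if (n_hit[i] > 1) paste(g, collapse = "∩")
      else if (universe[i] %in% quad_set) "quad-residual"
      else "poliv-specific"
  }
  flagged <- n_hit > 0 & !(universe %in% quad_set)
  w <- wt_counts[universe]
  w[is.na(w)] <- 0
  fr <- tapply(w, category, sum) / sum(w)
  list(clusters = data.frame(id = universe, category = category,
                             not_in_quad = flagged,
                             stringsAsFactors = FALSE),
       fractions = fr[sort(unique(category))])
}
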