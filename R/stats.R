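#' Siren loci by cumulative abundance
#'
#' Orders clusters by descending wild-type-average fpkm and designates as
#' siren loci the shortest prefix whose cumulative fpkm reaches the target
#' fraction (default 80%) of the total — the small set of ultra-highly
#' expressed clusters that dominates a tissue's 24nt-siRNA output.
#'
#' @param wt_avg_fpkm named numeric vector of per-cluster wild-type
#'   average fpkm (>= 0, not all zero).
#' @param target cumulative fraction defining the siren set.
#' @return A `siren_result` list: `table` (clusters in descending order
#'   with `fpkm`, `cumulative_fraction`, `is_siren`), `siren_ids`,
#'   `target`.
#' @export
siren_loci <- function(wt_avg_fpkm, target = 0.80) {
  if (any(wt_avg_fpkm < 0)) stop("fpkm values must be >= 0")
  if (all(wt_avg_fpkm == 0)) stop("all-zero expression; no siren set")
  if (target <= 0 || target > 1) stop("target must be in (0, 1]")
  if (is.null(names(wt_avg_fpkm)))
    names(wt_avg_fpkm) <- paste0("cluster", seq_along(wt_avg_fpkm))
  ## stable ordering: descending fpkm, ties by name for determinism
  o <- order(-wt_avg_fpkm, names(wt_avg_fpkm), method = "radix")
  fpkm <- wt_avg_fpkm[o]
  cum <- cumsum(fpkm) / sum(fpkm)
  n_siren <- which(cum >= target - 1e-12)[1]
  tab <- data.frame(id = names(fpkm), rank = seq_along(fpkm), fpkm = fpkm,
                    cumulative_fraction = cum,
                    is_siren = seq_along(fpkm) <= n_siren,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, siren_ids = tab$id[tab$is_siren],
                 target = target),
            class = "siren_result")
}

#' @export
print.siren_result <- function(x, ...) {
  cat("siren_result:", length(x$siren_ids), "of", nrow(x$table),
      "clusters reach", sprintf("%.0f%%", 100 * x$target),
      "of cumulative fpkm\n")
  invisible(x)
}

#' K-means expression classes under 1-minus-Pearson distance
#'
#' Partitions cluster expression profiles (rows) into `k` classes by
#' k-means under the one-minus-Pearson-correlation distance. Rows are
#' z-scored first, which makes squared Euclidean distance an affine
#' function of 1 - Pearson, so standard k-means optimises the intended
#' criterion. Rows with zero variance (flat profiles, where the
#' correlation distance is undefined) go to a dedicated degenerate class
#' labelled 0. Classes are relabelled 1..k by descending mean expression
#' so labels are stable across runs.
#'
#' @param expr numeric matrix, clusters x tissues (e.g. log2(fpkm + 1)).
#' @param k number of classes (10 for the landscape decomposition, 8 for
#'   the dependency-group views).
#' @param seed RNG seed; fixed seed gives identical labels.
#' @param nstart,iter_max passed to [stats::kmeans()].
#' @return Integer vector of class labels (0 = degenerate), named by row.
#' @export
classify_clusters <- function(expr, k = 10, seed = 1, nstart = 25,
                              iter_max = 100) {
  expr <- as.matrix(expr)
  if (k < 1) stop("k must be >= 1")
  v <- apply(expr, 1, stats::var)
  usable <- which(v > 0)
  if (k > length(usable))
    stop("k exceeds the number of rows with nonzero variance")
  z <- t(scale(t(expr[usable, , drop = FALSE])))
  fit <- with_seed(seed,
                   stats::kmeans(z, centers = k, nstart = nstart,
                                 iter.max = iter_max))
  labels <- integer(nrow(expr))
  labels[usable] <- fit$cluster
  ## relabel by descending class mean of the original values
  means <- tapply(rowMeans(expr[usable, , drop = FALSE]), fit$cluster, mean)
  remap <- integer(k)
  remap[order(-means)] <- seq_len(k)
  labels[usable] <- remap[fit$cluster]
  stats::setNames(labels, rownames(expr))
}

#' Total 1-minus-Pearson dispersion of a labelling
#'
#' Sum over classes of within-class distances to the class's mean profile,
#' under 1 - Pearson. Used to compare a clustering against random
#' labellings.
#'
#' @param expr numeric matrix, rows profiles.
#' @param labels class labels (label 0 rows are ignored).
#' @return Total within-class dispersion.
#' @export
pearson_dispersion <- function(expr, labels) {
  expr <- as.matrix(expr)
  tot <- 0
  for (g in setdiff(unique(labels), 0)) {
    rows <- expr[labels == g, , drop = FALSE]
    centre <- colMeans(rows)
    if (stats::var(centre) == 0) next
    tot <- tot + sum(1 - apply(rows, 1, function(r)
      suppressWarnings(stats::cor(r, centre))), na.rm = TRUE)
  }
  tot
}

#' Coefficient-of-variation comparison between two cluster sets
#'
#' Per-locus CV = sample standard deviation / mean across tissues
#' (n - 1 denominator, appropriate for the 3-4 tissue profiles); loci with
#' zero mean are excluded with a warning. The two sets' CV distributions
#' are compared by a two-sided Welch t-test.
#'
#' @param values numeric matrix, loci x tissues (expression or percent
#'   methylation).
#' @param set_a,set_b row names (or indices) of the two locus sets.
#' @return A list: `cv_a`, `cv_b` (named per-locus CVs), `p_value`,
#'   `t_statistic`.
#' @export
cv_comparison <- function(values, set_a, set_b) {
  values <- as.matrix(values)
  if (ncol(values) < 2) stop("need values across >= 2 tissues")
  cv_of <- function(rows) {
    m <- values[rows, , drop = FALSE]
    mu <- rowMeans(m)
    zero <- mu == 0
    if (any(zero)) {
      warning(sum(zero), " zero-mean locus/loci excluded from CV")
      m <- m[!zero, , drop = FALSE]
      mu <- mu[!zero]
    }
    apply(m, 1, stats::sd) / mu
  }
  cv_a <- cv_of(set_a)
  cv_b <- cv_of(set_b)
  tt <- stats::t.test(cv_a, cv_b, alternative = "two.sided")
  list(cv_a = cv_a, cv_b = cv_b, p_value = tt$p.value,
       t_statistic = unname(tt$statistic))
}

#' Permutation test of chromosome-arm enrichment
#'
#' Tests whether a query set of clusters is unusually arm- (or
#' pericentromere-) biased relative to the master set: the observed arm
#' fraction (midpoint compartment rule) is compared with the null
#' distribution obtained by drawing `n_perm` random subsets of the same
#' size from the master set without replacement. The two-sided p-value
#' uses the add-one estimator
#' p = (1 + #\{null at least as far from the null mean\}) / (1 + n_perm),
#' so p is never zero and the extreme case reports 1/(n_perm + 1).
#'
#' @param query_ids ids of the query clusters (subset of `master$id`).
#' @param master master cluster interval data frame with `id`.
#' @param layout a [genome_layout()].
#' @param n_perm number of permutations (default 1000).
#' @param seed RNG seed.
#' @param alternative `"two.sided"` (deviation from the null mean in
#'   either direction) or `"greater"`/`"less"` on the arm fraction.
#' @return A `permutation_result` list: `observed_arm_fraction`,
#'   `null_fractions`, `p_value`, `n_perm`, `seed`.
#' @export
arm_enrichment_permutation <- function(query_ids, master, layout,
                                       n_perm = 1000, seed = 1,
                                       alternative = c("two.sided",
                                                       "greater", "less")) {
  alternative <- match.arg(alternative)
  validate_intervals(master, "master")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (is.null(master$id)) stop("master clusters need an id column")
  if (!all(query_ids %in% master$id))
    stop("query ids must be a subset of the master set")
  if (length(query_ids) > nrow(master))
    stop("query larger than the master set")
  arm <- assign_compartment(master, layout) == "arm"
  names(arm) <- master$id
  observed <- mean(arm[query_ids])
  null <- with_seed(seed, vapply(seq_len(n_perm), function(i)
    mean(arm[sample.int(length(arm), length(query_ids))]), numeric(1)))
  p <- switch(alternative,
    two.sided = {
      dev <- abs(observed - mean(null))
      (1 + sum(abs(null - mean(null)) >= dev - 1e-12)) / (1 + n_perm)
    },
    greater = (1 + sum(null >= observed - 1e-12)) / (1 + n_perm),
    less = (1 + sum(null <= observed + 1e-12)) / (1 + n_perm))
  structure(list(observed_arm_fraction = observed, null_fractions = null,
                 p_value = p, n_perm = n_perm, seed = seed,
                 alternative = alternative),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "permutation_result: observed arm fraction %.3f, null mean %.3f, p = %.4g (%s, %d permutations)\n",
    x$observed_arm_fraction, mean(x$null_fractions), x$p_value,
    x$alternative, x$n_perm))
  invisible(x)
}
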