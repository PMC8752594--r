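#' Wild-type replicate clusters and core set for one tissue
#'
#' Simulates the tissue's wild-type replicate libraries from a landscape,
#' calls clusters in each, and intersects them into the tissue's core set.
#' Replicate seeds are substreams of the config seed keyed by tissue and
#' replicate index.
#'
#' @param landscape a [simulate_landscape()] result.
#' @param tissue tissue name.
#' @param n_reps number of wild-type replicates (the design uses 3).
#' @param library_size per-library total mapped reads; defaults to the
#'   config value.
#' @param mincov,pad cluster-calling parameters (see [call_clusters()]).
#' @return A list: `samples` (replicate read sets), `cluster_sets`
#'   (per-replicate calls) and `core` (the tissue core set).
#' @export
wt_core_for_tissue <- function(landscape, tissue, n_reps = 3,
                               library_size = NULL, mincov = 20,
                               pad = 100) {
  cfg <- landscape$config
  samples <- lapply(seq_len(n_reps), function(i)
    simulate_sirna_sample(
      landscape, tissue, "WT", library_size,
      seed = substream_seed(cfg$seed,
                            paste(tissue, "WT", i, "sirna", sep = "/"))))
  names(samples) <- paste0(tissue, "_WT", seq_len(n_reps))
  cluster_sets <- lapply(samples, function(s)
    call_clusters(s$reads, mincov = mincov, pad = pad))
  core <- core_clusters(cluster_sets[[1]], cluster_sets[[2]],
                        cluster_sets[[3]])
  list(samples = samples, cluster_sets = cluster_sets, core = core)
}

#' Master cluster list from simulated wild-type data
#'
#' Runs [wt_core_for_tissue()] for every tissue and merges the core sets
#' into the master cluster list.
#'
#' @param landscape a [simulate_landscape()] result.
#' @param tissues tissues to include; defaults to all configured tissues.
#' @param ... passed to [wt_core_for_tissue()].
#' @return A list: `master` (master cluster intervals), `core_sets`, and
#'   `wt_samples` (named list of per-tissue replicate samples).
#' @export
build_master_clusters <- function(landscape, tissues = NULL, ...) {
  if (is.null(tissues)) tissues <- landscape$config$tissues
  per_tissue <- lapply(tissues, function(t)
    wt_core_for_tissue(landscape, t, ...))
  names(per_tissue) <- tissues
  core_sets <- lapply(per_tissue, `[[`, "core")
  list(master = master_clusters(core_sets), core_sets = core_sets,
       wt_samples = lapply(per_tissue, `[[`, "samples"))
}

#' Differential clusters for a panel of genotypes in one tissue
#'
#' Quantifies 24nt reads over the master clusters for the tissue's
#' wild-type replicates plus one simulated library per mutant genotype,
#' derives wild-type-anchored size factors, and tests each genotype
#' against the wild-type controls.
#'
#' @param landscape a [simulate_landscape()] result.
#' @param master master cluster intervals (with `id`).
#' @param tissue tissue name.
#' @param wt_samples list of the tissue's wild-type replicate samples
#'   (from [wt_core_for_tissue()]).
#' @param genotypes mutant genotype names to test.
#' @param library_size per-library total mapped reads.
#' @param ... passed to [differential_clusters()].
#' @return A list: `counts` (the [count_24nt()] object over all samples),
#'   `size_factors`, and `diff` (named list of per-genotype differential
#'   tables).
#' @export
genotype_differential <- function(landscape, master, tissue, wt_samples,
                                  genotypes, library_size = NULL, ...) {
  mut_samples <- lapply(genotypes, function(g)
    simulate_sirna_sample(landscape, tissue, g, library_size))
  names(mut_samples) <- paste0(tissue, "_", genotypes)
  all_samples <- c(wt_samples, mut_samples)
  cm <- count_24nt(master,
                   lapply(all_samples, `[[`, "reads"),
                   vapply(all_samples, `[[`, numeric(1),
                          "total_mapped_reads"))
  wt_names <- names(wt_samples)
  sf <- wt_anchored_size_factors(cm, wt_names)
  diff <- lapply(genotypes, function(g) {
    cols <- c(wt_names, paste0(tissue, "_", g))
    sub <- structure(list(counts = cm$counts[, cols, drop = FALSE],
                          total_mapped_reads = cm$total_mapped_reads[cols],
                          widths = cm$widths),
                     class = "count_matrix")
    groups <- stats::setNames(c(rep("WT", length(wt_names)), g), cols)
    differential_clusters(sub, sf[cols], groups, ...)
  })
  names(diff) <- genotypes
  list(counts = cm, size_factors = sf, diff = diff)
}

#' Consensus hypo-CHH DMRs for one mutant against wild-type controls
#'
#' Simulates (or accepts) three wild-type methylomes and one mutant
#' methylome for a tissue, calls pairwise CHH DMRs of the mutant against
#' each control, and intersects the three calls.
#'
#' @param landscape a [simulate_landscape()] result.
#' @param tissue tissue name.
#' @param genotype mutant genotype.
#' @param wt_meths optional list of three wild-type methylomes to reuse
#'   across mutants.
#' @param context methylation context (default CHH).
#' @param ... passed to [pairwise_dmrs()].
#' @return Consensus DMR data frame (hypo and hyper; filter on
#'   `direction` as needed).
#' @export
mutant_consensus_dmrs <- function(landscape, tissue, genotype,
                                  wt_meths = NULL, context = "CHH", ...) {
  cfg <- landscape$config
  if (is.null(wt_meths))
    wt_meths <- lapply(1:3, function(i)
      simulate_methylome(
        landscape, tissue, "WT",
        seed = substream_seed(cfg$seed,
                              paste(tissue, "WT", i, "meth", sep = "/"))))
  mut <- simulate_methylome(landscape, tissue, genotype)
  sets <- lapply(wt_meths, function(w)
    pairwise_dmrs(mut, w, context = context, layout = landscape$layout,
                  ...))
  consensus_dmrs(sets)
}

#' Consensus DMRs between two tissues over replicated wild types
#'
#' Simulates `n_reps` wild-type methylome replicates per tissue, runs all
#' [replicate_pairings()] comparisons (`n_reps` x `n_reps`, i.e. 9 for
#' triplicates), and keeps the bins called consistently in every one.
#'
#' @param landscape a [simulate_landscape()] result.
#' @param tissue_a,tissue_b the two tissues; comparisons are oriented
#'   `tissue_a` vs `tissue_b`.
#' @param n_reps wild-type replicates per tissue (the design uses 3).
#' @param context methylation context.
#' @param ... passed to [pairwise_dmrs()].
#' @return Consensus DMR data frame with attribute `n_comparisons`.
#' @export
tissue_consensus_dmrs <- function(landscape, tissue_a, tissue_b,
                                  n_reps = 3, context = "CHH", ...) {
  cfg <- landscape$config
  meths <- function(tissue) lapply(seq_len(n_reps), function(i)
    simulate_methylome(
      landscape, tissue, "WT",
      seed = substream_seed(cfg$seed,
                            paste(tissue, "WT", i, "meth", sep = "/"))))
  ma <- meths(tissue_a)
  mb <- meths(tissue_b)
  pairs <- replicate_pairings(seq_len(n_reps), seq_len(n_reps))
  sets <- lapply(seq_len(nrow(pairs)), function(j)
    pairwise_dmrs(ma[[as.integer(pairs$a[j])]],
                  mb[[as.integer(pairs$b[j])]],
                  context = context, layout = landscape$layout, ...))
  out <- consensus_dmrs(sets)
  attr(out, "n_comparisons") <- nrow(pairs)
  out
}
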