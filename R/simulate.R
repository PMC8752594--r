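#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded simulation calls
#' never perturb the surrounding random stream.
#'
#' @param seed integer RNG seed.
#' @param code expression to evaluate under the seed.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Derive a per-sample RNG substream seed
#'
#' Hashes a sample key (e.g. "flower/WT/rep1/sirna") together with the
#' global seed into a 31-bit integer, so adding samples never perturbs the
#' streams of existing ones.
#'
#' @param seed global integer seed.
#' @param key character key identifying the sample and data type.
#' @return A single integer in [0, 2^31 - 1].
#' @export
substream_seed <- function(seed, key) {
  p <- 2147483647
  h <- as.numeric(seed) %% p
  for (v in utf8ToInt(key)) h <- (h * 131 + v) %% p
  as.integer(h)
}

#' Simulation configuration for the tissue-by-genotype study design
#'
#' Defines the synthetic genome, the 24nt-siRNA cluster classes with their
#' per-tissue expression profiles, the siren settings, the genotype effect
#' map, and the methylome model. Defaults emulate a four-tissue design
#' (flower, ovule, leaf, rosette) with three wild-type replicates plus
#' single, double and quadruple chromatin-remodeler mutants and a Pol-IV
#' null: class 10 is a small set of ovule-dominant siren clusters whose
#' expected fpkm is engineered to account for `siren_fraction` of total
#' ovule 24nt-siRNA fpkm; `clsy1`/`clsy2` ablate classes 1/2, the
#' `clsy12` double additionally ablates redundantly-controlled classes 3
#' and 8, `clsy3`/`clsy4` ablate classes 10/9, `clsy34` ablates classes
#' 8-10, the quadruple ablates the union, and `poliv` ablates everything.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length (bp).
#' @param pericentromere_fraction fraction of each chromosome occupied by a
#'   central pericentromeric block.
#' @param tissues tissue names.
#' @param class_profiles numeric matrix (classes x tissues) of expected
#'   wild-type fpkm per cluster; the siren class / siren tissue entry is
#'   recomputed from `siren_fraction`.
#' @param n_clusters integer vector, clusters per class.
#' @param arm_bias per-class probability that a cluster is placed in the
#'   chromosome arms (vs the pericentromere).
#' @param siren_class index of the siren class.
#' @param siren_fraction target share of total fpkm held by the siren class
#'   in `siren_tissue`.
#' @param siren_tissue tissue in which sirens dominate.
#' @param genotype_effects named list: genotype -> named vector of
#'   multiplicative effects on class expression (0 = ablation); classes not
#'   named keep effect 1; `"WT"` must map to no effects.
#' @param nb_dispersion negative-binomial dispersion of per-cluster counts.
#' @param in_cluster_fraction expected fraction of a wild-type library's
#'   mapped reads (all size classes) that fall in 24nt-siRNA clusters; the
#'   remainder represents other size classes and dispersed loci and is
#'   carried in the library-size metadata, not emitted as placements.
#' @param background_rate expected dispersed background read placements
#'   per kb of genome (sparse noise entering cluster calling).
#' @param cluster_width_range min/max cluster width (bp).
#' @param cluster_length_probs read-length distribution (21-24 nt) inside
#'   clusters; 24 nt dominant.
#' @param background_length_probs read-length distribution of background
#'   reads.
#' @param context_density cytosines per bp for each context (CG, CHG, CHH).
#' @param baseline_methylation per-context baseline methylation level.
#' @param rddm_chh CHH methylation level inside active clusters
#'   (RdDM-coupled).
#' @param active_fpkm minimum expected fpkm for a cluster to carry
#'   RdDM-coupled CHH methylation in a tissue.
#' @param mean_coverage mean per-cytosine bisulfite coverage.
#' @param library_size default total mapped reads per small-RNA library.
#' @param seed global simulation seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chroms = 2,
                       chrom_length = 2e6,
                       pericentromere_fraction = 0.3,
                       tissues = c("flower", "ovule", "leaf", "rosette"),
                       class_profiles = NULL,
                       n_clusters = NULL,
                       arm_bias = NULL,
                       siren_class = 10,
                       siren_fraction = 0.8,
                       siren_tissue = "ovule",
                       genotype_effects = NULL,
                       nb_dispersion = 0.05,
                       in_cluster_fraction = 0.5,
                       background_rate = 0.5,
                       cluster_width_range = c(400, 1200),
                       cluster_length_probs = c(`21` = 0.04, `22` = 0.03,
                                                `23` = 0.03, `24` = 0.90),
                       background_length_probs = c(`21` = 0.25, `22` = 0.25,
                                                   `23` = 0.25, `24` = 0.25),
                       context_density = c(CG = 0.04, CHG = 0.04, CHH = 0.25),
                       baseline_methylation = c(CG = 0.10, CHG = 0.05,
                                                CHH = 0.02),
                       rddm_chh = 0.30,
                       active_fpkm = 2,
                       mean_coverage = 20,
                       library_size = 5e5,
                       seed = 1) {
  if (is.null(class_profiles)) {
    class_profiles <- matrix(c(
      10, 2, 10, 10,   # class 1: broad, clsy1-dependent
       8, 2,  8,  8,   # class 2: broad, clsy2-dependent
      12, 3,  6,  6,   # class 3: redundantly clsy1/2-controlled
       5, 1, 20,  5,   # class 4: leaf-dominant, pol-iv-only
       5, 1,  5, 20,   # class 5: rosette-dominant, pol-iv-only
      20, 2,  5,  5,   # class 6: flower-dominant, pol-iv-only
       3, 3,  3,  3,   # class 7: low uniform, pol-iv-only
       6, 4,  6,  6,   # class 8: redundantly controlled across families
      10, 5,  2,  2,   # class 9: clsy4-dependent
      15, NA,  2,  2   # class 10: sirens; ovule entry set from siren_fraction
    ), nrow = 10, byrow = TRUE,
    dimnames = list(paste0("class", 1:10), tissues))
  }
  n_classes <- nrow(class_profiles)
  if (is.null(n_clusters))
    n_clusters <- c(rep(64L, n_classes - 1L), 20L)
  if (is.null(arm_bias))
    arm_bias <- c(rep(0.8, 3), rep(0.5, 4), rep(0.2, 3))[seq_len(n_classes)]
  if (is.null(genotype_effects)) {
    genotype_effects <- list(
      WT = numeric(0),
      clsy1 = c(class1 = 0),
      clsy2 = c(class2 = 0),
      clsy3 = c(class10 = 0),
      clsy4 = c(class9 = 0),
      clsy12 = c(class1 = 0, class2 = 0, class3 = 0, class8 = 0),
      clsy34 = c(class8 = 0, class9 = 0, class10 = 0),
      clsy1234 = c(class1 = 0, class2 = 0, class3 = 0,
                   class8 = 0, class9 = 0, class10 = 0),
      poliv = stats::setNames(rep(0, n_classes), rownames(class_profiles))
    )
  }
  cfg <- list(n_chroms = n_chroms, chrom_length = chrom_length,
              pericentromere_fraction = pericentromere_fraction,
              tissues = tissues, class_profiles = class_profiles,
              n_clusters = as.integer(n_clusters), arm_bias = arm_bias,
              siren_class = siren_class, siren_fraction = siren_fraction,
              siren_tissue = siren_tissue,
              genotype_effects = genotype_effects,
              nb_dispersion = nb_dispersion,
              in_cluster_fraction = in_cluster_fraction,
              background_rate = background_rate,
              cluster_width_range = cluster_width_range,
              cluster_length_probs = cluster_length_probs,
              background_length_probs = background_length_probs,
              context_density = context_density,
              baseline_methylation = baseline_methylation,
              rddm_chh = rddm_chh, active_fpkm = active_fpkm,
              mean_coverage = mean_coverage, library_size = library_size,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' @noRd
validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_chroms >= 1, cfg$chrom_length > 0)
  if (cfg$pericentromere_fraction < 0 || cfg$pericentromere_fraction > 1)
    stop("pericentromere_fraction must be in [0, 1]")
  if (cfg$siren_fraction <= 0 || cfg$siren_fraction >= 1)
    stop("siren_fraction must be in (0, 1)")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (any(cfg$arm_bias < 0 | cfg$arm_bias > 1))
    stop("arm_bias values must be in [0, 1]")
  if (any(unlist(cfg$genotype_effects) < 0))
    stop("genotype effects must be >= 0")
  if (!cfg$siren_tissue %in% cfg$tissues)
    stop("siren_tissue not among tissues")
  if (length(cfg$n_clusters) != nrow(cfg$class_profiles))
    stop("n_clusters must have one entry per class")
  bad <- is.na(cfg$class_profiles)
  bad[cfg$siren_class, cfg$siren_tissue] <- FALSE
  if (any(bad)) stop("class_profiles may be NA only at the siren entry")
  invisible(cfg)
}

#' Simulate the ground-truth landscape
#'
#' Places non-overlapping clusters per class with class-specific arm bias,
#' fixes per-tissue expected wild-type fpkm from the class profiles
#' (engineering the siren class to hold the configured share of total fpkm
#' in its dominant tissue), and lays down labelled cytosine positions for
#' the methylome model. Everything downstream (read and methylome sampling)
#' draws from this object, so planted truth and realisations always agree.
#'
#' @param config a [sim_config()].
#' @return A `true_landscape` list with elements `config`, `layout`,
#'   `clusters` (intervals + class + compartment), `expected_fpkm`
#'   (clusters x tissues), `siren_ids`, `cytosines` (chrom, 1-based pos,
#'   strand, context, cluster index or NA) and `genotypes`.
#' @export
simulate_landscape <- function(config) {
  validate_sim_config(config)
  layout <- default_layout(config)
  with_seed(substream_seed(config$seed, "landscape"), {
    clusters <- place_clusters(config, layout)
    profiles <- config$class_profiles
    ## engineer the siren share: siren fpkm so that the siren class holds
    ## siren_fraction of total fpkm in the siren tissue
    st <- config$siren_tissue
    sc <- config$siren_class
    cls <- clusters$class
    nonsiren_total <- sum(profiles[cls[cls != rownames(profiles)[sc]], st])
    n_siren <- sum(cls == rownames(profiles)[sc])
    profiles[sc, st] <- config$siren_fraction / (1 - config$siren_fraction) *
      nonsiren_total / n_siren
    expected_fpkm <- profiles[cls, , drop = FALSE]
    dimnames(expected_fpkm) <- list(clusters$id, config$tissues)
    cytosines <- place_cytosines(config, layout, clusters)
    structure(list(config = config, layout = layout, clusters = clusters,
                   expected_fpkm = expected_fpkm,
                   siren_ids = clusters$id[cls == rownames(profiles)[sc]],
                   cytosines = cytosines,
                   genotypes = names(config$genotype_effects)),
              class = "true_landscape")
  })
}

#' @export
print.true_landscape <- function(x, ...) {
  cat("true_landscape:", nrow(x$clusters), "planted clusters in",
      length(unique(x$clusters$class)), "classes;",
      length(x$siren_ids), "siren loci;",
      nrow(x$cytosines), "cytosines\n")
  invisible(x)
}

#' @noRd
default_layout <- function(config) {
  sizes <- stats::setNames(rep(config$chrom_length, config$n_chroms),
                           paste0("chr", seq_len(config$n_chroms)))
  half <- config$pericentromere_fraction / 2
  peri <- data.frame(
    chrom = names(sizes),
    start = floor(config$chrom_length * (0.5 - half)),
    end = floor(config$chrom_length * (0.5 + half)),
    stringsAsFactors = FALSE)
  if (config$pericentromere_fraction == 0) peri <- peri[0, , drop = FALSE]
  genome_layout(sizes, peri)
}

## Rejection-sample non-overlapping cluster positions, respecting each
## class's arm/pericentromere bias. Clusters are kept >= 2 * pad-width
## (250 bp) apart so calling never merges neighbours.
#' @noRd
place_clusters <- function(config, layout, min_separation = 250) {
  n_total <- sum(config$n_clusters)
  widths <- round(stats::runif(n_total, config$cluster_width_range[1],
                               config$cluster_width_range[2]))
  classes <- rep(rownames(config$class_profiles), config$n_clusters)
  bias <- rep(config$arm_bias, config$n_clusters)
  compartments <- ifelse(stats::runif(n_total) < bias,
                         "arm", "pericentromere")
  pools <- list(arm = layout$arms, pericentromere = layout$pericentromere)
  occupied <- data.frame(chrom = character(), start = numeric(),
                         end = numeric(), stringsAsFactors = FALSE)
  rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    pool <- pools[[compartments[i]]]
    if (nrow(pool) == 0)
      stop("no ", compartments[i], " space configured for cluster placement")
    placed <- FALSE
    for (try in 1:200) {
      seg <- pool[sample.int(nrow(pool), 1,
                             prob = pool$end - pool$start), , drop = FALSE]
      if (seg$end - seg$start < widths[i]) next
      s <- floor(stats::runif(1, seg$start, seg$end - widths[i]))
      cand <- data.frame(chrom = seg$chrom,
                         start = max(0, s - min_separation),
                         end = s + widths[i] + min_separation,
                         stringsAsFactors = FALSE)
      if (!any(overlaps_any(cand, occupied))) {
        rows[[i]] <- data.frame(chrom = seg$chrom, start = s,
                                end = s + widths[i],
                                stringsAsFactors = FALSE)
        occupied <- rbind(occupied, rows[[i]])
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place ", n_total, " non-overlapping clusters; ",
           "reduce n_clusters or widths, or enlarge the genome")
  }
  clusters <- do.call(rbind, rows)
  clusters$id <- sprintf("cl%04d", seq_len(n_total))
  clusters$class <- classes
  clusters$compartment <- compartments
  rownames(clusters) <- NULL
  clusters
}

#' @noRd
place_cytosines <- function(config, layout, clusters) {
  out <- lapply(names(layout$chrom_sizes), function(chr) {
    len <- layout$chrom_sizes[[chr]]
    per_ctx <- lapply(names(config$context_density), function(ctx) {
      n <- stats::rpois(1, config$context_density[[ctx]] * len)
      pos <- sort(sample.int(len, min(n, len)))
      data.frame(chrom = chr, pos = pos,
                 strand = sample(c("+", "-"), length(pos), replace = TRUE),
                 context = ctx, stringsAsFactors = FALSE)
    })
    do.call(rbind, per_ctx)
  })
  cyt <- do.call(rbind, out)
  cyt <- cyt[order(cyt$chrom, cyt$pos, method = "radix"), , drop = FALSE]
  rownames(cyt) <- NULL
  ## map each cytosine to its containing cluster (positions are 1-based)
  cyt$cluster <- NA_integer_
  for (chr in unique(cyt$chrom)) {
    ci <- which(cyt$chrom == chr)
    ki <- which(clusters$chrom == chr)
    if (!length(ki)) next
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(cyt$pos[ci], cyt$pos[ci]),
      IRanges::IRanges(clusters$start[ki] + 1L, clusters$end[ki]))
    cyt$cluster[ci[S4Vectors::queryHits(hits)]] <-
      ki[S4Vectors::subjectHits(hits)]
  }
  cyt
}

#' Expected per-cluster 24nt read counts for one sample
#'
#' Converts the landscape's expected fpkm into expected 24nt read counts at
#' a given library size, applying the genotype's class effects. Counts are
#' allocated so a wild-type library places `in_cluster_fraction` of its
#' reads in clusters.
#'
#' @param landscape a [simulate_landscape()] result.
#' @param tissue,genotype sample condition.
#' @param library_size total mapped reads of all size classes.
#' @return Named numeric vector of expected 24nt counts per cluster.
#' @export
expected_cluster_counts <- function(landscape, tissue, genotype,
                                    library_size = NULL) {
  cfg <- landscape$config
  if (is.null(library_size)) library_size <- cfg$library_size
  if (!tissue %in% cfg$tissues) stop("unknown tissue: ", tissue)
  if (!genotype %in% names(cfg$genotype_effects))
    stop("unknown genotype: ", genotype)
  fpkm <- landscape$expected_fpkm[, tissue]
  w_kb <- (landscape$clusters$end - landscape$clusters$start) / 1000
  weight <- fpkm * w_kb
  weight <- weight / sum(weight)
  eff <- genotype_effect_vector(cfg, genotype)[landscape$clusters$class]
  stats::setNames(weight * cfg$in_cluster_fraction * library_size * eff,
                  landscape$clusters$id)
}

#' Per-class abundance multipliers for a genotype
#'
#' Expands a config's `genotype_effects` entry into a full named vector
#' over all classes, with 1 for unaffected classes and the configured
#' multiplier (0 for complete ablation) otherwise.
#'
#' @param cfg a [sim_config()].
#' @param genotype genotype name present in `cfg$genotype_effects`.
#' @return Named numeric vector over the class labels.
#' @export
genotype_effect_vector <- function(cfg, genotype) {
  eff <- stats::setNames(rep(1, nrow(cfg$class_profiles)),
                         rownames(cfg$class_profiles))
  ge <- cfg$genotype_effects[[genotype]]
  if (length(ge)) eff[names(ge)] <- ge
  eff
}

#' Simulate one small-RNA library
#'
#' Draws per-cluster 24nt (and minor 21-23nt) read counts from a negative
#' binomial around the landscape's expected abundance times the genotype
#' effect, places reads uniformly inside their cluster, and scatters
#' background reads of mixed sizes across the genome. Deterministic given
#' the landscape and seed.
#'
#' @param landscape a [simulate_landscape()] result.
#' @param tissue,genotype sample condition (must exist in the landscape).
#' @param library_size total mapped reads of all size classes; defaults to
#'   the config value.
#' @param seed integer seed for this sample; defaults to a substream of the
#'   config seed keyed by tissue/genotype.
#' @return A list with `reads` (data frame: chrom, start, end, length;
#'   0-based half-open) and `total_mapped_reads`.
#' @export
simulate_sirna_sample <- function(landscape, tissue, genotype,
                                  library_size = NULL, seed = NULL) {
  cfg <- landscape$config
  if (is.null(library_size)) library_size <- cfg$library_size
  if (is.null(seed))
    seed <- substream_seed(cfg$seed,
                           paste(tissue, genotype, "sirna", sep = "/"))
  mu <- expected_cluster_counts(landscape, tissue, genotype, library_size)
  with_seed(seed, {
    counts <- stats::rnbinom(length(mu), mu = mu,
                             size = 1 / cfg$nb_dispersion)
    cl <- landscape$clusters
    idx <- rep(seq_len(nrow(cl)), counts)
    lens_in <- as.integer(sample(names(cfg$cluster_length_probs),
                                 length(idx), replace = TRUE,
                                 prob = cfg$cluster_length_probs))
    span <- pmax(cl$end[idx] - cl$start[idx] - lens_in, 0)
    starts_in <- cl$start[idx] + floor(stats::runif(length(idx)) * (span + 1))
    genome_kb <- sum(landscape$layout$chrom_sizes) / 1000
    n_bg <- stats::rpois(1, cfg$background_rate * genome_kb)
    chroms <- names(landscape$layout$chrom_sizes)
    bg_chrom <- sample(chroms, n_bg, replace = TRUE,
                       prob = landscape$layout$chrom_sizes)
    lens_bg <- as.integer(sample(names(cfg$background_length_probs),
                                 n_bg, replace = TRUE,
                                 prob = cfg$background_length_probs))
    bg_start <- floor(stats::runif(n_bg) *
                        (landscape$layout$chrom_sizes[bg_chrom] - lens_bg))
    reads <- data.frame(
      chrom = c(cl$chrom[idx], bg_chrom),
      start = c(starts_in, bg_start),
      length = c(lens_in, lens_bg),
      stringsAsFactors = FALSE)
    reads$end <- reads$start + reads$length
    reads <- reads[, c("chrom", "start", "end", "length")]
    reads <- sort_intervals(reads)
    ## total mapped reads of all size classes: the emitted dicer-sized
    ## placements plus the library's non-cluster remainder (metadata only)
    list(reads = reads,
         total_mapped_reads = round((1 - cfg$in_cluster_fraction) *
                                      library_size) + nrow(reads),
         tissue = tissue, genotype = genotype, seed = seed)
  })
}

#' Simulate one per-cytosine methylome
#'
#' Coverage is Poisson around `mean_coverage`; methylated counts are
#' binomial at the context baseline, elevated to the RdDM-coupled CHH level
#' inside clusters that are active (expected fpkm at or above
#' `active_fpkm`) in the sample's tissue and not ablated by its genotype.
#' Ablated clusters revert to baseline CHH. Cytosine positions are fixed by
#' the landscape, so methylomes from different samples are comparable
#' site-by-site.
#'
#' @param landscape a [simulate_landscape()] result.
#' @param tissue,genotype sample condition.
#' @param mean_coverage mean coverage; defaults to the config value.
#' @param seed integer seed; defaults to a substream keyed by
#'   tissue/genotype. Pass distinct seeds for replicate libraries.
#' @return Data frame of cytosine records: chrom, pos (1-based), strand,
#'   context, mc_count, coverage.
#' @export
simulate_methylome <- function(landscape, tissue, genotype,
                               mean_coverage = NULL, seed = NULL) {
  cfg <- landscape$config
  if (is.null(mean_coverage)) mean_coverage <- cfg$mean_coverage
  if (mean_coverage <= 0) stop("mean_coverage must be > 0")
  if (!tissue %in% cfg$tissues) stop("unknown tissue: ", tissue)
  if (!genotype %in% names(cfg$genotype_effects))
    stop("unknown genotype: ", genotype)
  if (is.null(seed))
    seed <- substream_seed(cfg$seed,
                           paste(tissue, genotype, "methylome", sep = "/"))
  cyt <- landscape$cytosines
  p <- cfg$baseline_methylation[cyt$context]
  eff <- genotype_effect_vector(cfg, genotype)
  active_cl <- which(landscape$expected_fpkm[, tissue] >= cfg$active_fpkm &
                       eff[landscape$clusters$class] > 0)
  hot <- cyt$context == "CHH" & !is.na(cyt$cluster) &
    cyt$cluster %in% active_cl
  p[hot] <- cfg$rddm_chh
  with_seed(seed, {
    coverage <- stats::rpois(nrow(cyt), mean_coverage)
    mc <- stats::rbinom(nrow(cyt), coverage, p)
    data.frame(chrom = cyt$chrom, pos = cyt$pos, strand = cyt$strand,
               context = cyt$context, mc_count = mc, coverage = coverage,
               stringsAsFactors = FALSE)
  })
}

#' Bins carrying planted RdDM-coupled CHH methylation
#'
#' Returns the 100-bp grid bins fully contained in clusters that are
#' active in the given tissue in wild type but ablated in the given
#' genotype — the regions a hypo-CHH DMR caller comparing mutant against
#' wild type should recover. Bins only partially overlapping a cluster
#' carry mixed (baseline + elevated) signal by construction and are not
#' part of the planted truth.
#'
#' @param landscape a [simulate_landscape()] result.
#' @param tissue tissue of comparison.
#' @param genotype mutant genotype.
#' @param bin_size bin width (bp).
#' @return Interval data frame of planted hypo-CHH bins.
#' @export
planted_hypo_chh_bins <- function(landscape, tissue, genotype,
                                  bin_size = 100) {
  cfg <- landscape$config
  eff <- genotype_effect_vector(cfg, genotype)
  lost <- landscape$clusters[
    landscape$expected_fpkm[, tissue] >= cfg$active_fpkm &
      eff[landscape$clusters$class] == 0, , drop = FALSE]
  bins <- make_bins(landscape$layout, bin_size)
  hit <- intersect_any(bins, lost)
  ## keep bins whose whole span lies inside one planted cluster
  contained <- logical(nrow(hit))
  for (chr in unique(hit$chrom)) {
    hi <- which(hit$chrom == chr)
    ki <- which(lost$chrom == chr)
    if (!length(ki)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(hit$start[hi] + 1L, hit$end[hi]),
      IRanges::IRanges(lost$start[ki] + 1L, lost$end[ki]),
      type = "within")
    contained[hi[unique(S4Vectors::queryHits(ov))]] <- TRUE
  }
  hit[contained, , drop = FALSE]
}

#' Write simulated data in standard formats
#'
#' `write_sirna_bed()` writes read placements as BED6 (name = running read
#' index, score = read length). `write_cgmap()` writes a CGmap-style TSV
#' (chrom, 1-based position, strand, context, methylated count, coverage;
#' no header) readable by [read_cgmap()]. `write_truth_ledger()` serialises
#' the planted truth (clusters, classes, expected fpkm, siren set) as JSON.
#'
#' @param sample result of [simulate_sirna_sample()].
#' @param meth result of [simulate_methylome()].
#' @param landscape a [simulate_landscape()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sirna_bed <- function(sample, path) {
  r <- sample$reads
  r$id <- sprintf("r%d", seq_len(nrow(r)))
  r$score <- r$length
  write_bed(r[, c("chrom", "start", "end", "id", "score")], path)
}

#' @rdname write_sirna_bed
#' @export
write_cgmap <- function(meth, path) {
  utils::write.table(meth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_sirna_bed
#' @export
write_truth_ledger <- function(landscape, path) {
  truth <- list(
    clusters = cbind(landscape$clusters,
                     as.data.frame(landscape$expected_fpkm)),
    siren_ids = landscape$siren_ids,
    siren_tissue = landscape$config$siren_tissue,
    siren_fraction = landscape$config$siren_fraction,
    chrom_sizes = as.list(landscape$layout$chrom_sizes),
    pericentromere = landscape$layout$pericentromere,
    seed = landscape$config$seed)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sirna_bed
#' @param samples data frame describing samples (one row per sample).
#' @export
write_manifest <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
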