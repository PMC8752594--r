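make_cm <- function(counts, total_mapped = NULL, widths = NULL) {
  if (is.null(total_mapped))
    total_mapped <- stats::setNames(rep(1e6, ncol(counts)),
                                    colnames(counts))
  if (is.null(widths))
    widths <- stats::setNames(rep(1000, nrow(counts)), rownames(counts))
  structure(list(counts = counts, total_mapped_reads = total_mapped,
                 widths = widths),
            class = "count_matrix")
}

test_that("count_24nt counts only 24nt reads with >=1 bp overlap", {
  clusters <- genomic_intervals(c("chr1", "chr1"), c(0, 2000),
                                c(1000, 3000), id = c("a", "b"))
  r24 <- data.frame(chrom = "chr1", start = rep(100, 10),
                    end = rep(124, 10), length = 24)
  r23 <- data.frame(chrom = "chr1", start = rep(2100, 7),
                    end = rep(2123, 7), length = 23)
  cm <- count_24nt(clusters, list(s1 = rbind(r24, r23)),
                   c(s1 = 1e6))
  expect_equal(unname(cm$counts[, "s1"]), c(10L, 0L))
  expect_equal(unname(fpkm_24nt(cm)[, "s1"]), c(10, 0))  # 10 / (1kb x 1M)

  empty <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), length = numeric())
  expect_equal(sum(count_24nt(clusters, list(s = empty),
                              c(s = 1))$counts), 0)

  overlapping <- genomic_intervals(c("chr1", "chr1"), c(0, 500),
                                   c(1000, 1500))
  expect_error(count_24nt(overlapping, list(s1 = r24), c(s1 = 1)),
               "non-overlapping")
})

test_that("count_24nt matches brute-force overlap counting", {
  set.seed(500)
  clusters <- merge_intervals(random_intervals(40), 0)
  clusters$id <- sprintf("c%02d", seq_len(nrow(clusters)))
  n <- 1500
  start <- sample.int(5000, n, replace = TRUE) - 1
  len <- sample(21:24, n, replace = TRUE)
  reads <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                      start = start, end = start + len, length = len)
  cm <- count_24nt(clusters, list(s = reads), c(s = 1e6))
  oracle <- bin_count_oracle(reads[reads$length == 24, ], clusters)
  expect_equal(unname(cm$counts[, "s"]), oracle)
})

test_that("wild-type size factors are median-of-ratios among WT columns", {
  set.seed(501)
  counts <- matrix(rnbinom(50 * 3, mu = 100, size = 5), 50, 3,
                   dimnames = list(sprintf("c%02d", 1:50),
                                   c("wt1", "wt2", "wt3")))
  cm <- make_cm(counts)
  sf <- wt_anchored_size_factors(cm, c("wt1", "wt2", "wt3"))
  # direct-formula oracle
  loggeo <- rowMeans(log(counts))
  ok <- is.finite(loggeo)
  oracle <- apply(counts, 2, function(col)
    exp(median((log(col) - loggeo)[ok])))
  expect_equal(sf, oracle)

  # identical WT columns give factors of 1
  same <- make_cm(matrix(rep(counts[, 1], 3), ncol = 3,
                         dimnames = dimnames(counts)))
  expect_equal(unname(wt_anchored_size_factors(same, colnames(counts))),
               rep(1, 3))
})

test_that("size factors agree with DESeq2's median-of-ratios on WT columns", {
  skip_if_not_installed("DESeq2")
  set.seed(502)
  counts <- matrix(rnbinom(80 * 3, mu = 200, size = 10), 80, 3,
                   dimnames = list(NULL, c("wt1", "wt2", "wt3")))
  cm <- make_cm(counts)
  rownames(cm$counts) <- sprintf("c%02d", 1:80)
  names(cm$widths) <- rownames(cm$counts)
  got <- wt_anchored_size_factors(cm, colnames(counts))
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(got), unname(ref), tolerance = 1e-8)
})

test_that("non-WT samples are anchored to sequencing depth", {
  counts <- matrix(c(10, 10, 10, 0), 1, 4,
                   dimnames = list("c1", c("wt1", "wt2", "wt3", "mut")))
  counts <- rbind(counts, matrix(20, 3, 4,
                                 dimnames = list(c("c2", "c3", "c4"), NULL)))
  tm <- c(wt1 = 1e6, wt2 = 1e6, wt3 = 1e6, mut = 2e6)
  cm <- make_cm(counts, tm)
  sf <- wt_anchored_size_factors(cm, c("wt1", "wt2", "wt3"))
  expect_equal(unname(sf[c("wt1", "wt2", "wt3")]), rep(1, 3))
  # mutant at twice the mean WT depth with WT factors 1 gets factor 2
  expect_equal(unname(sf["mut"]), 2)
})

test_that("differential_clusters flags all-zero clusters untestable and respects thresholds", {
  set.seed(503)
  n <- 300
  counts <- cbind(matrix(rnbinom(n * 3, mu = 200, size = 20), n, 3),
                  matrix(rnbinom(n * 3, mu = 25, size = 20), n, 3))
  counts[1, ] <- 0
  dimnames(counts) <- list(sprintf("c%03d", 1:n),
                           c(paste0("wt", 1:3), paste0("m", 1:3)))
  cm <- make_cm(counts)
  sf <- stats::setNames(rep(1, 6), colnames(counts))
  groups <- stats::setNames(c(rep("WT", 3), rep("mut", 3)),
                            colnames(counts))
  d <- differential_clusters(cm, sf, groups)
  expect_equal(d$status[1], "untestable")
  expect_true(is.na(d$padj[1]))
  expect_gt(mean(d$status[-1] == "reduced_DE"), 0.95)

  # column order invariance
  perm <- sample(colnames(counts))
  cm2 <- make_cm(counts[, perm])
  d2 <- differential_clusters(cm2, sf[perm], groups[perm])
  expect_equal(d$log2fc, d2$log2fc)
  expect_equal(d$padj, d2$padj)

  # monotonicity: stricter FDR never adds reduced calls
  d_strict <- differential_clusters(cm, sf, groups, fdr_threshold = 1e-4)
  expect_true(all(d_strict$status != "reduced_DE" |
                    d$status == "reduced_DE"))
})

test_that("rescue promotes sub-threshold reductions overlapping free hypo DMRs", {
  clusters <- genomic_intervals(c("chr1", "chr1", "chr1"),
                                c(0, 2000, 4000), c(1000, 3000, 5000),
                                id = c("a", "b", "c"))
  diff <- data.frame(
    id = c("a", "b", "c"),
    log2fc = c(-0.50, -0.30, -2.0),
    padj = c(0.2, 0.2, 0.001),
    status = c("unchanged", "unchanged", "reduced_DE"),
    stringsAsFactors = FALSE)
  dmrs <- genomic_intervals(rep("chr1", 3), c(100, 2100, 4100),
                            c(200, 2200, 4200))
  out <- rescue_reduced_clusters(diff, dmrs, clusters)
  # -0.50 with a DMR: rescued; -0.30: below the ~25% cutoff, unchanged;
  # DMR inside the reduced_DE cluster is consumed without side effects
  expect_equal(out$status, c("reduced_rescued", "unchanged", "reduced_DE"))

  # a DMR overlapping only the DE cluster never promotes anything
  only_de <- rescue_reduced_clusters(
    transform(diff, status = c("unchanged", "unchanged", "reduced_DE")),
    genomic_intervals("chr1", 4100, 4200), clusters)
  expect_equal(sum(only_de$status == "reduced_rescued"), 0)

  # rescue never removes a DE call; the two reduced sets stay disjoint
  expect_true(all(out$status[diff$status == "reduced_DE"] == "reduced_DE"))
})

test_that("dependency categories partition the pol-iv universe with conserved abundance", {
  reduced <- list(clsy1 = c("a", "b"), clsy2 = c("b"),
                  clsy3 = c("d"), clsy4 = character())
  quad <- c("a", "b", "d", "e")
  poliv <- c("a", "b", "c", "d", "e", "f")
  wt <- c(a = 100, b = 50, c = 25, d = 200, e = 10, f = 15)
  res <- dependency_categories(reduced, quad, poliv, wt)
  cats <- stats::setNames(res$clusters$category, res$clusters$id)
  expect_equal(unname(cats["a"]), "clsy1-sp")
  expect_equal(unname(cats["b"]), "clsy1∩clsy2")
  expect_equal(unname(cats["d"]), "clsy3-sp")
  expect_equal(unname(cats["e"]), "quad-residual")
  expect_equal(unname(cats["c"]), "poliv-specific")
  expect_equal(sum(res$fractions), 1, tolerance = 1e-9)
  expect_equal(unname(res$fractions["clsy3-sp"]), 200 / 400)
  expect_false(any(res$clusters$not_in_quad[res$clusters$id %in% quad]))

  # cluster reduced in a single but absent from the quad set is flagged
  res2 <- dependency_categories(list(clsy1 = c("a")), quad = c("b"),
                                poliv = c("a", "b"), wt)
  expect_true(res2$clusters$not_in_quad[res2$clusters$id == "a"])
})

test_that("abundance fractions sum to one over random assignments", {
  set.seed(504)
  for (rep in 1:5) {
    ids <- sprintf("c%03d", 1:100)
    poliv <- sample(ids, 80)
    reduced <- list(g1 = sample(poliv, 30), g2 = sample(poliv, 25))
    quad <- unique(c(sample(poliv, 50), unlist(reduced)))
    wt <- stats::setNames(runif(100, 1, 1000), ids)
    res <- dependency_categories(reduced, quad, poliv, wt)
    expect_equal(sum(res$fractions), 1, tolerance = 1e-9)
    expect_equal(nrow(res$clusters), length(unique(poliv)))
  }
})
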