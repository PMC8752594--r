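tiny_layout <- function(len = 1000) genome_layout(
  c(chr1 = len), genomic_intervals(character(), numeric(), numeric()))

cyt <- function(pos, mc, cov, context = "CHH", chrom = "chr1",
                strand = "+") {
  data.frame(chrom = chrom, pos = pos, strand = strand, context = context,
             mc_count = mc, coverage = cov, stringsAsFactors = FALSE)
}

test_that("bin_methylome pools strands on a fixed 0-anchored grid", {
  recs <- rbind(cyt(c(5, 50, 99), c(1, 2, 3), c(10, 10, 10)),
                cyt(150, 10, 10, strand = "-"))
  b <- bin_methylome(recs, tiny_layout(), bin_size = 100)
  expect_equal(nrow(b), 2)
  expect_equal(b$start, c(0, 100))
  expect_equal(b$n_cytosines, c(3L, 1L))
  expect_equal(b$mc, c(6, 10))
  expect_equal(b$level, c(6 / 30, 1.0))

  # a position on the bin edge: 1-based pos 101 belongs to bin [100, 200)
  edge <- bin_methylome(cyt(101, 0, 5), tiny_layout())
  expect_equal(edge$start, 100)

  expect_error(bin_methylome(cyt(2000, 0, 5), tiny_layout()), "bounds")

  # brute-force aggregation oracle on random records
  set.seed(600)
  n <- 400
  recs <- cyt(sample.int(1000, n, replace = TRUE),
              mc = 0, cov = sample.int(30, n, replace = TRUE))
  recs$mc_count <- rbinom(n, recs$coverage, 0.3)
  b <- bin_methylome(recs, tiny_layout(), 100)
  for (i in sample.int(nrow(b), 5)) {
    sel <- recs$pos - 1 >= b$start[i] & recs$pos - 1 < b$end[i]
    expect_equal(b$mc[i], sum(recs$mc_count[sel]))
    expect_equal(b$coverage[i], sum(recs$coverage[sel]))
    expect_equal(b$n_cytosines[i], sum(sel))
  }
})

test_that("the vectorised Fisher test matches stats::fisher.test", {
  set.seed(601)
  cov_a <- sample(4:200, 50, replace = TRUE)
  cov_b <- sample(4:200, 50, replace = TRUE)
  mc_a <- rbinom(50, cov_a, runif(50))
  mc_b <- rbinom(50, cov_b, runif(50))
  got <- sirenscape:::fisher_2x2_p(mc_a, cov_a, mc_b, cov_b)
  ref <- vapply(1:50, function(i)
    stats::fisher.test(matrix(c(mc_a[i], cov_a[i] - mc_a[i],
                                mc_b[i], cov_b[i] - mc_b[i]), 2))$p.value,
    numeric(1))
  expect_equal(got, ref, tolerance = 1e-10)
})

test_that("pairwise_dmrs applies the context filters the caller requires", {
  # identical methylomes: no DMRs
  set.seed(602)
  m <- cyt(seq(10, 990, by = 10), mc = 5, cov = 10)
  expect_equal(nrow(pairwise_dmrs(m, m, "CHH", tiny_layout())), 0)

  # an extreme CG bin: 40/40 vs 0/40 pooled; Fisher p equals the
  # hypergeometric point mass and the bin is called with delta 1
  a <- cyt(c(10, 20, 30, 40), mc = 10, cov = 10, context = "CG")
  b <- cyt(c(10, 20, 30, 40), mc = 0, cov = 10, context = "CG")
  d <- pairwise_dmrs(a, b, "CG", tiny_layout())
  expect_equal(nrow(d), 1)
  expect_equal(d$delta, 1)
  expect_equal(d$direction, "hyper")
  expect_equal(d$pvalue, stats::dhyper(40, 40, 40, 40) * 2 -
                 stats::dhyper(40, 40, 40, 40), tolerance = 1e-12)
  expect_equal(d$pvalue, 1 / choose(80, 40), tolerance = 1e-12)

  # three cytosines only: below the >=4 filter, never a candidate
  a3 <- a[1:3, ]; b3 <- b[1:3, ]
  expect_equal(nrow(pairwise_dmrs(a3, b3, "CG", tiny_layout())), 0)

  # low per-cytosine coverage in one sample drops the site pair
  b_low <- b; b_low$coverage <- 3; b_low$mc_count <- 0
  expect_equal(nrow(pairwise_dmrs(a, b_low, "CG", tiny_layout())), 0)

  # CHH delta below 10% is rejected no matter how small the p-value
  n <- 40
  a_sub <- cyt(seq(2, 80, by = 2), mc = round(0.09 * 200), cov = 200)
  b_sub <- cyt(seq(2, 80, by = 2), mc = 0, cov = 200)
  d_sub <- pairwise_dmrs(a_sub, b_sub, "CHH", tiny_layout())
  expect_equal(nrow(d_sub), 0)
  cand <- attr(d_sub, "candidates")
  expect_true(any(cand$padj <= 0.01))  # significant, but under-threshold
})

test_that("DMR calling is symmetric up to direction", {
  set.seed(603)
  pos <- seq(5, 995, by = 5)
  a <- cyt(pos, rbinom(length(pos), 20, 0.3), 20)
  b <- cyt(pos, rbinom(length(pos), 20, 0.05), 20)
  ab <- pairwise_dmrs(a, b, "CHH", tiny_layout())
  ba <- pairwise_dmrs(b, a, "CHH", tiny_layout())
  expect_equal(nrow(ab), nrow(ba))
  expect_equal(ab$start, ba$start)
  expect_equal(ab$delta, -ba$delta)
  expect_equal(ab$pvalue, ba$pvalue)
  expect_true(all(ab$direction == "hyper") && all(ba$direction == "hypo"))
})

test_that("raising thresholds or lowering alpha never adds DMRs", {
  set.seed(604)
  pos <- seq(5, 995, by = 5)
  a <- cyt(pos, rbinom(length(pos), 20, 0.25), 20)
  b <- cyt(pos, rbinom(length(pos), 20, 0.08), 20)
  base <- pairwise_dmrs(a, b, "CHH", tiny_layout())
  stricter_delta <- pairwise_dmrs(a, b, "CHH", tiny_layout(),
                                  delta_threshold = c(CHH = 0.2))
  stricter_alpha <- pairwise_dmrs(a, b, "CHH", tiny_layout(),
                                  alpha = 0.001)
  expect_true(all(bin_key(stricter_delta) %in% bin_key(base)))
  expect_true(all(bin_key(stricter_alpha) %in% bin_key(base)))
})

test_that("consensus keeps bins present in every comparison with matching direction", {
  d1 <- data.frame(chrom = "chr1", start = c(0, 100, 200),
                   end = c(100, 200, 300), context = "CHH",
                   n_cytosines = 5L, level_a = 0.01, level_b = 0.3,
                   delta = -0.29, pvalue = 1e-8, padj = 1e-6,
                   direction = "hypo", stringsAsFactors = FALSE)
  d2 <- d1[c(1, 2), ]
  d3 <- d1[c(2, 3), ]
  cons <- consensus_dmrs(list(d1, d2, d3))
  expect_equal(cons$start, 100)

  expect_equal(consensus_dmrs(list(d1, d1, d1))$start, d1$start)
  expect_error(consensus_dmrs(list()), "at least one")

  # direction must match, not just the bin
  flip <- d1
  flip$direction <- c("hyper", "hypo", "hypo")
  cons2 <- consensus_dmrs(list(d1, flip))
  expect_equal(cons2$start, c(100, 200))

  # an 8-of-9 bin is excluded under the all-9 tissue rule
  nine <- c(rep(list(d1), 8), list(d1[c(1, 3), ]))
  expect_false(100 %in% consensus_dmrs(nine)$start)
})

test_that("combine_tissue_dmrs unions bins and records supports", {
  d1 <- data.frame(chrom = "chr1", start = 0, end = 100, context = "CHH",
                   n_cytosines = 5L, level_a = 0.01, level_b = 0.3,
                   delta = -0.29, pvalue = 1e-8, padj = 1e-6,
                   direction = "hypo", all_deltas = "-0.29",
                   stringsAsFactors = FALSE)
  d2 <- transform(d1, start = 100, end = 200)
  shared <- transform(d1, start = 300, end = 400)
  u <- combine_tissue_dmrs(list(`ovule-flower` = rbind(d1, shared),
                                `ovule-rosette` = rbind(d2, shared)))
  expect_equal(nrow(u), 3)
  expect_equal(u$supports[u$start == 300], "ovule-flower,ovule-rosette")

  # union size equals brute-force de-duplication
  expect_equal(nrow(u), length(unique(c(bin_key(rbind(d1, shared)),
                                        bin_key(rbind(d2, shared))))))
})

test_that("cgmap records survive a write/read round trip", {
  set.seed(605)
  m <- cyt(sample.int(1000, 50), 2, 10,
           context = sample(c("CG", "CHG", "CHH"), 50, replace = TRUE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cgmap(m, path)
  expect_equal(read_cgmap(path), m)
  expect_error(read_cgmap({
    bad <- withr::local_tempfile(fileext = ".tsv")
    write.table(transform(m, mc_count = coverage + 1), bad, sep = "\t",
                row.names = FALSE, col.names = FALSE, quote = FALSE)
    bad
  }), "mc_count")
})
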