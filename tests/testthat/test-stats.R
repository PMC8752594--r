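test_that("siren_loci returns the minimal prefix reaching the target share", {
  # one dominant cluster carrying 85% of output is the whole siren set
  f <- c(a = 85, b = 5, c = 5, d = 5)
  s <- siren_loci(f)
  expect_equal(s$siren_ids, "a")
  expect_equal(s$table$cumulative_fraction[1], 0.85)

  # 100 equal clusters: exactly 80 needed for the 80% target
  eq <- stats::setNames(rep(1, 100), sprintf("c%03d", 1:100))
  expect_equal(length(siren_loci(eq)$siren_ids), 80)

  # input-order invariance and scale invariance
  set.seed(700)
  f2 <- stats::setNames(rexp(50), sprintf("c%02d", 1:50))
  s1 <- siren_loci(f2)
  s2 <- siren_loci(f2[sample.int(50)])
  s3 <- siren_loci(f2 * 1000)
  expect_equal(sort(s1$siren_ids), sort(s2$siren_ids))
  expect_equal(s1$siren_ids, s3$siren_ids)

  # the prefix is minimal: dropping its last member falls below target
  tab <- s1$table
  n <- sum(tab$is_siren)
  expect_gte(tab$cumulative_fraction[n], 0.80)
  if (n > 1) expect_lt(tab$cumulative_fraction[n - 1], 0.80)
  # and the set is a rank prefix
  expect_equal(s1$siren_ids, tab$id[seq_len(n)])

  expect_error(siren_loci(c(a = -1, b = 2)), ">= 0")
  expect_error(siren_loci(c(a = 0, b = 0)), "all-zero")
})

test_that("classify_clusters recovers structure under 1-minus-Pearson", {
  # k = 1 labels every non-degenerate row identically
  set.seed(701)
  expr <- matrix(runif(40), 10, 4,
                 dimnames = list(sprintf("r%02d", 1:10), NULL))
  expect_equal(unname(unique(classify_clusters(expr, k = 1))), 1L)

  # two anti-correlated shape groups are separated perfectly
  up <- c(1, 2, 3, 4); down <- c(4, 3, 2, 1)
  x <- rbind(t(replicate(15, up * runif(1, 1, 5))),
             t(replicate(15, down * runif(1, 1, 5))))
  rownames(x) <- sprintf("r%02d", 1:30)
  lab <- classify_clusters(x, k = 2, seed = 42)
  expect_equal(length(unique(lab[1:15])), 1)
  expect_equal(length(unique(lab[16:30])), 1)
  expect_false(lab[1] == lab[16])

  # same seed, same labels; flat rows get the degenerate class 0
  expect_identical(classify_clusters(x, k = 2, seed = 42), lab)
  x0 <- rbind(x, flat = rep(3, 4))
  lab0 <- classify_clusters(x0, k = 2, seed = 42)
  expect_equal(unname(lab0["flat"]), 0L)

  # fitted labelling has dispersion no worse than random labellings
  set.seed(702)
  expr2 <- matrix(rnorm(200), 50, 4,
                  dimnames = list(sprintf("r%02d", 1:50), NULL))
  lab2 <- classify_clusters(expr2, k = 5, seed = 7)
  d_fit <- pearson_dispersion(expr2, lab2)
  d_rand <- replicate(100, pearson_dispersion(
    expr2, sample(lab2)))
  expect_true(all(d_fit <= d_rand))

  # row-order invariance of the partition
  perm <- sample.int(30)
  lab_p <- classify_clusters(x[perm, ], k = 2, seed = 42)
  expect_equal(unname(lab_p[rownames(x)]), unname(lab))

  expect_error(classify_clusters(x, k = 40), "nonzero variance")
})

test_that("cv_comparison computes sample CVs and a Welch test", {
  v <- rbind(a = c(1, 2, 3, 4), b = c(10, 20, 30, 40),
             c = c(5, 5, 5, 5), d = c(0, 0, 0, 0), e = c(6, 6, 6, 7))
  expect_warning(res <- cv_comparison(v, c("a", "b", "d"), c("c", "e")),
                 "zero-mean")
  expect_equal(unname(res$cv_a["a"]), stats::sd(1:4) / 2.5)
  expect_equal(unname(res$cv_a["a"]), 0.5163978, tolerance = 1e-6)
  # CV is scale-invariant: row b equals row a
  expect_equal(unname(res$cv_a["b"]), unname(res$cv_a["a"]))
  expect_equal(unname(res$cv_b["c"]), 0)
  expect_false("d" %in% names(res$cv_a))

  # oracle: p matches a direct t.test on the same CVs
  set.seed(703)
  m <- matrix(rexp(200, 0.1) + 1, 50, 4,
              dimnames = list(sprintf("r%02d", 1:50), NULL))
  res2 <- cv_comparison(m, 1:25, 26:50)
  ref <- stats::t.test(res2$cv_a, res2$cv_b)
  expect_equal(res2$p_value, ref$p.value)

  expect_error(cv_comparison(v[, 1, drop = FALSE], "a", "b"), ">= 2")
})

test_that("arm enrichment permutation behaves at the extremes and is seeded", {
  gl <- genome_layout(c(chr1 = 10000),
                      genomic_intervals("chr1", 4000, 6000))
  n_arm <- 30; n_peri <- 30
  master <- genomic_intervals(
    rep("chr1", n_arm + n_peri),
    c(seq(0, by = 100, length.out = n_arm / 2),
      seq(7000, by = 100, length.out = n_arm / 2),
      seq(4000, by = 60, length.out = n_peri)),
    c(seq(0, by = 100, length.out = n_arm / 2) + 50,
      seq(7000, by = 100, length.out = n_arm / 2) + 50,
      seq(4000, by = 60, length.out = n_peri) + 50),
    id = sprintf("m%02d", seq_len(n_arm + n_peri)))
  arm_ids <- master$id[assign_compartment(master, gl) == "arm"]
  expect_equal(length(arm_ids), n_arm)

  # query = whole master set: null is constant, p must be 1
  full <- arm_enrichment_permutation(master$id, master, gl, n_perm = 200,
                                     seed = 10)
  expect_equal(full$observed_arm_fraction, 0.5)
  expect_equal(full$p_value, 1)

  # pure-arm query of size 20: observed 1.0 is never matched by chance
  # here, so the add-one estimator returns exactly 1/(n_perm + 1)
  ext <- arm_enrichment_permutation(arm_ids[1:20], master, gl,
                                    n_perm = 1000, seed = 11)
  expect_equal(ext$observed_arm_fraction, 1)
  expect_true(all(abs(ext$null_fractions - mean(ext$null_fractions)) <
                    abs(1 - mean(ext$null_fractions))))
  expect_equal(ext$p_value, 1 / 1001)

  # determinism and one-sided consistency
  again <- arm_enrichment_permutation(arm_ids[1:20], master, gl,
                                      n_perm = 1000, seed = 11)
  expect_identical(ext$null_fractions, again$null_fractions)
  expect_identical(ext$p_value, again$p_value)
  gr <- arm_enrichment_permutation(arm_ids[1:20], master, gl,
                                   n_perm = 1000, seed = 11,
                                   alternative = "greater")
  expect_equal(gr$p_value, 1 / 1001)

  expect_error(arm_enrichment_permutation(c("nope"), master, gl), "subset")
  expect_error(arm_enrichment_permutation(
    master$id, master[, c("chrom", "start", "end")], gl), "id")
})
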