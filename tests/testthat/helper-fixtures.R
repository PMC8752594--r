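# Shared simulation fixtures. The default landscape represents the study
# conditions; a reduced landscape keeps unit tests fast. Both are built
# once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, expr, envir = .fixture_env)
  get(name, envir = .fixture_env)
}

default_landscape <- function() {
  cached("default_landscape", simulate_landscape(sim_config(seed = 20260101)))
}

# One chromosome of 1 Mb (10^4 hundred-bp bins), fewer clusters: the scale
# used for DMR calibration and quick integration checks.
small_config <- function(seed = 7) {
  sim_config(n_chroms = 1, chrom_length = 1e6,
             n_clusters = c(rep(12L, 9), 8L),
             library_size = 2e5, seed = seed)
}

small_landscape <- function() {
  cached("small_landscape", simulate_landscape(small_config()))
}

# Fraction of set-a intervals having a reciprocal-overlap partner in set b.
reciprocal_recovery <- function(a, b, min_frac = 0.5) {
  hit <- vapply(seq_len(nrow(a)), function(i) {
    cand <- b[b$chrom == a$chrom[i] & b$start < a$end[i] &
                a$start[i] < b$end, , drop = FALSE]
    if (!nrow(cand)) return(FALSE)
    ov <- pmin(cand$end, a$end[i]) - pmax(cand$start, a$start[i])
    any(ov >= min_frac * (a$end[i] - a$start[i]) &
          ov >= min_frac * (cand$end - cand$start))
  }, logical(1))
  mean(hit)
}

bin_key <- function(d) paste(d$chrom, d$start)
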