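# Small fixtures built in code.

toy_variants <- function(m, chrom = "1", spacing = 10000L) {
  data.frame(id = sprintf("v%03d", seq_len(m)), chrom = chrom,
             pos = seq_len(m) * spacing, ref = "A", alt = "C",
             stringsAsFactors = FALSE)
}

toy_samples <- function(n, sites = 2) {
  data.frame(id = sprintf("s%03d", seq_len(n)),
             site_id = rep(sprintf("site_%02d", seq_len(sites)),
                           length.out = n),
             stringsAsFactors = FALSE)
}

toy_genotypes <- function(n = 12, m = 6, seed = 1, miss = 0) {
  set.seed(seed)
  d <- matrix(rbinom(n * m, 2, 0.4), n, m)
  if (miss > 0) d[sample(length(d), miss)] <- NA
  genotype_matrix(d, toy_variants(m), toy_samples(n))
}

small_config <- function(...) {
  args <- list(n_populations = 5, n_per_pop = 30, n_variants = 400,
               n_chromosomes = 4, n_causal = 40, n_traits = 2,
               selection_gradient = 0, mean_gap_bp = 4000, seed = 7)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

geno_from_counts <- function(n0, n1, n2, id = "v001") {
  g <- rep(0:2, times = c(n0, n1, n2))
  n <- length(g)
  genotype_matrix(matrix(as.integer(g), n, 1, dimnames = list(NULL, id)),
                  toy_variants(1), toy_samples(n))
}

# one shared small null study for tests that just need realistic objects
shared_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(small_config())
    cache
  }
})
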