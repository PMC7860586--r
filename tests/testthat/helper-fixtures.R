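# Shared fixture builders. Everything is generated in code; the desk-profile
# experiment and the within-line inbreeding simulation are computed once per
# test run and cached, because several acceptance properties are read off the
# same run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# evenly spaced loci on one or more chromosomes
toy_genome <- function(n_loci = 10, n_chr = 1, chr_length = 1, qtl = seq_len(n_loci * n_chr)) {
  pos <- lapply(seq_len(n_chr), function(c)
    seq(0, chr_length, length.out = n_loci + 2)[-c(1, n_loci + 2)])
  genome_map(rep(chr_length, n_chr), pos, qtl)
}

# Hardy-Weinberg population at given allele frequencies
toy_pop <- function(freq, n = 200, genome = toy_genome(length(freq)), line = "A") {
  init_founders(genome, ceiling(n / 2), floor(n / 2), freq = freq, line = line)
}

# random genotype-frequency table (not necessarily Hardy-Weinberg)
random_freqs <- function(m) {
  x <- matrix(runif(3 * m), m)
  x <- x / rowSums(x)
  structure(data.frame(locus = seq_len(m), P = x[, 1], H = x[, 2], Q = x[, 3],
                       p = x[, 1] + x[, 2] / 2),
            class = c("line_freqs", "data.frame"))
}

hwe_freqs <- function(p) {
  structure(data.frame(locus = seq_along(p), P = p^2, H = 2 * p * (1 - p),
                       Q = (1 - p)^2, p = p),
            class = c("line_freqs", "data.frame"))
}

# random small architecture with the requested components
random_arch <- function(m, dominance = TRUE, pairs = TRUE, config = "AA") {
  a <- rnorm(m)
  d <- if (dominance) rnorm(m, 0.2, 0.3) * abs(a) else numeric(m)
  pr <- if (pairs && m >= 2) {
    km <- t(combn(m, 2))
    km <- km[sample(nrow(km), min(nrow(km), 2 * m)), , drop = FALSE]
    data.frame(k = km[, 1], l = km[, 2],
               epsilon = rnorm(nrow(km), 0, 0.16), config = config,
               stringsAsFactors = FALSE)
  } else NULL
  trait_architecture(seq_len(m), a, d,
                     if (is.null(pr)) rpcsim:::empty_pairs() else pr,
                     scenario = "toy")
}

# The desk-profile experiment used by the acceptance properties. One
# 5-replicate run is shared: fraction and ordering statistics are read from
# all 5 replicates, point statistics tied to the 2-replicate desk design from
# its first two replicates (per-cell seeds make that slice identical to a
# 2-replicate run).
desk_results <- function() {
  cached("desk", {
    run_experiment(desk_profile(base_seed = 1, replicates = 5))
  })
}

desk_results_2rep <- function() subset(desk_results(), replicate <= 2)

# within-line pedigree simulation at full parent counts on a reduced genome
line_inbreeding <- function(n_rep = 3, n_gen = 20, seed = 1) {
  cached(paste0("inb", n_rep, "_", n_gen, "_", seed), {
    lapply(seq_len(n_rep), function(r) {
      set.seed(seed + r)
      genome <- sample_genome(1, 1, 200)
      genome$qtl <- 1:200
      pop0 <- run_history(genome, fast = TRUE, expand = c(1500, 1500))
      arch <- sample_architecture(genome$qtl, "D")
      Ve <- calibrate_ve(genotypic_value(qtl_geno(pop0, genome), arch), 0.3)
      sim <- simulate_line(pop0, genome, arch, n_gen, "positive", Ve,
                           n_sires = 50, n_dams = 300, line = "P")
      ped <- rbind(pop_pedigree(pop0), sim$pedigree)
      pedigree_inbreeding(ped)
    })
  })
}

# deterministic mean over the two cross directions of a divergent pair
divergent_means <- function(res) {
  res$pair <- with(res, ifelse(paste0(line1, line2) %in% c("P10N10", "N10P10"), "10",
                        ifelse(paste0(line1, line2) %in% c("P25N25", "N25P25"), "25",
                        ifelse(paste0(line1, line2) %in% c("P50N50", "N50P50"), "50", NA))))
  out <- aggregate(realized_rpc ~ scenario + pair, subset(res, !is.na(pair)), mean)
  out[order(out$scenario, as.integer(out$pair)), ]
}
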