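test_that("founders match the requested design and target frequencies", {
  set.seed(1)
  genome <- toy_genome(n_loci = 50, n_chr = 10)
  pop <- init_founders(genome, 100, 600)
  expect_equal(pop_size(pop), 700)
  expect_equal(dim(pop$hap1), c(500, 700))
  expect_equal(sum(pop$sex == 1L), 100)
  expect_equal(sum(pop$sex == 2L), 600)
  expect_true(all(pop$hap1 %in% 0:1))

  # law of large numbers over uniform target frequencies
  big <- toy_genome(n_loci = 5000, n_chr = 10)
  pop <- init_founders(big, 10, 50)
  pbar <- mean(rowMeans(pop$hap1) + rowMeans(pop$hap2)) / 2
  expect_equal(pbar, 0.5, tolerance = 0.01)

  # degenerate target frequencies give monomorphic loci
  gm <- toy_genome(2)
  pop <- init_founders(gm, 5, 5, freq = c(0, 1))
  expect_true(all(pop$hap1[1, ] == 0L) && all(pop$hap2[1, ] == 0L))
  expect_true(all(pop$hap1[2, ] == 1L) && all(pop$hap2[2, ] == 1L))

  expect_error(init_founders(gm, 0, 5), "positive")
})

test_that("gametes of a homozygous parent reproduce the parent haplotype", {
  set.seed(2)
  genome <- toy_genome(40)
  h <- matrix(rbinom(40, 1, 0.5), 40, 1)
  storage.mode(h) <- "integer"
  pop <- new_population(h, h, sex = 1L, id = 1L)
  g <- make_gamete(pop, 1, genome, mutation_rate = 0)
  expect_identical(g, drop(h))
  expect_error(make_gametes(pop, 1, genome, mutation_rate = -1), "non-negative")
})

test_that("crossover process follows Haldane's model", {
  set.seed(3)
  # fully informative parent: strand switches are observable crossovers
  L <- 200
  genome <- toy_genome(L)
  pop <- new_population(matrix(0L, L, 1), matrix(1L, L, 1), sex = 1L, id = 1L)
  g <- make_gametes(pop, rep(1, 10000), genome)
  xo <- colSums(abs(diff(g)))
  expect_equal(mean(xo), 1.0, tolerance = 0.05)  # Poisson mean = map length

  # two loci 0.5 Morgan apart: Haldane recombinant fraction (1 - exp(-1))/2
  gm2 <- genome_map(1, list(c(0.25, 0.75)))
  pop2 <- new_population(matrix(0L, 2, 1), matrix(1L, 2, 1), sex = 1L, id = 1L)
  g2 <- make_gametes(pop2, rep(1, 10000), gm2)
  rf <- mean(g2[1, ] != g2[2, ])
  expect_equal(rf, (1 - exp(-1)) / 2, tolerance = 0.02)

  # Mendelian sampling at a heterozygous locus
  gm1 <- genome_map(1, list(0.5))
  pop1 <- new_population(matrix(0L, 1, 1), matrix(1L, 1, 1), sex = 1L, id = 1L)
  g1 <- make_gametes(pop1, rep(1, 10000), gm1)
  expect_equal(mean(g1), 0.5, tolerance = 0.02)
})

test_that("mutation flips transmitted alleles at the requested rate", {
  set.seed(4)
  L <- 1000
  genome <- toy_genome(L)
  pop <- new_population(matrix(0L, L, 1), matrix(0L, L, 1), sex = 1L, id = 1L)
  g <- make_gametes(pop, rep(1, 2000), genome, mutation_rate = 0.01)
  expect_equal(mean(colSums(g)), L * 0.01, tolerance = 0.5)
  # without mutation an absent allele never appears
  g0 <- make_gametes(pop, rep(1, 500), genome, mutation_rate = 0)
  expect_true(all(g0 == 0L))
})

test_that("advance_generation produces litters with the documented structure", {
  set.seed(5)
  genome <- toy_genome(20)
  pop <- init_founders(genome, 60, 320)
  off <- advance_generation(pop, genome, 50, 300, "random", litter_size = 10)
  expect_equal(pop_size(off), 3000)
  expect_equal(sum(off$sex == 1L), 1500)
  expect_equal(sum(off$sex == 2L), 1500)
  expect_equal(off$generation, pop$generation + 1L)
  # pedigree: sires male, dams female, each dam one litter of 10
  expect_true(all(off$sire %in% pop$id[pop$sex == 1L]))
  expect_true(all(off$dam %in% pop$id[pop$sex == 2L]))
  expect_true(all(table(off$dam) == 10))
  expect_error(advance_generation(pop, genome, 100, 300, "random"),
               "need 100 sires")
  # tied phenotypes select the full quota without error
  off2 <- advance_generation(pop, genome, 5, 10, "positive",
                             phenotypes = rep(1, pop_size(pop)), litter_size = 2)
  expect_equal(pop_size(off2), 20)
})

test_that("one generation of selection orders offspring genotypic means", {
  set.seed(6)
  genome <- toy_genome(30)
  arch <- trait_architecture(1:30, a = rnorm(30))
  diffs <- replicate(12, {
    pop <- init_founders(genome, 40, 80, freq = runif(30, 0.2, 0.8))
    G <- genotypic_value(qtl_geno(pop, genome), arch)
    mg <- vapply(c("positive", "random", "negative"), function(dir) {
      off <- advance_generation(pop, genome, 10, 30, dir, phenotypes = G,
                                litter_size = 4)
      mean(genotypic_value(qtl_geno(off, genome), arch))
    }, numeric(1))
    c(mg["positive"] - mg["random"], mg["random"] - mg["negative"])
  })
  # response to selection: positive > random > negative on average
  expect_gt(mean(diffs[1, ]), 0)
  expect_gt(mean(diffs[2, ]), 0)
  expect_gt(mean(diffs[1, ] > 0), 0.8)
  expect_gt(mean(diffs[2, ] > 0), 0.8)
})

test_that("fast history yields the expanded cohort with U-shaped frequencies", {
  set.seed(7)
  genome <- toy_genome(500)
  pop0 <- run_history(genome, fast = TRUE)
  expect_equal(pop_size(pop0), 3000)
  p <- (rowSums(pop0$hap1) + rowSums(pop0$hap2)) / (2 * 3000)
  outer_mass <- mean(p < 0.1 | p > 0.9)
  central_mass <- mean(p > 0.4 & p < 0.6)
  expect_gt(outer_mass, central_mass)
})

test_that("full history runs the three phases, the expansion and historical-only mutation", {
  set.seed(8)
  genome <- toy_genome(60)
  pop0 <- run_history(genome, fast = FALSE, phase_gens = c(4L, 4L, 4L))
  expect_equal(pop_size(pop0), 3000)
  expect_equal(sum(pop0$sex == 1L), 1500)
  expect_equal(max(pop0$generation), 12)  # 11 historical transitions + expansion
})

test_that("harmonic-mean effective size matches the analytic values", {
  expect_equal(ne_harmonic(data.frame(Nm = 50, Nf = 300)), 4 * 50 * 300 / 350,
               tolerance = 1e-12)
  expect_equal(ne_harmonic(data.frame(Nm = 100, Nf = 600)), 2400 / 7,
               tolerance = 1e-12)
  sched <- historical_schedule()
  expect_equal(nrow(sched), 600)
  expect_equal(round(ne_harmonic(sched)), 234)
  expect_error(ne_harmonic(data.frame(Nm = 0, Nf = 10)), "positive")
})

test_that("pedigree inbreeding reproduces textbook kinship identities", {
  # full-sib mating of unrelated non-inbred parents: offspring F = 0.25
  ped <- data.frame(id = 1:5,
                    sire = c(0, 0, 1, 1, 3),
                    dam  = c(0, 0, 2, 2, 4),
                    generation = c(0, 0, 1, 1, 2))
  s <- pedigree_inbreeding(ped)
  expect_equal(s$F, c(0, 0, 0, 0, 0.25))
  # half sibs: F = 0.125
  ped2 <- data.frame(id = 1:6,
                     sire = c(0, 0, 0, 1, 1, 4),
                     dam  = c(0, 0, 0, 2, 3, 5),
                     generation = c(0, 0, 0, 1, 1, 2))
  expect_equal(pedigree_inbreeding(ped2)$F[6], 0.125)
  # founders have F = 0 by definition
  expect_true(all(pedigree_inbreeding(ped)$F[1:2] == 0))
  # cycles / non-generational parents are rejected
  bad <- data.frame(id = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2),
                    generation = c(0, 0, 2))
  expect_error(pedigree_inbreeding(bad), "generation")
})

test_that("random-mating line recovers the expected effective size", {
  set.seed(9)
  genome <- genome_map(1, list(c(0.3, 0.7)), qtl = 1:2)
  pop <- init_founders(genome, 50, 300, freq = c(0.5, 0.5))
  ped <- list(pop_pedigree(pop))
  for (g in 1:20) {
    pop <- advance_generation(pop, genome, 50, 300, "random", litter_size = 10)
    ped[[g + 1]] <- pop_pedigree(pop)
  }
  s <- pedigree_inbreeding(do.call(rbind, ped))
  expect_equal(s$ne, 4 * 50 * 300 / 350, tolerance = 0.2)
})

test_that("run_lines produces the seven-line structure with shared branch points", {
  set.seed(10)
  genome <- toy_genome(80)
  pop0 <- run_history(genome, fast = TRUE, expand = c(60, 60))
  genome <- designate_qtl(genome, pop0, 20)
  arch <- sample_architecture(genome$qtl, "D")
  sim <- run_lines(pop0, genome, arch, h2 = 0.3, total_gens = 4L,
                   branch_gens = c(0L, 2L, 3L), n_sires = 5, n_dams = 20)
  expect_named(sim$lines, c("P4", "N4", "R", "P2", "N2", "P1", "N1"))
  expect_true(all(vapply(sim$lines, function(l) l$generation, integer(1)) == 4L))
  expect_true(all(vapply(sim$lines, pop_size, integer(1)) == 200L))
  # branch lines descend from R individuals
  r_ids <- sim$pedigree$id[sim$pedigree$line == "R"]
  p2_founder_sires <- sim$pedigree$sire[sim$pedigree$line == "P2" &
                                        sim$pedigree$generation == 3]
  expect_true(all(p2_founder_sires %in% r_ids))
  # divergence grows with generations of divergent selection
  p <- vapply(sim$lines, function(l) line_freqs(l, genome)$p,
              numeric(length(genome$qtl)))
  d1 <- mean(abs(p[, "P1"] - p[, "N1"]))
  d4 <- mean(abs(p[, "P4"] - p[, "N4"]))
  expect_lt(d1, d4 + 0.05)
})

test_that("simulation is reproducible from the seed", {
  run <- function() {
    set.seed(11)
    genome <- toy_genome(30)
    pop0 <- run_history(genome, fast = TRUE, expand = c(30, 30))
    genome <- designate_qtl(genome, pop0, 10)
    arch <- sample_architecture(genome$qtl, "D_EAA", pairs_per_qtl = 3)
    run_lines(pop0, genome, arch, total_gens = 3L, branch_gens = c(0L, 1L, 2L),
              n_sires = 4, n_dams = 10)
  }
  a <- run(); b <- run()
  expect_identical(a$lines$P3$hap1, b$lines$P3$hap1)
  expect_identical(a$pedigree, b$pedigree)
})
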