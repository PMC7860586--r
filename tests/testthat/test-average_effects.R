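test_that("line frequencies are observed genotype counts", {
  gm <- toy_genome(1)
  all_FF <- new_population(matrix(1L, 1, 4), matrix(1L, 1, 4),
                           sex = rep(1:2, 2), id = 1:4)
  f <- line_freqs(all_FF, gm)
  expect_equal(unlist(f[, c("P", "H", "Q", "p")]), c(P = 1, H = 0, Q = 0, p = 1))

  # 25 FF / 50 Ff / 25 ff
  h1 <- matrix(rep(c(1L, 1L, 0L), c(25, 50, 25)), 1)
  h2 <- matrix(rep(c(1L, 0L, 0L), c(25, 50, 25)), 1)
  pop <- new_population(h1, h2, sex = rep(1:2, 50), id = 1:100)
  f <- line_freqs(pop, gm)
  expect_equal(unlist(f[, c("P", "H", "Q", "p")]),
               c(P = 0.25, H = 0.5, Q = 0.25, p = 0.5))

  set.seed(30)
  pop <- toy_pop(runif(10), n = 60, genome = toy_genome(10))
  f <- line_freqs(pop, toy_genome(10))
  expect_equal(f$p, f$P + f$H / 2)
  expect_equal(f$P + f$H + f$Q, rep(1, 10), tolerance = 1e-12)
})

test_that("closed-form purebred average effects evaluate the dominance and A-by-A terms", {
  # dominance term vanishes at p = 1/2
  arch <- trait_architecture(1L, a = 1, d = 0.5)
  expect_equal(alpha_pb_closed(arch, hwe_freqs(0.5))$alpha, 1)
  # a + (1 - 2p) d at p = 0
  arch <- trait_architecture(1L, a = 1, d = 1)
  expect_equal(alpha_pb_closed(arch, hwe_freqs(0))$alpha, 2)
  # A-by-A partner fixed at the focal allele adds +eps
  arch <- trait_architecture(1:2, a = c(1, 0),
                             pairs = data.frame(k = 1, l = 2, epsilon = 0.5,
                                                config = "AA"))
  f <- hwe_freqs(c(0.5, 1))
  expect_equal(alpha_pb_closed(arch, f)$alpha[1], 1.5)
  # no closed form under complementary epistasis
  archC <- trait_architecture(1:2, a = c(1, 0),
                              pairs = data.frame(k = 1, l = 2, epsilon = 0.5,
                                                 config = "C"))
  expect_error(alpha_pb_closed(archC, f), "complementary")
})

test_that("closed-form crossbred average effects use mate and cross frequencies", {
  # pure dominance: alpha_cb depends on the mate line only
  arch <- trait_architecture(1L, a = 0, d = 1)
  f1 <- hwe_freqs(0.5); f2 <- hwe_freqs(0.1)
  expect_equal(alpha_pb_closed(arch, f1)$alpha, 0)
  expect_equal(alpha_cb_closed(arch, f1, f2)$alpha, 0.8)
  expect_equal(alpha_cb_closed(arch, f1, f2)$alpha,
               alpha_pb_closed(arch, f2)$alpha)

  # pure A-by-A: crossbred alpha is the mean of the two purebred alphas
  set.seed(31)
  arch <- random_arch(10, dominance = FALSE)
  f1 <- random_freqs(10); f2 <- random_freqs(10)
  expect_equal(alpha_cb_closed(arch, f1, f2)$alpha,
               0.5 * (alpha_pb_closed(arch, f1)$alpha +
                      alpha_pb_closed(arch, f2)$alpha),
               tolerance = 1e-12)
})

test_that("identical parental lines give identical PB and CB average effects", {
  set.seed(32)
  arch <- random_arch(8)
  f <- random_freqs(8)
  expect_equal(alpha_cb_closed(arch, f, f)$alpha, alpha_pb_closed(arch, f)$alpha)
  expect_equal(alpha_regression(arch, target_cb(f, f))$alpha,
               alpha_regression(arch, target_pb(f))$alpha,
               tolerance = 1e-12)
})

test_that("average-excess engine matches the closed forms on random architectures", {
  set.seed(33)
  for (i in 1:100) {
    m <- sample(c(1, 2, 10), 1)
    arch <- random_arch(m, dominance = TRUE, pairs = m > 1, config = "AA")
    f1 <- random_freqs(m); f2 <- random_freqs(m)
    expect_equal(alpha_regression(arch, target_pb(f1))$alpha,
                 alpha_pb_closed(arch, f1)$alpha, tolerance = 1e-10)
    expect_equal(alpha_regression(arch, target_cb(f1, f2))$alpha,
                 alpha_cb_closed(arch, f1, f2)$alpha, tolerance = 1e-10)
  }
  # all effects zero: all alpha zero
  arch0 <- trait_architecture(1:3, a = rep(0, 3))
  expect_equal(alpha_regression(arch0, random_freqs(3))$alpha, rep(0, 3))
})

test_that("dominance-model crossbred effects ignore the focal line's own frequencies", {
  set.seed(34)
  arch <- random_arch(6, pairs = FALSE)
  f2 <- random_freqs(6)
  a1 <- alpha_regression(arch, target_cb(random_freqs(6), f2))
  a2 <- alpha_regression(arch, target_cb(random_freqs(6), f2))
  expect_equal(a1$alpha, a2$alpha, tolerance = 1e-12)
})

test_that("difference between PB and CB effects scales with the frequency gap", {
  # dominance: d(alpha1 - alpha1C)/dd = 2 (p2 - p1)
  p1 <- 0.8; p2 <- 0.3
  delta_alpha <- function(d) {
    arch <- trait_architecture(1L, a = 1, d = d)
    alpha_pb_closed(arch, hwe_freqs(p1))$alpha -
      alpha_cb_closed(arch, hwe_freqs(p1), hwe_freqs(p2))$alpha
  }
  expect_equal(delta_alpha(2) - delta_alpha(1), 2 * (p2 - p1))
  # A-by-A: d(alpha1 - alpha1C)/deps = (p_partner1 - p_partner2)
  delta_alpha_aa <- function(eps) {
    arch <- trait_architecture(1:2, a = c(1, 0),
                               pairs = data.frame(k = 1, l = 2, epsilon = eps,
                                                  config = "AA"))
    (alpha_pb_closed(arch, hwe_freqs(c(0.5, p1)))$alpha -
       alpha_cb_closed(arch, hwe_freqs(c(0.5, p1)), hwe_freqs(c(0.5, p2)))$alpha)[1]
  }
  expect_equal(delta_alpha_aa(2) - delta_alpha_aa(1), p1 - p2)
})

test_that("three-way dominance crossbred effects equal the direct two-way values", {
  set.seed(35)
  arch <- random_arch(7, pairs = FALSE)   # pure dominance
  sire <- random_freqs(7); dam1 <- random_freqs(7); dam2 <- random_freqs(7)
  three <- cross_spec(list(sire, dam1, dam2), "three", focal = 2)
  two <- target_cb(dam1, sire)
  expect_equal(alpha_cb_multiway(arch, three)$alpha,
               alpha_regression(arch, two)$alpha, tolerance = 1e-12)
  # with epistasis the three-way result differs once partner frequencies differ
  archE <- random_arch(7, dominance = FALSE, pairs = TRUE)
  a3 <- alpha_cb_multiway(archE, cross_spec(list(sire, dam1, dam2), "three", 2))
  a2 <- alpha_regression(archE, target_cb(dam1, sire))
  expect_gt(max(abs(a3$alpha - a2$alpha)), 1e-6)
  # all lines identical: crossbred equals purebred in any topology
  allsame <- cross_spec(list(sire, sire, sire), "three", focal = 2)
  expect_equal(alpha_cb_multiway(arch, allsame)$alpha,
               alpha_regression(arch, target_pb(sire))$alpha, tolerance = 1e-12)
})

test_that("four-way A-by-A effects use the mean frequency of all four lines", {
  set.seed(36)
  arch <- random_arch(5, dominance = FALSE, pairs = TRUE)
  fs <- replicate(4, random_freqs(5), simplify = FALSE)
  four <- cross_spec(fs, "four", focal = 1)
  pbar <- Reduce(`+`, lapply(fs, `[[`, "p")) / 4
  manual <- arch$a + rpcsim:::pair_sum(arch, pbar)
  expect_equal(alpha_cb_multiway(arch, four)$alpha, manual, tolerance = 1e-10)
  expect_error(cross_spec(fs[1:2], "three"), "3 parental lines")
})
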