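#' Average effects of allele substitution
#'
#' Average effects are computed from the average-excess definition: the
#' average effect of an allele is the mean genotypic value of offspring
#' produced by transmitting that allele minus the population mean, and the
#' average effect of allele substitution at a locus is the difference between
#' the average effects of its two alleles (identical to the regression /
#' NOIA average effect under random mating). [alpha_regression()] evaluates
#' this by exact enumeration over the pairing-allele pool and the
#' partner-locus genotype distribution of the target population and is valid
#' for every configuration, including complementary epistasis.
#' [alpha_pb_closed()] and [alpha_cb_closed()] are the closed forms for
#' dominance and additive-by-additive architectures.
#'
#' @name average_effects
NULL

# An alpha target bundles, per QTL: the frequency of the focal allele in the
# gamete pool that pairs with the transmitted allele, and the partner-locus
# genotype distribution (P, H, Q) of the population in which the offspring's
# genotypic value is evaluated. Loci are assumed in linkage equilibrium
# inside the engine (frequencies enter per locus).
alpha_target <- function(pool, P, H, Q, label) {
  structure(list(pool = pool, P = P, H = H, Q = Q, label = label),
            class = "alpha_target")
}

#' Purebred target population for the average-effect engine
#'
#' Transmitted alleles pair with a gamete from the line's own pool and
#' partner loci follow the line's observed genotype frequencies.
#'
#' @param own A [line_freqs()] table for the line.
#' @export
target_pb <- function(own) {
  alpha_target(own$p, own$P, own$H, own$Q, "PB")
}

#' Two-way crossbred target population
#'
#' Transmitted focal-line alleles pair with a gamete from the mate line;
#' partner-locus genotypes follow the two-way cross offspring distribution
#' `(p1 p2, p1 q2 + q1 p2, q1 q2)` (random line crossing).
#'
#' @param own,mate [line_freqs()] tables of the focal and mate lines.
#' @export
target_cb <- function(own, mate) {
  p1 <- own$p; p2 <- mate$p
  alpha_target(p2,
               P = p1 * p2,
               H = p1 * (1 - p2) + (1 - p1) * p2,
               Q = (1 - p1) * (1 - p2),
               label = "CB")
}

#' Cross specification for two-, three- and four-way crosses
#'
#' Describes which gamete pool the focal line's transmitted alleles pair with
#' and which population supplies the partner-locus genotype distribution:
#' \describe{
#'   \item{two}{`lines = list(line1, line2)`, focal = 1 or 2; offspring of
#'     `line1 x line2`.}
#'   \item{three}{`lines = list(sire, dam1, dam2)`; offspring of
#'     `sire x F1(dam1, dam2)`. Alleles transmitted from a dam line always
#'     pair with a sire-line gamete; sire alleles pair with the F1 pool.}
#'   \item{four}{`lines = list(a, b, c, d)`; offspring of
#'     `F1(a, b) x F1(c, d)`. Alleles descending from `a` or `b` pair with
#'     the `F1(c, d)` pool and vice versa.}
#' }
#'
#' @param lines List of [line_freqs()] tables (the parental lines, in the
#'   roles above).
#' @param type Cross topology.
#' @param focal Index (into `lines`) of the focal line.
#' @return An `alpha_target` for use with [alpha_regression()].
#' @export
cross_spec <- function(lines, type = c("two", "three", "four"), focal = 1) {
  type <- match.arg(type)
  need <- c(two = 2L, three = 3L, four = 4L)[[type]]
  if (length(lines) != need)
    stop("a ", type, "-way cross needs ", need, " parental lines")
  if (focal < 1 || focal > need) stop("`focal` must index one of the lines")
  p <- lapply(lines, function(f) f$p)
  gam <- switch(type,
    two   = list(p[[1]], p[[2]]),
    three = list(p[[1]], 0.5 * (p[[2]] + p[[3]])),
    four  = list(0.5 * (p[[1]] + p[[2]]), 0.5 * (p[[3]] + p[[4]])))
  pool <- switch(type,
    two   = gam[[if (focal == 1) 2 else 1]],
    three = if (focal == 1) gam[[2]] else gam[[1]],
    four  = if (focal <= 2) gam[[2]] else gam[[1]])
  pa <- gam[[1]]; pb <- gam[[2]]
  alpha_target(pool,
               P = pa * pb,
               H = pa * (1 - pb) + (1 - pa) * pb,
               Q = (1 - pa) * (1 - pb),
               label = paste0("CB:", type))
}

#' Average effects by exact average-excess enumeration
#'
#' For each QTL the engine enumerates the offspring genotype distribution
#' conditional on the transmitted allele: the pairing allele comes from the
#' target's gamete pool and partner-locus genotypes from the target's
#' per-locus genotype distribution (loci independent). The average effect of
#' allele substitution is the difference in expected genotypic value between
#' transmitting the focal and the alternative allele. At most 2 x 3 genotype
#' combinations arise per epistatic pair, so the result is exact.
#'
#' @param arch A `trait_architecture`.
#' @param target A [line_freqs()] table (purebred target), or an
#'   `alpha_target` built by [target_pb()], [target_cb()] or [cross_spec()].
#' @return An `alpha_set`: data frame with columns `locus` (QTL id), `alpha`,
#'   plus a `target` attribute.
#' @export
alpha_regression <- function(arch, target) {
  if (inherits(target, "line_freqs")) target <- target_pb(target)
  if (!inherits(target, "alpha_target")) stop("invalid target")
  m <- length(arch$qtl_ids)
  if (length(target$pool) != m) stop("target and architecture disagree on QTL count")
  pool <- target$pool
  # focal-locus part: transmit F -> {FF w.p. pool, Ff w.p. 1-pool} on the
  # (-a, d, +a) scale; transmit f -> {Ff, ff}; difference a + (1 - 2 pool) d.
  alpha <- arch$a + (1 - 2 * pool) * arch$d
  pr <- arch$pairs
  if (nrow(pr)) {
    # both directions of every pair contribute to the focal member's alpha
    ki <- c(pr$k, pr$l); li <- c(pr$l, pr$k)
    eps <- rep(pr$epsilon, 2); cfg <- rep(pr$config, 2)
    P <- target$P[li]; H <- target$H[li]; Q <- target$Q[li]
    pj <- pool[ki]
    # E over the partner genotype of the contrast c(s, x_l) for focal code s
    aa <- cfg == "AA"
    Ec1 <- Ec0 <- Ecm1 <- numeric(length(ki))
    Ec1[aa] <- (P - Q)[aa]; Ec0[aa] <- 0; Ecm1[aa] <- -(P - Q)[aa]
    if (any(!aa)) {  # complementary: +1 iff both codes >= 0
      Ec1[!aa] <- (P + H - Q)[!aa]
      Ec0[!aa] <- (P + H - Q)[!aa]
      Ecm1[!aa] <- -1
    }
    # E[c | transmit F] - E[c | transmit f] with the focal code mixing over
    # the pairing allele: F -> {1 w.p. pj, 0}, f -> {0 w.p. pj, -1}
    delta <- pj * Ec1 + (1 - 2 * pj) * Ec0 - (1 - pj) * Ecm1
    add <- rowsum(eps * delta, group = ki)
    alpha[as.integer(rownames(add))] <- alpha[as.integer(rownames(add))] + add[, 1]
  }
  alpha_set(arch$qtl_ids, alpha, target$label)
}

alpha_set <- function(qtl_ids, alpha, label) {
  structure(data.frame(locus = qtl_ids, alpha = alpha),
            class = c("alpha_set", "data.frame"), target = label)
}

#' Closed-form purebred average effects (dominance / A-by-A architectures)
#'
#' `alpha_j = a_j + (1 - 2 p_j) d_j - sum_l (1 - 2 p_l) eps_jl` over the A-by-A
#' partners `l` of `j`, with own-line frequencies throughout. Errors on
#' complementary pairs, for which no closed form exists.
#'
#' @param arch A `trait_architecture` with only dominance and/or "AA" pairs.
#' @param own [line_freqs()] of the line.
#' @return An `alpha_set`.
#' @export
alpha_pb_closed <- function(arch, own) {
  check_closed(arch)
  alpha <- arch$a + (1 - 2 * own$p) * arch$d + pair_sum(arch, own$p)
  alpha_set(arch$qtl_ids, alpha, "PB")
}

#' Closed-form crossbred average effects (dominance / A-by-A architectures)
#'
#' The dominance part uses the mate-line frequency (`a + (1 - 2 p2) d`, so a
#' pure-dominance architecture gives the mate line's purebred average
#' effects); the A-by-A part uses the cross frequency `pC = (p1 + p2) / 2` at
#' the partner loci (equivalently the mean of the two purebred alpha
#' vectors).
#'
#' @param arch A `trait_architecture` with only dominance and/or "AA" pairs.
#' @param own,mate [line_freqs()] of the focal and mate lines.
#' @return An `alpha_set`.
#' @export
alpha_cb_closed <- function(arch, own, mate) {
  check_closed(arch)
  pc <- 0.5 * (own$p + mate$p)
  alpha <- arch$a + (1 - 2 * mate$p) * arch$d + pair_sum(arch, pc)
  alpha_set(arch$qtl_ids, alpha, "CB")
}

check_closed <- function(arch) {
  if (nrow(arch$pairs) && any(arch$pairs$config != "AA"))
    stop("no closed form exists for complementary epistatic pairs; use alpha_regression()")
}

# - sum over AA partners of (1 - 2 p_partner) * epsilon, per focal QTL
pair_sum <- function(arch, p) {
  pr <- arch$pairs
  out <- numeric(length(arch$qtl_ids))
  if (!nrow(pr)) return(out)
  ki <- c(pr$k, pr$l); li <- c(pr$l, pr$k); eps <- rep(pr$epsilon, 2)
  add <- rowsum(-(1 - 2 * p[li]) * eps, group = ki)
  out[as.integer(rownames(add))] <- add[, 1]
  out
}

#' Average effects for multi-way crossbred performance
#'
#' Runs the average-excess engine with the pairing pool and partner-locus
#' population set by the cross topology (see [cross_spec()]). Under a pure
#' dominance architecture the dam-line average effects for three-way
#' crossbred performance equal the two-way values obtained by mating the dam
#' line directly to the sire line, because dam-line alleles always pair with
#' a sire-line gamete.
#'
#' @param arch A `trait_architecture`.
#' @param cross An `alpha_target` from [cross_spec()].
#' @return An `alpha_set`.
#' @export
alpha_cb_multiway <- function(arch, cross) {
  if (!inherits(cross, "alpha_target")) stop("`cross` must come from cross_spec()")
  alpha_regression(arch, cross)
}
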