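#' Sample a functional trait architecture
#'
#' Additive effects are `a ~ N(0, 1)` per QTL. In the dominance scenarios
#' ("D", "D_EAA") dominance coefficients `delta ~ N(0.2, 0.3^2)` are sampled
#' independently of `a` and scaled, `d = delta * |a|`. In the epistatic
#' scenarios each QTL interacts with exactly five others: a 5-regular random
#' pairing is built by configuration-model stub matching with rejection of
#' self-pairs and duplicate pairs. Epistatic coefficients
#' `gamma ~ N(0, 0.2^2 + 0.3^2 over 5)` (standard deviation about 0.16, so
#' that the functional epistatic variance per QTL matches the functional
#' dominance variance per QTL of scenario D) are scaled as
#' `epsilon = gamma * sqrt(|a_k a_l|)`. Pairs carry the additive-by-additive
#' contrast in scenarios "EAA"/"D_EAA" and the complementary contrast in
#' "EC".
#'
#' @param qtl_ids Integer QTL identifiers (genome locus indices), or a single
#'   count.
#' @param scenario One of "D", "EAA", "D_EAA", "EC".
#' @param pairs_per_qtl Interactions per QTL in epistatic scenarios.
#' @return A `trait_architecture`: `qtl_ids`, `a`, `d`, `pairs` (data frame
#'   `k`, `l` as 1-based positions in `qtl_ids`, `epsilon`, `config`),
#'   `scenario`.
#' @export
sample_architecture <- function(qtl_ids, scenario = c("D", "EAA", "D_EAA", "EC"),
                                pairs_per_qtl = 5) {
  scenario <- match.arg(scenario)
  if (length(qtl_ids) == 1L && qtl_ids > 1L) qtl_ids <- seq_len(qtl_ids)
  m <- length(qtl_ids)
  a <- rnorm(m)
  d <- if (scenario %in% c("D", "D_EAA")) rnorm(m, 0.2, 0.3) * abs(a) else numeric(m)
  pairs <- empty_pairs()
  if (scenario != "D") {
    km <- regular_pairing(m, pairs_per_qtl)
    gamma_sd <- epistasis_gamma_sd(pairs_per_qtl)
    gam <- rnorm(nrow(km), 0, gamma_sd)
    eps <- gam * sqrt(abs(a[km[, 1]] * a[km[, 2]]))
    pairs <- data.frame(k = km[, 1], l = km[, 2], epsilon = eps,
                        config = if (scenario == "EC") "C" else "AA",
                        stringsAsFactors = FALSE)
  }
  trait_architecture(qtl_ids, a, d, pairs, scenario)
}

#' Calibration constant for epistatic coefficients
#'
#' Standard deviation of the epistatic coefficient distribution,
#' `sqrt((0.2^2 + 0.3^2) / pairs_per_qtl)`: the squared mean plus variance of
#' the dominance coefficients, split over the interactions per QTL.
#'
#' @param pairs_per_qtl Interactions per QTL.
#' @export
epistasis_gamma_sd <- function(pairs_per_qtl = 5) {
  sqrt((0.2^2 + 0.3^2) / pairs_per_qtl)
}

empty_pairs <- function() {
  data.frame(k = integer(), l = integer(), epsilon = numeric(),
             config = character(), stringsAsFactors = FALSE)
}

#' Construct a trait architecture
#'
#' @param qtl_ids Integer QTL identifiers.
#' @param a,d Per-QTL additive and dominance effects (trait units; the
#'   genotype scale is `-a`, `d`, `+a` for the 0/1/2 allele counts).
#' @param pairs Data frame `k`, `l` (1-based positions in `qtl_ids`, k != l),
#'   `epsilon`, `config` ("AA" or "C").
#' @param scenario Scenario label.
#' @export
trait_architecture <- function(qtl_ids, a, d = numeric(length(a)),
                               pairs = empty_pairs(), scenario = "D") {
  m <- length(qtl_ids)
  stopifnot(length(a) == m, length(d) == m)
  pairs <- as.data.frame(pairs)
  if (nrow(pairs)) {
    if (any(pairs$k == pairs$l)) stop("epistatic pairs must reference distinct QTL")
    if (any(pairs$k < 1 | pairs$k > m | pairs$l < 1 | pairs$l > m))
      stop("pair indices out of range")
    if (!all(pairs$config %in% c("AA", "C"))) stop("unknown pair configuration")
    key <- paste(pmin(pairs$k, pairs$l), pmax(pairs$k, pairs$l))
    if (anyDuplicated(key)) stop("duplicate epistatic pairs")
  }
  structure(list(qtl_ids = as.integer(qtl_ids), a = as.numeric(a),
                 d = as.numeric(d), pairs = pairs, scenario = scenario),
            class = "trait_architecture")
}

#' @export
print.trait_architecture <- function(x, ...) {
  cat(sprintf("trait_architecture (%s): %d QTL, %d epistatic pairs\n",
              x$scenario, length(x$qtl_ids), nrow(x$pairs)))
  invisible(x)
}

# Exact k-regular random pairing on m nodes: stub matching with rejection.
regular_pairing <- function(m, k, max_tries = 10000L) {
  if ((m * k) %% 2 != 0 || m <= k)
    stop("no ", k, "-regular pairing exists for ", m, " QTL")
  for (i in seq_len(max_tries)) {
    stubs <- sample(rep.int(seq_len(m), k))
    km <- matrix(stubs, ncol = 2)
    if (any(km[, 1] == km[, 2])) next
    key <- pmin(km[, 1], km[, 2]) * (m + 1) + pmax(km[, 1], km[, 2])
    if (anyDuplicated(key)) next
    return(km)
  }
  stop("failed to build a ", k, "-regular pairing after ", max_tries, " attempts")
}

#' Genotypic values under a functional architecture
#'
#' With `x = allele count - 1` and `h = 1` for heterozygotes:
#' `G = sum_j a_j x_j + d_j h_j + sum_(k,l) eps_kl c(x_k, x_l)`, where the
#' additive-by-additive contrast is `c = x_k x_l` (the nine two-locus cells
#' `a+eps, 0, -a-eps / a, 0, -a / a-eps, 0, -a+eps`) and the complementary
#' contrast is `+1` when both loci carry at least one copy of their focal
#' allele and `-1` otherwise.
#'
#' @param geno Integer matrix of QTL allele counts (individuals x QTL),
#'   entries in 0/1/2.
#' @param arch A `trait_architecture`.
#' @return Numeric vector of genotypic values, one per individual.
#' @export
genotypic_value <- function(geno, arch) {
  if (is.vector(geno)) geno <- matrix(geno, nrow = 1)
  if (ncol(geno) != length(arch$qtl_ids))
    stop("genotype matrix and architecture disagree on QTL count")
  if (any(geno < 0L | geno > 2L)) stop("genotype codes must be 0, 1 or 2")
  x <- geno - 1
  G <- drop(x %*% arch$a)
  if (any(arch$d != 0)) G <- G + drop((geno == 1L) %*% arch$d)
  pr <- arch$pairs
  if (nrow(pr)) {
    xk <- x[, pr$k, drop = FALSE]; xl <- x[, pr$l, drop = FALSE]
    cc <- matrix(0, nrow(x), nrow(pr))
    aa <- pr$config == "AA"
    if (any(aa)) cc[, aa] <- xk[, aa, drop = FALSE] * xl[, aa, drop = FALSE]
    if (any(!aa)) {
      both <- (xk[, !aa, drop = FALSE] >= 0) & (xl[, !aa, drop = FALSE] >= 0)
      cc[, !aa] <- ifelse(both, 1, -1)
    }
    G <- G + drop(cc %*% pr$epsilon)
  }
  G
}

#' Environmental variance for a target broad-sense heritability
#'
#' Solves `H2 = Var(G) / (Var(G) + Ve)` for `Ve`:
#' `Ve = Var(G) (1 - H2) / H2`.
#'
#' @param G Genotypic values (or their variance as a single number).
#' @param H2 Target broad-sense heritability in (0, 1].
#' @export
calibrate_ve <- function(G, H2) {
  if (H2 <= 0 || H2 > 1) stop("H2 must be in (0, 1]")
  vg <- if (length(G) == 1L) G else var(G)
  if (vg <= 0 && H2 < 1) stop("Var(G) must be positive")
  vg * (1 - H2) / H2
}

#' Phenotypes from genotypic values
#'
#' `phenotype = G + N(0, Ve)`, independent across individuals.
#'
#' @param G Genotypic values.
#' @param Ve Environmental variance (>= 0).
#' @export
phenotypes <- function(G, Ve) {
  if (Ve < 0) stop("Ve must be non-negative")
  G + rnorm(length(G), 0, sqrt(Ve))
}
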