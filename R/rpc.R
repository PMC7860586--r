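#' Centered genotype matrix
#'
#' Codes genotypes as allele count minus `2 p_j`, with `p_j` the focal-line
#' allele frequency: `2 - 2p`, `1 - 2p`, `0 - 2p` for the three genotypes.
#' Columns centered on the population's own frequencies have mean zero.
#'
#' @param pop A `qtl_pop`.
#' @param genome A `genome_map` with designated QTL (or locus index vector).
#' @param focal [line_freqs()] supplying the centering frequencies; defaults
#'   to the population's own frequencies.
#' @return Numeric matrix, individuals x QTL.
#' @export
center_genotypes <- function(pop, genome, focal = line_freqs(pop, genome)) {
  g <- qtl_geno(pop, genome)
  if (ncol(g) != nrow(focal)) stop("QTL sets of population and frequencies disagree")
  sweep(g, 2, 2 * focal$p)
}

#' Additive genetic values
#'
#' `v = H alpha` (Falconer's breeding-value sum over loci of centered allele
#' counts times average effects).
#'
#' @param H Centered genotype matrix from [center_genotypes()].
#' @param alpha An `alpha_set` or numeric vector of average effects.
#' @return Numeric vector, one additive genetic value per individual.
#' @export
additive_values <- function(H, alpha) {
  a <- if (inherits(alpha, "alpha_set")) alpha$alpha else as.numeric(alpha)
  if (ncol(H) != length(a)) stop("dimension mismatch between H and alpha")
  drop(H %*% a)
}

#' Realized purebred-crossbred genetic correlation
#'
#' Pearson correlation between the additive genetic values for purebred and
#' crossbred performance of the same individuals.
#'
#' @param v_pb,v_cb Additive genetic values for PB and CB performance.
#' @export
realized_rpc <- function(v_pb, v_cb) {
  if (length(v_pb) != length(v_cb) || length(v_pb) < 3)
    stop("need at least 3 paired additive genetic values")
  if (sd(v_pb) == 0 || sd(v_cb) == 0)
    stop("correlation undefined: an additive-value vector has zero variance")
  cor(v_pb, v_cb)
}

#' Parental-line variance components for r_pc prediction
#'
#' Computes `sigma1_sq` (additive variance in line 1 for its own trait),
#' `sigma1_2_sq` (variance in line 1 for the trait as expressed in line 2,
#' i.e. with the mate line's purebred average effects) and their covariance
#' `cov_1_12`, all taken over line-1 genotypes. The empirical method uses
#' sample (co)variances of `H alpha1` and `H alpha2` (denominator `n - 1`);
#' the LE-formula method evaluates the linkage-equilibrium sums
#' `sum 2 p1 (1 - p1) alpha^2` and the matching cross-product.
#'
#' @param H Centered line-1 genotype matrix (empirical method).
#' @param alpha1,alpha2 `alpha_set`s (or vectors): purebred average effects of
#'   the focal and mate lines.
#' @param method "empirical" or "le".
#' @param freqs Line-1 [line_freqs()] (required for `method = "le"`).
#' @return A `variance_components` list: `sigma1_sq`, `sigma1_2_sq`,
#'   `cov_1_12`, `method`.
#' @export
variance_components <- function(H = NULL, alpha1, alpha2,
                                method = c("empirical", "le"), freqs = NULL) {
  method <- match.arg(method)
  a1 <- if (inherits(alpha1, "alpha_set")) alpha1$alpha else as.numeric(alpha1)
  a2 <- if (inherits(alpha2, "alpha_set")) alpha2$alpha else as.numeric(alpha2)
  if (method == "empirical") {
    if (is.null(H) || nrow(H) < 3) stop("empirical components need >= 3 individuals")
    v1 <- drop(H %*% a1); v2 <- drop(H %*% a2)
    out <- list(sigma1_sq = var(v1), sigma1_2_sq = var(v2), cov_1_12 = cov(v1, v2))
  } else {
    if (is.null(freqs)) stop("LE-formula components need line-1 frequencies")
    w <- 2 * freqs$p * (1 - freqs$p)
    out <- list(sigma1_sq = sum(w * a1^2), sigma1_2_sq = sum(w * a2^2),
                cov_1_12 = sum(w * a1 * a2))
  }
  out$method <- method
  structure(out, class = "variance_components")
}

#' Dominance-model r_pc predictor (equals the between-line genetic correlation)
#'
#' `r_pc^D = cov_1_12 / (sigma1 sigma1(2))`: under a dominance architecture
#' the crossbred average effects in line 1 equal the purebred average effects
#' of line 2, so r_pc is the correlation between the two additive genetic
#' values of line-1 members, i.e. the between-line genetic correlation r_g.
#'
#' @param vc A `variance_components` (or list with the three components).
#' @export
predict_rpc_D <- function(vc) {
  if (vc$sigma1_sq <= 0 || vc$sigma1_2_sq <= 0)
    stop("correlation undefined: zero additive variance")
  vc$cov_1_12 / sqrt(vc$sigma1_sq * vc$sigma1_2_sq)
}

#' A-by-A epistasis-model r_pc predictor
#'
#' `r_pc^AA = (sigma1^2 + cov_1_12) /
#'   (sigma1 sqrt(sigma1^2 + sigma1(2)^2 + 2 cov_1_12))`: under a pure A-by-A
#' architecture the crossbred average effects are the mean of the two lines'
#' purebred average effects.
#'
#' @inheritParams predict_rpc_D
#' @export
predict_rpc_AA <- function(vc) {
  den2 <- vc$sigma1_sq + vc$sigma1_2_sq + 2 * vc$cov_1_12
  if (vc$sigma1_sq <= 0 || den2 <= 0)
    stop("correlation undefined: non-positive denominator")
  (vc$sigma1_sq + vc$cov_1_12) / (sqrt(vc$sigma1_sq) * sqrt(den2))
}

#' Between-line additive genetic correlation
#'
#' `r_g = cov_1_12 / (sigma1 sigma1(2))`; identical to [predict_rpc_D()].
#'
#' @inheritParams predict_rpc_D
#' @export
rg_between_lines <- function(vc) predict_rpc_D(vc)

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("variance_components (%s): sigma1_sq = %.4g, sigma1_2_sq = %.4g, cov = %.4g\n",
              x$method, x$sigma1_sq, x$sigma1_2_sq, x$cov_1_12))
  invisible(x)
}

#' Realized and predicted r_pc for one ordered line pair
#'
#' For focal line 1 mated to line 2: computes purebred average effects in
#' both lines and crossbred average effects in line 1 with the
#' average-excess engine, additive genetic values over line-1 genotypes
#' (centered on line-1 frequencies), the realized r_pc, and the two
#' predictors from empirical parental-line variance components.
#'
#' @param pop1,pop2 Final cohorts of the focal and mate lines.
#' @param genome A `genome_map` with designated QTL.
#' @param arch A `trait_architecture`.
#' @param method Component method passed to [variance_components()].
#' @return One-row data frame: line labels, number of QTL segregating in the
#'   focal line, `realized_rpc`, `pred_rpc_D`, `pred_rpc_AA`, `rg`, the three
#'   components and the method tag.
#' @export
rpc_pair <- function(pop1, pop2, genome, arch, method = "empirical") {
  f1 <- line_freqs(pop1, genome); f2 <- line_freqs(pop2, genome)
  a1 <- alpha_regression(arch, target_pb(f1))
  a2 <- alpha_regression(arch, target_pb(f2))
  ac <- alpha_regression(arch, target_cb(f1, f2))
  H <- center_genotypes(pop1, genome, f1)
  rpc_pair_core(H, f1, a1, a2, ac, pop1$line, pop2$line, method)
}

# shared by rpc_pair and run_experiment (which caches per-line quantities)
rpc_pair_core <- function(H, f1, a1, a2, ac, line1, line2, method = "empirical") {
  v1 <- additive_values(H, a1)
  vC <- additive_values(H, ac)
  vc <- variance_components(H, a1, a2, method = method, freqs = f1)
  data.frame(line1 = line1, line2 = line2,
             n_segregating_qtl = sum(f1$p > 0 & f1$p < 1),
             realized_rpc = realized_rpc(v1, vC),
             pred_rpc_D = predict_rpc_D(vc),
             pred_rpc_AA = predict_rpc_AA(vc),
             rg = rg_between_lines(vc),
             sigma1_sq = vc$sigma1_sq, sigma1_2_sq = vc$sigma1_2_sq,
             cov_1_12 = vc$cov_1_12, method = vc$method,
             stringsAsFactors = FALSE)
}
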