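#' Construct a population of phased individuals
#'
#' Haplotype matrices are stored locus-major (`n_loci x n_individuals`) so
#' that a gamete is a contiguous column; `hap1` holds the paternal and `hap2`
#' the maternal haplotype. Sex is coded 1 = male, 2 = female. `sire`/`dam`
#' are the global pedigree ids of the parents (0 for founders).
#'
#' @param hap1,hap2 Integer 0/1 matrices, loci in rows, individuals in columns.
#' @param sex Integer vector (1 male, 2 female).
#' @param id Integer vector of global pedigree ids.
#' @param sire,dam Integer vectors of parent ids (0 = founder).
#' @param generation Integer generation label of this cohort.
#' @param line Line label, e.g. "HIST", "R", "P50".
#' @return An object of class `qtl_pop`.
#' @export
new_population <- function(hap1, hap2, sex, id,
                           sire = rep(0L, length(id)),
                           dam = rep(0L, length(id)),
                           generation = 0L, line = "HIST") {
  stopifnot(is.matrix(hap1), is.matrix(hap2),
            all(dim(hap1) == dim(hap2)),
            ncol(hap1) == length(sex), length(sex) == length(id))
  structure(list(hap1 = hap1, hap2 = hap2,
                 sex = as.integer(sex), id = as.integer(id),
                 sire = as.integer(sire), dam = as.integer(dam),
                 generation = as.integer(generation), line = line),
            class = "qtl_pop")
}

#' @export
print.qtl_pop <- function(x, ...) {
  cat(sprintf("qtl_pop: line %s, generation %d, %d individuals (%d M / %d F), %d loci\n",
              x$line, x$generation, pop_size(x),
              sum(x$sex == 1L), sum(x$sex == 2L), nrow(x$hap1)))
  invisible(x)
}

#' Number of individuals in a population
#' @param pop A `qtl_pop`.
#' @export
pop_size <- function(pop) ncol(pop$hap1)

#' Initialize founder individuals in linkage equilibrium
#'
#' Each locus gets a target allele frequency (uniform on (0,1) by default, as
#' in the first historical generation) and founder alleles are drawn
#' independently per haplotype, i.e. linkage equilibrium and Hardy-Weinberg
#' proportions in expectation.
#'
#' @param genome A `genome_map`.
#' @param n_males,n_females Founder counts by sex.
#' @param freq Optional per-locus allele frequencies; defaults to `runif`.
#' @param line Line label for the cohort.
#' @return A founder `qtl_pop` (generation 0, parents unknown).
#' @export
init_founders <- function(genome, n_males, n_females, freq = NULL, line = "HIST") {
  n <- n_males + n_females
  if (n_males < 1 || n_females < 1)
    stop("founder counts must be positive")
  L <- genome$n_loci
  if (is.null(freq)) freq <- runif(L)
  if (length(freq) != L || any(freq < 0) || any(freq > 1))
    stop("`freq` must be per-locus frequencies in [0, 1]")
  hap1 <- matrix(rbinom(L * n, 1L, freq), L, n)
  hap2 <- matrix(rbinom(L * n, 1L, freq), L, n)
  storage.mode(hap1) <- "integer"; storage.mode(hap2) <- "integer"
  new_population(hap1, hap2,
                 sex = rep(c(1L, 2L), c(n_males, n_females)),
                 id = seq_len(n), generation = 0L, line = line)
}

#' QTL genotype matrix (allele counts)
#'
#' @param pop A `qtl_pop`.
#' @param genome A `genome_map` with designated QTL, or an integer vector of
#'   locus indices.
#' @return Integer matrix, individuals x loci, entries in 0/1/2.
#' @export
qtl_geno <- function(pop, genome) {
  loci <- if (inherits(genome, "genome_map")) genome$qtl else as.integer(genome)
  if (!length(loci)) stop("no QTL designated")
  t(pop$hap1[loci, , drop = FALSE] + pop$hap2[loci, , drop = FALSE])
}

#' Observed genotype and allele frequencies at the QTL of a line
#'
#' Genotype frequencies are the observed counts normalized per locus; no
#' Hardy-Weinberg assumption is made. The allele frequency is `p = P + H/2`,
#' where `P`, `H`, `Q` are the frequencies of the 2/1/0 allele-count
#' genotypes.
#'
#' @inheritParams qtl_geno
#' @return A data frame of class `line_freqs` with columns `locus`, `P`, `H`,
#'   `Q`, `p`.
#' @export
line_freqs <- function(pop, genome) {
  if (pop_size(pop) == 0L) stop("empty population")
  loci <- if (inherits(genome, "genome_map")) genome$qtl else as.integer(genome)
  g <- pop$hap1[loci, , drop = FALSE] + pop$hap2[loci, , drop = FALSE]
  P <- rowMeans(g == 2L); H <- rowMeans(g == 1L); Q <- rowMeans(g == 0L)
  structure(data.frame(locus = loci, P = P, H = H, Q = Q, p = P + H / 2),
            class = c("line_freqs", "data.frame"))
}

#' Pedigree table of a cohort
#'
#' @param pop A `qtl_pop`.
#' @return Data frame with columns id, sire, dam, sex, generation, line.
#' @export
pop_pedigree <- function(pop) {
  data.frame(id = pop$id, sire = pop$sire, dam = pop$dam, sex = pop$sex,
             generation = pop$generation, line = pop$line)
}
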