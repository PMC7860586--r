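#' Sample gametes from parents
#'
#' Draws one gamete per entry of `parents` from the phased haplotypes in
#' `pop`. Crossovers follow Haldane's model (Poisson count with mean equal to
#' the chromosome map length, uniform positions, no interference); the
#' starting strand is random per chromosome. With `mutation_rate > 0` every
#' transmitted allele flips (0 to 1 or 1 to 0) independently with that
#' probability, the recurrent mutation model used during the historical phase.
#'
#' @param pop A `qtl_pop`.
#' @param parents Integer vector of 1-based individual (column) indices; one
#'   gamete is produced per entry, in order.
#' @param genome A `genome_map`.
#' @param mutation_rate Per-locus, per-gamete flip probability.
#' @return Integer matrix, loci x gametes.
#' @export
make_gametes <- function(pop, parents, genome, mutation_rate = 0) {
  if (mutation_rate < 0) stop("mutation rate must be non-negative")
  cpp_gametes(pop$hap1, pop$hap2, as.integer(parents) - 1L,
              genome$pos, genome$chr_start, genome$chr_nloci,
              genome$chr_lengths, mutation_rate)
}

#' Sample a single gamete from one parent
#'
#' Convenience wrapper around [make_gametes()] for one individual.
#'
#' @inheritParams make_gametes
#' @param individual 1-based index of the parent in `pop`.
#' @return Integer vector of transmitted alleles, one per locus.
#' @export
make_gamete <- function(pop, individual, genome, mutation_rate = 0) {
  drop(make_gametes(pop, individual, genome, mutation_rate))
}
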