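#' Genome map
#'
#' A genome map holds the chromosome lengths (in Morgan), the map position of
#' every locus, and the subset of loci designated as QTL. Loci are bi-allelic
#' with alleles coded 0/1; positions are strictly increasing within a
#' chromosome and lie in `[0, chromosome length]`.
#'
#' @param chr_lengths Numeric vector of chromosome map lengths in Morgan.
#' @param positions List (one element per chromosome) of strictly increasing
#'   locus positions in Morgan.
#' @param qtl Integer vector of genome-wide (1-based) locus indices designated
#'   as QTL. May be empty; QTL are usually designated after the historical
#'   simulation with [designate_qtl()].
#' @return An object of class `genome_map` with per-locus lookup vectors
#'   (`chrom`, `pos`) alongside the per-chromosome structure.
#' @seealso [sample_genome()], [designate_qtl()]
#' @export
genome_map <- function(chr_lengths, positions, qtl = integer()) {
  if (length(chr_lengths) != length(positions))
    stop("`chr_lengths` and `positions` must have one entry per chromosome")
  for (c in seq_along(positions)) {
    p <- positions[[c]]
    if (length(p) && (any(p < 0) || any(p > chr_lengths[c])))
      stop("locus positions must lie in [0, chromosome length]")
    if (is.unsorted(p, strictly = TRUE))
      stop("locus positions must be strictly increasing within a chromosome")
  }
  nloc <- vapply(positions, length, integer(1))
  L <- sum(nloc)
  qtl <- as.integer(qtl)
  if (anyDuplicated(qtl) || any(qtl < 1L) || any(qtl > L))
    stop("`qtl` must be unique locus indices in 1..", L)
  structure(list(
    chr_lengths = as.numeric(chr_lengths),
    positions   = lapply(positions, as.numeric),
    qtl         = sort(qtl),
    n_chr       = length(chr_lengths),
    n_loci      = L,
    chr_nloci   = nloc,
    chr_start   = cumsum(c(0L, nloc[-length(nloc)])),  # 0-based, for the C kernel
    chrom       = rep(seq_along(nloc), nloc),
    pos         = unlist(positions, use.names = FALSE)
  ), class = "genome_map")
}

#' Sample a random genome map
#'
#' Draws `loci_per_chr` uniformly positioned loci on each of `n_chr`
#' chromosomes. The reference design is 10 chromosomes of 1 Morgan with 5000
#' loci each; the desk profile uses 2 chromosomes of 1000 loci.
#'
#' @param n_chr Number of chromosomes.
#' @param chr_length Map length of every chromosome, Morgan.
#' @param loci_per_chr Loci per chromosome.
#' @return A `genome_map` without designated QTL.
#' @export
sample_genome <- function(n_chr = 10, chr_length = 1, loci_per_chr = 5000) {
  # positions on a micro-Morgan grid: uniform, distinct, and exactly
  # representable in VCF POS (see write_vcf)
  grid <- round(chr_length * 1e6)
  positions <- lapply(seq_len(n_chr), function(c)
    sort(sample.int(grid, loci_per_chr)) / 1e6)
  genome_map(rep(chr_length, n_chr), positions)
}

#' Designate QTL among segregating loci
#'
#' Randomly selects `n_qtl` loci that segregate (allele frequency strictly
#' between 0 and 1) in `pop` to act as QTL.
#'
#' @param genome A `genome_map`.
#' @param pop A population, typically the expanded generation-0 cohort.
#' @param n_qtl Number of QTL to designate.
#' @return The `genome_map` with its `qtl` field set.
#' @export
designate_qtl <- function(genome, pop, n_qtl) {
  ac <- rowSums(pop$hap1) + rowSums(pop$hap2)
  seg <- which(ac > 0L & ac < 2L * pop_size(pop))
  if (length(seg) < n_qtl)
    stop("only ", length(seg), " segregating loci available for ", n_qtl, " QTL")
  genome$qtl <- sort(sample(seg, n_qtl))
  genome
}

#' @export
print.genome_map <- function(x, ...) {
  cat("genome_map:", x$n_chr, "chromosome(s),", x$n_loci, "loci,",
      length(x$qtl), "QTL\n")
  cat("  lengths (Morgan):", paste(format(x$chr_lengths), collapse = ", "), "\n")
  invisible(x)
}
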