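#' Write a population to VCF
#'
#' Plain-text VCF v4.2 with phased genotypes (`0|1`), one record per locus.
#' CHROM is the chromosome number, POS is `round(position_in_Morgan * 1e6) + 1`
#' (map positions are stored to micro-Morgan resolution), REF/ALT are the
#' placeholder alleles A/C for the 0/1 codes, and QTL records carry
#' `QTL=1` in INFO.
#'
#' @param pop A `qtl_pop`.
#' @param genome A `genome_map`.
#' @param file Output path.
#' @export
write_vcf <- function(pop, genome, file) {
  n <- pop_size(pop)
  L <- genome$n_loci
  info <- rep(".", L)
  info[genome$qtl] <- "QTL=1"
  fixed <- paste(genome$chrom,
                 as.integer(round(genome$pos * 1e6)) + 1L,
                 paste0("L", seq_len(L)), "A", "C", ".", "PASS", info, "GT",
                 sep = "\t")
  gt <- matrix(paste0(pop$hap1, "|", pop$hap2), L, n)
  body <- paste(fixed, apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=rpcsim",
    sprintf("##contig=<ID=%d>", seq_len(genome$n_chr)),
    "##INFO=<ID=QTL,Number=1,Type=Integer,Description=\"Locus is a QTL\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("I", pop$id)), collapse = "\t"))
  writeLines(c(header, body), file)
  invisible(file)
}

#' Read a population from VCF
#'
#' Reads a VCF written by [write_vcf()] (or any phased bi-allelic VCF with
#' the same layout) via `vcfR` and reconstructs the haplotypes, genome map
#' (positions `(POS - 1) / 1e6` Morgan) and QTL flags.
#'
#' @param file VCF path.
#' @return List with elements `pop` (a `qtl_pop`, pedigree unknown) and
#'   `genome` (a `genome_map`).
#' @export
read_vcf <- function(file) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v)
  chrom <- as.integer(vcfR::getCHROM(v))
  pos <- (as.numeric(vcfR::getPOS(v)) - 1) / 1e6
  info <- vcfR::getINFO(v)
  qtl <- which(grepl("QTL=1", info, fixed = TRUE))
  hap1 <- matrix(as.integer(substr(gt, 1, 1)), nrow(gt), ncol(gt))
  hap2 <- matrix(as.integer(substr(gt, 3, 3)), nrow(gt), ncol(gt))
  chrs <- sort(unique(chrom))
  positions <- split(pos, chrom)[as.character(chrs)]
  genome <- genome_map(vapply(positions, function(p) max(1, ceiling(max(p))), numeric(1)),
                       positions, qtl)
  ids <- suppressWarnings(as.integer(sub("^I", "", colnames(gt))))
  if (anyNA(ids)) ids <- seq_len(ncol(gt))
  pop <- new_population(hap1, hap2, sex = rep(c(1L, 2L), length.out = ncol(gt)),
                        id = ids)
  list(pop = pop, genome = genome)
}

#' Write / read a pedigree TSV
#'
#' Four columns: id, sire, dam, sex; 0 for founder parents.
#'
#' @param ped Pedigree data frame (e.g. from [run_lines()]).
#' @param file Path.
#' @export
write_pedigree <- function(ped, file) {
  write.table(ped[, intersect(c("id", "sire", "dam", "sex", "generation", "line"),
                              names(ped))],
              file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write a trait architecture to TSV
#'
#' Two files: `<stem>_effects.tsv` (qtl_id, chrom, pos, a, d) and
#' `<stem>_pairs.tsv` (qtl_k, qtl_l, epsilon, config). Round-trips through
#' [read_architecture()].
#'
#' @param arch A `trait_architecture`.
#' @param genome A `genome_map` (for chrom/pos columns).
#' @param stem Output path stem.
#' @return The two file paths, invisibly.
#' @export
write_architecture <- function(arch, genome, stem) {
  ef <- paste0(stem, "_effects.tsv"); pf <- paste0(stem, "_pairs.tsv")
  write.table(data.frame(qtl_id = arch$qtl_ids,
                         chrom = genome$chrom[arch$qtl_ids],
                         pos = genome$pos[arch$qtl_ids],
                         a = arch$a, d = arch$d),
              ef, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(qtl_k = arch$qtl_ids[arch$pairs$k],
                         qtl_l = arch$qtl_ids[arch$pairs$l],
                         epsilon = arch$pairs$epsilon,
                         config = arch$pairs$config),
              pf, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(ef, pf))
}

#' @rdname write_architecture
#' @param scenario Scenario label to attach on read.
#' @export
read_architecture <- function(stem, scenario = "D") {
  ef <- read.table(paste0(stem, "_effects.tsv"), header = TRUE, sep = "\t")
  pf <- read.table(paste0(stem, "_pairs.tsv"), header = TRUE, sep = "\t",
                   colClasses = c("integer", "integer", "numeric", "character"))
  pairs <- if (nrow(pf)) {
    data.frame(k = match(pf$qtl_k, ef$qtl_id), l = match(pf$qtl_l, ef$qtl_id),
               epsilon = pf$epsilon, config = pf$config,
               stringsAsFactors = FALSE)
  } else empty_pairs()
  trait_architecture(ef$qtl_id, ef$a, ef$d, pairs, scenario)
}

#' Write an average-effect set to TSV
#'
#' Columns: qtl_id, target, alpha.
#'
#' @param alpha An `alpha_set`.
#' @param file Path.
#' @export
write_alpha <- function(alpha, file) {
  write.table(data.frame(qtl_id = alpha$locus,
                         target = attr(alpha, "target"),
                         alpha = alpha$alpha),
              file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read an experiment configuration from JSON
#'
#' Keys mirror the arguments of [experiment_config()]; absent keys fall back
#' to the desk-profile defaults.
#'
#' @param file JSON path.
#' @export
read_config <- function(file) {
  x <- jsonlite::fromJSON(file)
  known <- names(formals(experiment_config))
  bad <- setdiff(names(x), known)
  if (length(bad)) stop("unknown configuration keys: ", paste(bad, collapse = ", "))
  do.call(experiment_config, x)
}
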