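#' Experiment configuration
#'
#' Bundles every knob of the validation experiment: the genetic-model
#' scenarios, replicate count, base seed, genome dimensions, demography and
#' selection schedule. Two ready-made profiles exist: [reference_profile()]
#' (the full design: 10 chromosomes x 5000 loci, 1000 QTL, full 600-generation
#' history) and [desk_profile()] (fast history, 2 chromosomes x 1000 loci,
#' 200 QTL, unchanged selection counts), the configuration used by the test
#' suite and the acceptance run.
#'
#' @param scenarios Character subset of `c("D", "EAA", "D_EAA", "EC")`.
#' @param replicates Number of replicates (>= 1).
#' @param base_seed Base random seed; each (scenario, replicate) cell uses
#'   `base_seed + replicate + 100000 * scenario_index`.
#' @param n_chr,loci_per_chr,chr_length,n_qtl Genome dimensions.
#' @param fast_history Use the Beta(0.2, 0.2) fast history.
#' @param pop0_males,pop0_females Size of the expanded generation-0 cohort.
#' @param total_gens,branch_gens Selection schedule (see [run_lines()]).
#' @param n_sires,n_dams,litter_size Selection and litter parameters.
#' @param h2 Broad-sense heritability of the selection phenotype.
#' @param mutation_rate Historical mutation rate (full history only).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(scenarios = c("D", "EAA", "D_EAA", "EC"),
                              replicates = 2, base_seed = 1,
                              n_chr = 2, loci_per_chr = 1000, chr_length = 1,
                              n_qtl = 200, fast_history = TRUE,
                              pop0_males = 1500, pop0_females = 1500,
                              total_gens = 50L, branch_gens = c(0L, 25L, 40L),
                              n_sires = 50, n_dams = 300, litter_size = 10,
                              h2 = 0.3, mutation_rate = 5e-5) {
  scenarios <- match.arg(scenarios, c("D", "EAA", "D_EAA", "EC"), several.ok = TRUE)
  if (replicates < 1) stop("need at least one replicate")
  structure(as.list(environment()), class = "experiment_config")
}

#' @rdname experiment_config
#' @export
desk_profile <- function(base_seed = 1, replicates = 2, ...) {
  experiment_config(base_seed = base_seed, replicates = replicates, ...)
}

#' @rdname experiment_config
#' @export
reference_profile <- function(base_seed = 1, replicates = 20, ...) {
  experiment_config(base_seed = base_seed, replicates = replicates,
                    n_chr = 10, loci_per_chr = 5000, n_qtl = 1000,
                    fast_history = FALSE, ...)
}

# small configuration for fast unit tests and CLI smoke runs
mini_profile <- function(base_seed = 1, replicates = 1, ...) {
  experiment_config(base_seed = base_seed, replicates = replicates,
                    n_chr = 1, loci_per_chr = 120, n_qtl = 20,
                    pop0_males = 60, pop0_females = 60,
                    total_gens = 4L, branch_gens = c(0L, 2L, 3L),
                    n_sires = 5, n_dams = 20, ...)
}

#' Run the r_pc validation experiment
#'
#' For every scenario and replicate: simulates one history, designates QTL
#' among segregating loci, samples a fresh architecture, simulates the seven
#' selected lines, and computes realized and predicted r_pc for every ordered
#' pair of lines (7 x 6 = 42 pairs). Purebred average effects are computed
#' once per line and reused across the pairs of a replicate.
#'
#' @param config An [experiment_config()].
#' @param progress Print one line per (scenario, replicate) cell.
#' @return Data frame with one row per scenario x replicate x ordered pair:
#'   scenario, replicate, and the [rpc_pair()] columns.
#' @export
run_experiment <- function(config, progress = FALSE) {
  all_scen <- c("D", "EAA", "D_EAA", "EC")
  rows <- list()
  for (scen in config$scenarios) {
    for (r in seq_len(config$replicates)) {
      seed <- config$base_seed + r + 100000L * match(scen, all_scen)
      set.seed(seed)
      if (progress)
        message(sprintf("scenario %s replicate %d (seed %d)", scen, r, seed))
      res <- run_experiment_cell(config, scen)
      res <- cbind(scenario = scen, replicate = r, res,
                   stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

run_experiment_cell <- function(config, scenario) {
  genome <- sample_genome(config$n_chr, config$chr_length, config$loci_per_chr)
  pop0 <- run_history(genome, fast = config$fast_history,
                      expand = c(config$pop0_males, config$pop0_females),
                      mutation_rate = config$mutation_rate)
  genome <- designate_qtl(genome, pop0, config$n_qtl)
  arch <- sample_architecture(genome$qtl, scenario)
  sim <- run_lines(pop0, genome, arch, h2 = config$h2,
                   total_gens = config$total_gens,
                   branch_gens = config$branch_gens,
                   n_sires = config$n_sires, n_dams = config$n_dams,
                   litter_size = config$litter_size)
  lines <- sim$lines
  freqs <- lapply(lines, line_freqs, genome = genome)
  apb <- lapply(freqs, function(f) alpha_regression(arch, target_pb(f)))
  Hs <- lapply(names(lines), function(nm)
    center_genotypes(lines[[nm]], genome, freqs[[nm]]))
  names(Hs) <- names(lines)
  labs <- names(lines)
  out <- list()
  for (i in labs) for (j in labs) {
    if (i == j) next
    ac <- alpha_regression(arch, target_cb(freqs[[i]], freqs[[j]]))
    out[[paste(i, j)]] <- rpc_pair_core(Hs[[i]], freqs[[i]], apb[[i]], apb[[j]],
                                        ac, i, j)
  }
  do.call(rbind, out)
}

#' Summarize experiment results
#'
#' Per (scenario, line pair): minimum, mean and maximum realized r_pc across
#' replicates, and the fraction of rows violating the predicted bounds
#' (realized below the dominance-model predictor or above the A-by-A
#' predictor).
#'
#' @param results Output of [run_experiment()].
#' @param tol Numerical slack when counting bound violations.
#' @return Data frame keyed by scenario, line1, line2.
#' @export
summarize_experiment <- function(results, tol = 0) {
  if (!nrow(results)) stop("empty results table")
  key <- interaction(results$scenario, results$line1, results$line2, drop = TRUE)
  agg <- lapply(split(results, key), function(d) {
    data.frame(scenario = d$scenario[1], line1 = d$line1[1], line2 = d$line2[1],
               n = nrow(d),
               min_rpc = min(d$realized_rpc),
               mean_rpc = mean(d$realized_rpc),
               max_rpc = max(d$realized_rpc),
               frac_below_lower = mean(d$realized_rpc < d$pred_rpc_D - tol),
               frac_above_upper = mean(d$realized_rpc > d$pred_rpc_AA + tol),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$scenario, out$line1, out$line2), ]
}
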