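#' Select parents and produce the next cohort
#'
#' Truncation selection on own phenotype within each sex: the top
#' (`direction = "positive"`) or bottom (`"negative"`) `n_sires` males and
#' `n_dams` females are selected; `"random"` ignores phenotypes. Ties are
#' broken uniformly at random. Each selected dam is mated to one sire drawn
#' uniformly with replacement and produces a single litter of `litter_size`
#' offspring with equal sexes (mating of selected parents is at random).
#'
#' @param pop Current cohort (`qtl_pop`).
#' @param genome A `genome_map`.
#' @param n_sires,n_dams Numbers of selected male/female parents.
#' @param direction One of "positive", "negative", "random".
#' @param phenotypes Per-individual phenotype vector; required unless
#'   `direction = "random"`.
#' @param litter_size Offspring per mating (must be even; half each sex).
#' @param mutation_rate Per-locus, per-gamete mutation probability.
#' @param next_id First global pedigree id to assign to the offspring.
#' @return The offspring cohort (`qtl_pop`), generation incremented.
#' @export
advance_generation <- function(pop, genome, n_sires, n_dams,
                               direction = c("random", "positive", "negative"),
                               phenotypes = NULL, litter_size = 10,
                               mutation_rate = 0, next_id = max(pop$id) + 1L) {
  direction <- match.arg(direction)
  if (n_sires < 1 || n_dams < 1) stop("parent counts must be positive")
  if (litter_size %% 2 != 0) stop("litter_size must be even (equal sexes)")
  males <- which(pop$sex == 1L); females <- which(pop$sex == 2L)
  if (length(males) < n_sires || length(females) < n_dams)
    stop(sprintf("generation %d of line %s: need %d sires / %d dams but have %d males / %d females",
                 pop$generation, pop$line, n_sires, n_dams,
                 length(males), length(females)))
  sel <- function(cand) {
    if (direction == "random") return(sample(cand))
    if (is.null(phenotypes)) stop("phenotypes required for directional selection")
    tb <- runif(length(cand))  # uniform random tie-break
    cand[order(phenotypes[cand], tb, decreasing = (direction == "positive"))]
  }
  sires <- sel(males)[seq_len(n_sires)]
  dams  <- sel(females)[seq_len(n_dams)]
  mate_next(pop, genome, sires, dams, litter_size, mutation_rate, next_id)
}

# Mate given parent columns: one litter per dam, sire drawn with replacement.
mate_next <- function(pop, genome, sires, dams, litter_size, mutation_rate, next_id) {
  sire_of <- sires[sample.int(length(sires), length(dams), replace = TRUE)]
  pat_par <- rep(sire_of, each = litter_size)
  mat_par <- rep(dams,    each = litter_size)
  hap1 <- make_gametes(pop, pat_par, genome, mutation_rate)
  hap2 <- make_gametes(pop, mat_par, genome, mutation_rate)
  n <- length(mat_par)
  sex <- rep(rep(c(1L, 2L), each = litter_size / 2), length(dams))
  new_population(hap1, hap2, sex,
                 id = seq.int(next_id, length.out = n),
                 sire = pop$id[pat_par], dam = pop$id[mat_par],
                 generation = pop$generation + 1L, line = pop$line)
}

#' Historical population and expansion to generation 0
#'
#' Full mode reproduces the reference demography: random mating at
#' `n1 = (100 males, 600 females)` for `phase_gens[1]` generations, a linear
#' decline to `n2 = (50, 300)` over `phase_gens[2]` generations (sex counts
#' rounded to integers), `phase_gens[3]` generations at constant `n2`, and a
#' final expansion to `expand = (1500, 1500)` via litters of 10 per dam
#' mating. Recurrent mutation operates throughout the historical phase only;
#' the resulting generation-0 allele-frequency distribution is U-shaped.
#'
#' Fast mode skips the historical phase and draws generation-0 allele
#' frequencies from a U-shaped Beta(0.2, 0.2) with linkage-equilibrium
#' genotypes; a desk-scale approximation to the same generation-0 state (the
#' LD built up by the bottleneck is not reproduced).
#'
#' @param genome A `genome_map`.
#' @param fast Use the fast (Beta-frequency) mode.
#' @param phase_gens Lengths of the three historical phases (full mode).
#' @param n1,n2 `(males, females)` at the start and end of the decline.
#' @param expand `(males, females)` of the expanded generation 0.
#' @param mutation_rate Historical per-locus per-gamete mutation rate.
#' @param beta_shape Shape of the Beta(., .) used for fast-mode frequencies.
#' @return The generation-0 `qtl_pop` (line "HIST").
#' @export
run_history <- function(genome, fast = FALSE,
                        phase_gens = c(200L, 200L, 200L),
                        n1 = c(100L, 600L), n2 = c(50L, 300L),
                        expand = c(1500L, 1500L),
                        mutation_rate = 5e-5, beta_shape = 0.2) {
  if (fast) {
    freq <- rbeta(genome$n_loci, beta_shape, beta_shape)
    pop <- init_founders(genome, expand[1], expand[2], freq = freq)
    return(pop)
  }
  sched <- historical_schedule(phase_gens, n1, n2)
  pop <- init_founders(genome, sched$Nm[1], sched$Nf[1])
  nid <- pop_size(pop) + 1L
  for (t in 2:nrow(sched)) {
    pop <- random_union(pop, genome, sched$Nm[t], sched$Nf[t], mutation_rate, nid)
    nid <- nid + pop_size(pop)
  }
  # expansion: all final-generation individuals are parents, litters of 10
  males <- which(pop$sex == 1L); females <- which(pop$sex == 2L)
  litter <- (expand[1] + expand[2]) / length(females)
  pop <- mate_next(pop, genome, males, females, litter, 0, nid)
  pop
}

# Historical random mating at fixed census: each offspring gets a random sire
# and dam drawn with replacement (random union of gametes).
random_union <- function(pop, genome, n_males, n_females, mutation_rate, next_id) {
  males <- which(pop$sex == 1L); females <- which(pop$sex == 2L)
  n <- n_males + n_females
  pat <- males[sample.int(length(males), n, replace = TRUE)]
  mat <- females[sample.int(length(females), n, replace = TRUE)]
  hap1 <- make_gametes(pop, pat, genome, mutation_rate)
  hap2 <- make_gametes(pop, mat, genome, mutation_rate)
  new_population(hap1, hap2,
                 sex = rep(c(1L, 2L), c(n_males, n_females)),
                 id = seq.int(next_id, length.out = n),
                 sire = pop$id[pat], dam = pop$id[mat],
                 generation = pop$generation + 1L, line = pop$line)
}

#' Per-generation census of the historical demography
#'
#' @inheritParams run_history
#' @return Data frame with columns `Nm`, `Nf`, one row per historical
#'   generation (600 rows for the reference schedule).
#' @export
historical_schedule <- function(phase_gens = c(200L, 200L, 200L),
                                n1 = c(100L, 600L), n2 = c(50L, 300L)) {
  t <- seq_len(phase_gens[2])
  Nm <- c(rep(n1[1], phase_gens[1]),
          round(n1[1] + (n2[1] - n1[1]) * t / phase_gens[2]),
          rep(n2[1], phase_gens[3]))
  Nf <- c(rep(n1[2], phase_gens[1]),
          round(n1[2] + (n2[2] - n1[2]) * t / phase_gens[2]),
          rep(n2[2], phase_gens[3]))
  data.frame(Nm = as.integer(Nm), Nf = as.integer(Nf))
}

#' Harmonic-mean effective size of a demographic schedule
#'
#' Per generation `Ne_t = 4 Nm Nf / (Nm + Nf)`; the schedule's effective size
#' is the harmonic mean of `Ne_t`. The reference historical schedule gives
#' about 234.
#'
#' @param schedule Data frame with columns `Nm`, `Nf` (one row per
#'   generation), as returned by [historical_schedule()].
#' @return Harmonic mean effective size.
#' @export
ne_harmonic <- function(schedule) {
  Nm <- schedule$Nm; Nf <- schedule$Nf
  if (any(Nm <= 0) || any(Nf <= 0)) stop("sex counts must be positive")
  ne <- 4 * Nm * Nf / (Nm + Nf)
  length(ne) / sum(1 / ne)
}

#' Simulate one selected breeding line
#'
#' Founds a line by sampling `n_sires` males and `n_dams` females without
#' replacement from `source` (random founding, as when lines branch), then
#' runs `n_gen` rounds of mating. The founders mate at random; every later
#' cohort is truncation-selected on own phenotype (genotypic value plus a
#' normal deviate with variance `Ve`) before mating.
#'
#' @param source Cohort to found the line from.
#' @param genome A `genome_map` with designated QTL.
#' @param arch A `trait_architecture` providing genotypic values.
#' @param n_gen Number of offspring cohorts to produce.
#' @param direction Selection direction for the post-founding generations.
#' @param Ve Environmental variance (see [calibrate_ve()]).
#' @param n_sires,n_dams Selected parent counts per generation.
#' @param litter_size Offspring per mating.
#' @param line Line label.
#' @param snapshot_gens Absolute generation numbers whose full cohorts are
#'   returned (used for branching).
#' @param next_id First pedigree id for new individuals.
#' @return List with `final` (last cohort), `snapshots` (named list of
#'   cohorts), `pedigree` (rows for all new individuals) and `log`
#'   (per-generation line, generation, mean genotypic value, mean phenotype).
#' @export
simulate_line <- function(source, genome, arch, n_gen, direction, Ve,
                          n_sires = 50, n_dams = 300, litter_size = 10,
                          line = "L", snapshot_gens = integer(),
                          next_id = max(source$id) + 1L) {
  males <- which(source$sex == 1L); females <- which(source$sex == 2L)
  if (length(males) < n_sires || length(females) < n_dams)
    stop("source cohort too small to found line ", line)
  keep <- c(sample(males, n_sires), sample(females, n_dams))
  pop <- new_population(source$hap1[, keep, drop = FALSE],
                        source$hap2[, keep, drop = FALSE],
                        source$sex[keep], source$id[keep],
                        source$sire[keep], source$dam[keep],
                        source$generation, line)
  ped <- list(); logs <- list(); snaps <- list(); ph <- NULL
  for (g in seq_len(n_gen)) {
    if (g == 1L) {
      pop <- mate_next(pop, genome, seq_len(n_sires), n_sires + seq_len(n_dams),
                       litter_size, 0, next_id)
    } else {
      pop <- advance_generation(pop, genome, n_sires, n_dams, direction,
                                phenotypes = ph, litter_size = litter_size,
                                next_id = next_id)
    }
    next_id <- next_id + pop_size(pop)
    ped[[g]] <- pop_pedigree(pop)
    # own-performance records of the new cohort (used to select its parents-to-be)
    G <- genotypic_value(qtl_geno(pop, genome), arch)
    ph <- G + rnorm(length(G), 0, sqrt(Ve))
    logs[[g]] <- data.frame(line = line, generation = pop$generation,
                            mean_g = mean(G), mean_pheno = mean(ph))
    if (pop$generation %in% snapshot_gens)
      snaps[[as.character(pop$generation)]] <- pop
  }
  list(final = pop, snapshots = snaps,
       pedigree = do.call(rbind, ped), log = do.call(rbind, logs),
       next_id = next_id)
}

#' Simulate the seven selected breeding lines
#'
#' Reproduces the reference line structure: from the expanded generation-0
#' cohort, lines P (positive), N (negative) and R (random selection) are
#' founded and run for `total_gens` generations; at `branch_gens[2]` and
#' `branch_gens[3]` new positive/negative pairs branch off line R and run for
#' the remaining generations. With the defaults this yields P50/N50/R (50
#' generations), P25/N25 (branched at 25) and P10/N10 (branched at 40), all
#' ending at generation `total_gens`.
#'
#' The environmental variance is calibrated once from the genotypic variance
#' of the generation-0 cohort so that `Var(G)/Var(P) = h2`, and is held fixed
#' for all lines and generations.
#'
#' @param pop0 Expanded generation-0 cohort.
#' @param genome A `genome_map` with designated QTL.
#' @param arch A `trait_architecture`.
#' @param h2 Broad-sense heritability of the phenotype.
#' @param total_gens Generations from founding to the final cohort.
#' @param branch_gens Absolute generations at which the three divergent pairs
#'   are founded (first entry must be 0 = founding from `pop0`).
#' @param n_sires,n_dams,litter_size Selection and litter parameters.
#' @return List with `lines` (named list of seven final cohorts), `pedigree`
#'   (all individuals incl. `pop0`), `log`, and `Ve`.
#' @export
run_lines <- function(pop0, genome, arch, h2 = 0.3,
                      total_gens = 50L, branch_gens = c(0L, 25L, 40L),
                      n_sires = 50, n_dams = 300, litter_size = 10) {
  if (branch_gens[1] != 0L || is.unsorted(branch_gens, strictly = TRUE) ||
      any(branch_gens >= total_gens))
    stop("branch generations must be strictly increasing, start at 0 and precede the final generation")
  G0 <- genotypic_value(qtl_geno(pop0, genome), arch)
  Ve <- calibrate_ve(G0, h2)
  nid <- max(pop0$id) + 1L
  lab <- function(pfx, g) paste0(pfx, total_gens - g)

  runs <- list()
  R <- simulate_line(pop0, genome, arch, total_gens, "random", Ve,
                     n_sires, n_dams, litter_size, line = "R",
                     snapshot_gens = branch_gens[-1], next_id = nid)
  nid <- R$next_id
  runs$R <- R
  sources <- c(list(pop0), R$snapshots[as.character(branch_gens[-1])])
  for (b in seq_along(branch_gens)) {
    src <- sources[[b]]
    ngen <- total_gens - branch_gens[b]
    for (dir in c("positive", "negative")) {
      nm <- paste0(if (dir == "positive") "P" else "N", ngen)
      run <- simulate_line(src, genome, arch, ngen, dir, Ve,
                           n_sires, n_dams, litter_size, line = nm,
                           next_id = nid)
      nid <- run$next_id
      runs[[nm]] <- run
    }
  }
  order_labs <- c(paste0(c("P", "N"), total_gens), "R",
                  paste0(c("P", "N"), total_gens - branch_gens[2]),
                  paste0(c("P", "N"), total_gens - branch_gens[3]))
  lines <- lapply(runs, `[[`, "final")[order_labs]
  ped <- rbind(pop_pedigree(pop0), do.call(rbind, lapply(runs, `[[`, "pedigree")))
  rownames(ped) <- NULL
  list(lines = lines, pedigree = ped,
       log = do.call(rbind, lapply(runs, `[[`, "log")), Ve = Ve)
}

#' Pedigree inbreeding, inbreeding rate and effective size
#'
#' Computes per-individual inbreeding coefficients F by the tabular
#' (recursive kinship) method, blocked by generation: the kinship matrix is
#' carried forward among the individuals that actually become parents, so the
#' method is exact while scaling to deep multi-thousand-individual
#' pedigrees. Every non-founder's parents must belong to the previous
#' generation (the simulator guarantees this; violated pedigrees are
#' rejected). The inbreeding rate is estimated from the regression of
#' `log(1 - mean F_t)` on generation, and `Ne = 1/(2 dF)`.
#'
#' @param ped Data frame with columns `id`, `sire`, `dam` (0 = unknown) and
#'   `generation`.
#' @return An `inbreeding_summary`: `F` (per individual, in pedigree order),
#'   `mean_F` (named per-generation means), `delta_F`, `ne`.
#' @export
pedigree_inbreeding <- function(ped) {
  stopifnot(all(c("id", "sire", "dam", "generation") %in% names(ped)))
  if (anyDuplicated(ped$id)) stop("duplicated ids in pedigree")
  n <- nrow(ped)
  idx <- match(ped$sire, ped$id)  # NA for founders (sire = 0)
  idy <- match(ped$dam, ped$id)
  if (any(is.na(idx) & ped$sire != 0) || any(is.na(idy) & ped$dam != 0))
    stop("parent ids missing from pedigree")
  gens <- sort(unique(ped$generation))
  F <- numeric(n)
  rows_g <- split(seq_len(n), ped$generation)
  # check parents are exactly one generation back (founders exempt)
  for (g in gens) {
    r <- rows_g[[as.character(g)]]
    pg <- c(idx[r], idy[r]); pg <- pg[!is.na(pg)]
    if (length(pg) && any(ped$generation[pg] != g - 1))
      stop("pedigree not generation-ordered (cycles or skipped generations)")
  }
  K <- NULL; K_ids <- integer()  # kinship among previous generation's members that matter
  for (gi in seq_along(gens)) {
    r <- rows_g[[as.character(gens[gi])]]
    s <- idx[r]; d <- idy[r]
    if (gi > 1L) {
      si <- match(ped$id[s], K_ids); di <- match(ped$id[d], K_ids)
      f <- numeric(length(r))
      known <- !is.na(si) & !is.na(di)
      f[known] <- K[cbind(si[known], di[known])]
      F[r] <- f
    }
    # kinship among this generation's cohort (needed as next generation's parents)
    nxt <- if (gi < length(gens)) rows_g[[as.character(gens[gi + 1])]] else integer()
    par_next <- unique(c(idx[nxt], idy[nxt])); par_next <- par_next[!is.na(par_next)]
    keep <- intersect(r, par_next)
    if (length(keep)) {
      si <- match(ped$id[idx[keep]], K_ids); di <- match(ped$id[idy[keep]], K_ids)
      m <- length(keep)
      Knew <- matrix(0, m, m)
      if (!is.null(K)) {
        ok <- which(!is.na(si) & !is.na(di))
        if (length(ok)) {
          Knew[ok, ok] <- 0.25 * (K[si[ok], si[ok], drop = FALSE] +
                                  K[si[ok], di[ok], drop = FALSE] +
                                  K[di[ok], si[ok], drop = FALSE] +
                                  K[di[ok], di[ok], drop = FALSE])
        }
      }
      diag(Knew) <- 0.5 * (1 + F[keep])
      K <- Knew; K_ids <- ped$id[keep]
    } else {
      K <- NULL; K_ids <- integer()
    }
  }
  mean_F <- vapply(rows_g, function(r) mean(F[r]), numeric(1))
  names(mean_F) <- names(rows_g)
  dF <- delta_f_from_means(as.integer(names(mean_F)), mean_F)
  structure(list(F = F, mean_F = mean_F, delta_F = dF,
                 ne = if (!is.na(dF) && dF > 0) 1 / (2 * dF) else NA_real_),
            class = "inbreeding_summary")
}

# dF from regression of log(1 - mean F) on generation: slope = log(1 - dF).
delta_f_from_means <- function(gen, meanF) {
  ok <- meanF < 1
  if (sum(ok) < 2) return(NA_real_)
  slope <- coef(lm(log(1 - meanF[ok]) ~ gen[ok]))[[2]]
  1 - exp(slope)
}

#' @export
print.inbreeding_summary <- function(x, ...) {
  cat(sprintf("inbreeding_summary: %d individuals, %d generations\n",
              length(x$F), length(x$mean_F)))
  cat(sprintf("  final mean F = %.4f, delta F = %.4f%%/gen, Ne = %.1f\n",
              x$mean_F[length(x$mean_F)], 100 * x$delta_F, x$ne))
  invisible(x)
}
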