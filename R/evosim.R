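#' Configuration for the experimental-evolution simulator
#'
#' Parameters of the individual-based null model of nuclear-mutation-driven
#' adaptation: a haploid, isogenic population is expanded from `N` cells
#' through asynchronous cell divisions until it reaches `2^M_t * N` cells,
#' then bottlenecked back to `N` cells, for `n_cycles` cycles. Every
#' division can add chromosome duplications and point mutations whose
#' doubling-time effects act under diminishing-returns epistasis (see
#' [apply_mutation_effect()]), and every cell dies after `max_divisions`
#' divisions (yeast replicative aging); aged-out cells stop dividing but
#' remain in the population and can pass the bottleneck.
#'
#' The default population scale (`N = 5000`, `n_replicates = 48`) is a
#' desk-scale rendering of the study design; the full scale (bottlenecks of
#' ~50,000 cells, 1152 replicates) is reachable through these fields.
#'
#' @param N Bottleneck population size (default 5000).
#' @param M_t Generations (population doublings) per growth cycle: a
#'   scalar, or a vector of length `n_cycles` (default 5).
#' @param n_cycles Number of serial growth cycles (default 50).
#' @param mu_dup Chromosome duplications per cell division (default
#'   4.85e-5).
#' @param mu_snp Point mutations per bp per division (default 0.33e-9).
#' @param genome_bp Nuclear genome size in bp (default 12e6).
#' @param max_divisions Divisions before a cell stops dividing (default
#'   12).
#' @param D_founder_nostress_h Founder doubling time without stress, hours
#'   (default 1.55); the physiological floor.
#' @param D_founder_stress_h Founder doubling time under stress, hours
#'   (default 308/60).
#' @param n_replicates Independent replicate populations (default 48).
#' @param epistasis `"log2"` (default) reads a mutation's effect size as
#'   the log2 fold-change of the founder's stressed doubling time;
#'   `"absolute"` reads it as the mutant's absolute doubling time in hours.
#' @param mutate_both If `TRUE`, mutation draws apply to both post-division
#'   cells instead of the daughter only (default `FALSE`).
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(N = 5000L, M_t = 5, n_cycles = 50L,
                       mu_dup = 4.85e-5, mu_snp = 0.33e-9,
                       genome_bp = 12e6, max_divisions = 12L,
                       D_founder_nostress_h = 1.55,
                       D_founder_stress_h = 308 / 60,
                       n_replicates = 48L,
                       epistasis = c("log2", "absolute"),
                       mutate_both = FALSE, seed = 1L) {
  epistasis <- match.arg(epistasis)
  stopifnot(N >= 1L, n_cycles >= 1L, mu_dup >= 0, mu_snp >= 0,
            genome_bp > 0, max_divisions >= 1L,
            D_founder_stress_h > D_founder_nostress_h,
            D_founder_nostress_h > 0, n_replicates >= 1L,
            all(M_t > 0), length(M_t) %in% c(1L, n_cycles))
  if (length(M_t) == 1L) M_t <- rep(M_t, n_cycles)
  structure(as.list(environment())[names(formals(sim_config))],
            class = "sim_config")
}

#' Diminishing-returns epistasis on cell doubling time
#'
#' Computes the post-mutation doubling time `D_m` from the genotype's
#' current doubling time `D_G` and the mutation's no-epistasis effect size
#' `D_r`:
#' \deqn{k = \max\left(\frac{2^{D_r} D_{fs} - D_{fn}}{D_{fs} - D_{fn}},\; 0\right),
#'   \qquad D_m = k \, (D_G - D_{fn}) + D_{fn},}
#' where `D_fs` and `D_fn` are the founder's stressed and unstressed
#' doubling times. `D_r` is the log2 fold-change the mutation alone confers
#' on the founder's stressed doubling time (so `D_r = 0` is neutral and
#' `k = 1`). The result is floored at `D_fn`: the doubling time under
#' stress can never drop below the founder's unstressed doubling time.
#' Because each mutation multiplies the remaining gap to the floor by its
#' own factor `k`, benefits diminish as the genotype approaches the floor.
#'
#' With `mode = "absolute"`, `D_r` is instead read as the absolute doubling
#' time (hours) the mutation alone would confer on the founder, replacing
#' `2^{D_r} D_{fs}` in the numerator.
#'
#' @param D_G Doubling time(s) of the genotype before the mutation, hours.
#' @param D_r Effect size(s) of the mutation (log2 fold-change, or hours
#'   when `mode = "absolute"`).
#' @param D_founder_stress_h,D_founder_nostress_h Founder phenotypes,
#'   hours; the stressed value must exceed the unstressed one.
#' @param mode Effect-size convention, `"log2"` (default) or `"absolute"`.
#' @return Post-mutation doubling time(s), hours.
#' @examples
#' apply_mutation_effect(5, 0, 308 / 60, 1.55)    # neutral: unchanged
#' apply_mutation_effect(5, -0.2, 308 / 60, 1.55) # beneficial
#' @export
apply_mutation_effect <- function(D_G, D_r, D_founder_stress_h,
                                  D_founder_nostress_h,
                                  mode = c("log2", "absolute")) {
  mode <- match.arg(mode)
  if (D_founder_stress_h <= D_founder_nostress_h ||
      D_founder_nostress_h <= 0) {
    stop("founder phenotypes degenerate: need D_stress > D_nostress > 0")
  }
  stopifnot(all(D_G >= D_founder_nostress_h))
  D_abs <- if (mode == "log2") 2^D_r * D_founder_stress_h else D_r
  k <- pmax((D_abs - D_founder_nostress_h) /
              (D_founder_stress_h - D_founder_nostress_h), 0)
  pmax(k * (D_G - D_founder_nostress_h) + D_founder_nostress_h,
       D_founder_nostress_h)
}

#' Create a homogeneous founder population
#'
#' @param N Number of cells.
#' @param D_h Division time of every cell, hours.
#' @return A list of class `sim_population` with per-cell fields
#'   `division_time_h`, `divisions_used`, `genes` (list of mutated gene
#'   indices), `chrom_mask` (bitmask of duplicated chromosomes),
#'   `neutral` (neutral point-mutation counts).
#' @export
new_population <- function(N, D_h) {
  stopifnot(N >= 1L, D_h > 0)
  structure(list(division_time_h = rep(D_h, N),
                 divisions_used = integer(N),
                 genes = rep(list(integer(0)), N),
                 chrom_mask = integer(N),
                 neutral = integer(N)),
            class = "sim_population")
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf("Population of %d cells; mean division time %.3f h; %d carry mutations\n",
              length(x$division_time_h), mean(x$division_time_h),
              sum(lengths(x$genes) > 0 | x$chrom_mask > 0)))
  invisible(x)
}

# Internal: flatten an effect table into the vectors the compiled core uses.
prepare_effects <- function(effect_table, config) {
  Dfs <- config$D_founder_stress_h
  if (is.null(effect_table)) {
    return(list(cum_effectual = numeric(0), total_effectual = 0,
                gene_dr = numeric(0), chrom_dr = rep(0, 16L),
                gene_names = character(0), chrom_names = paste0("chr", 1:16)))
  }
  stopifnot(inherits(effect_table, "effect_table"))
  g <- effect_table$genes
  ch <- effect_table$chroms
  list(cum_effectual = cumsum(as.numeric(g$effectual_sites)),
       total_effectual = sum(as.numeric(g$effectual_sites)),
       gene_dr = log2(g$D_stress_h / Dfs),
       chrom_dr = log2(ch$D_stress_h / Dfs),
       gene_names = g$gene, chrom_names = ch$chrom)
}

#' Run one serial growth cycle
#'
#' Expands a population through asynchronous divisions on an event queue
#' (each cell divides every `division_time_h` hours; ties resolved by
#' insertion order) until it reaches `round(2^M_t * N)` cells, drawing
#' mutations for each newborn daughter, then samples `N` cells uniformly
#' without replacement as the next cycle's founders. If every cell reaches
#' `max_divisions` before the cap, the cycle ends early and is flagged
#' extinct.
#'
#' Uses R's global random number generator; call `set.seed()` for
#' reproducibility.
#'
#' @param population A `sim_population` (see [new_population()]).
#' @param M_t Generations for this cycle (> 0).
#' @param config A [sim_config()].
#' @param effect_table An `effect_table` from [gen_effect_tables()], or
#'   `NULL` for all-neutral mutations.
#' @return A list of class `sim_cycle`: `population` (the sampled
#'   survivors), `pop_size_at_halt`, `mean_D_at_halt`, `mean_D_sampled`,
#'   `extinct`, `t_final_h`.
#' @export
run_cycle <- function(population, M_t, config, effect_table = NULL) {
  stopifnot(inherits(population, "sim_population"), M_t > 0,
            inherits(config, "sim_config"))
  fx <- prepare_effects(effect_table, config)
  res <- run_cycle_cpp(
    population$division_time_h, population$divisions_used,
    population$genes, population$chrom_mask, population$neutral,
    M_t, config$max_divisions,
    config$mu_snp * config$genome_bp, config$mu_dup,
    fx$total_effectual, config$genome_bp,
    fx$cum_effectual, fx$gene_dr, fx$chrom_dr,
    config$D_founder_stress_h, config$D_founder_nostress_h,
    as.integer(config$N),
    config$epistasis == "log2", config$mutate_both)
  pop <- structure(list(division_time_h = res$division_time_h,
                        divisions_used = res$divisions_used,
                        genes = res$genes,
                        chrom_mask = res$chrom_mask,
                        neutral = res$neutral),
                   class = "sim_population")
  structure(list(population = pop,
                 pop_size_at_halt = res$pop_size_at_halt,
                 mean_D_at_halt = res$mean_D_at_halt,
                 mean_D_sampled = mean(res$division_time_h),
                 extinct = res$extinct,
                 t_final_h = res$t_final_h),
            class = "sim_cycle")
}

#' Draw the mutations acquired at one cell division
#'
#' The per-division mutation model: the number of point mutations is
#' Poisson with mean `mu_snp * genome_bp`; each hit lands on an effectual
#' site of gene `g` with probability `effectual_sites_g / genome_bp`
#' (otherwise it is neutral, `D_r = 0`); independently, a chromosome
#' duplication occurs with probability `mu_dup` on a uniformly chosen
#' not-yet-duplicated chromosome. Genes already mutated and chromosomes
#' already duplicated in the lineage are excluded.
#'
#' This is the reference R implementation of the draw; [run_cycle()]
#' performs the identical draw in compiled code.
#'
#' @param cell A list with elements `genes` (integer vector of 1-based
#'   mutated gene indices) and `chrom_mask` (duplicated-chromosome
#'   bitmask); e.g. one cell of a `sim_population`.
#' @param config A [sim_config()].
#' @param effect_table An `effect_table`, or `NULL` for a genome with no
#'   effectual sites.
#' @return A list of mutation events, each a list with `kind`
#'   (`"point"` or `"duplication"`), `target` (gene or chromosome name, or
#'   `NA` for neutral hits), `D_r` (log2 effect size) and `effectual`.
#' @export
draw_mutations <- function(cell, config, effect_table = NULL) {
  stopifnot(inherits(config, "sim_config"))
  fx <- prepare_effects(effect_table, config)
  events <- list()
  npm <- stats::rpois(1L, config$mu_snp * config$genome_bp)
  mutated <- cell$genes
  for (i in seq_len(npm)) {
    u <- stats::runif(1L, 0, config$genome_bp)
    if (u < fx$total_effectual) {
      g <- findInterval(u, fx$cum_effectual, left.open = TRUE) + 1L
      if (!(g %in% mutated)) {
        mutated <- c(mutated, g)
        events[[length(events) + 1L]] <- list(
          kind = "point", target = fx$gene_names[g],
          D_r = fx$gene_dr[g], effectual = TRUE)
        next
      }
    }
    events[[length(events) + 1L]] <- list(kind = "point", target = NA,
                                          D_r = 0, effectual = FALSE)
  }
  if (stats::runif(1L) < config$mu_dup) {
    bits <- bitwAnd(bitwShiftR(cell$chrom_mask,
                               0:(length(fx$chrom_dr) - 1L)), 1L)
    avail <- which(bits == 0L)
    if (length(avail) > 0L) {
      j <- avail[sample.int(length(avail), 1L)]
      events[[length(events) + 1L]] <- list(
        kind = "duplication", target = fx$chrom_names[j],
        D_r = fx$chrom_dr[j], effectual = TRUE)
    }
  }
  events
}

#' Run a replicated evolution experiment
#'
#' Runs `n_replicates` independent populations for `n_cycles` serial
#' growth cycles each, recording the mean division time of the sampled
#' bottleneck population after every cycle on a cumulative-generations
#' axis.
#'
#' @param config A [sim_config()].
#' @param effect_table An `effect_table` from [gen_effect_tables()], or
#'   `NULL` for all-neutral mutations.
#' @return A list of class `sim_result`: `trajectory` (tibble `replicate`,
#'   `cycle`, `generation`, `mean_D_h`, `mean_D_at_halt_h`,
#'   `frac_mutated`, `extinct`), `config`, and `final_populations` (list
#'   of `sim_population`, one per replicate).
#' @export
run_experiment <- function(config, effect_table = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gen_axis <- cumsum(config$M_t)
  rows <- vector("list", config$n_replicates)
  finals <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    pop <- new_population(config$N, config$D_founder_stress_h)
    rec <- vector("list", config$n_cycles)
    for (cy in seq_len(config$n_cycles)) {
      res <- run_cycle(pop, config$M_t[cy], config, effect_table)
      pop <- res$population
      rec[[cy]] <- tibble::tibble(
        replicate = r, cycle = cy, generation = gen_axis[cy],
        mean_D_h = res$mean_D_sampled,
        mean_D_at_halt_h = res$mean_D_at_halt,
        frac_mutated = mean(lengths(pop$genes) > 0 | pop$chrom_mask > 0),
        extinct = res$extinct)
    }
    rows[[r]] <- dplyr::bind_rows(rec)
    finals[[r]] <- pop
  }
  structure(list(trajectory = dplyr::bind_rows(rows), config = config,
                 final_populations = finals),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  last <- dplyr::filter(x$trajectory, .data$cycle == max(.data$cycle))
  cat(sprintf(
    "Simulation: %d replicates x %d cycles; final mean division time %.3f h (founder %.3f h)\n",
    x$config$n_replicates, x$config$n_cycles, mean(last$mean_D_h),
    x$config$D_founder_stress_h))
  invisible(x)
}

#' Summarize simulated adaptation trajectories
#'
#' Collapses a `sim_result` across replicates into per-cycle means and
#' standard errors of (i) the log2 fold reduction in cell doubling time
#' relative to the initial stressed phenotype and (ii) the percent of the
#' maximum possible reduction realized (see [percent_max_adaptation()]).
#'
#' @param result A `sim_result` from [run_experiment()].
#' @param D_floor_h Physiological floor, hours; defaults to the config's
#'   unstressed founder phenotype.
#' @param D_init_h Initial stressed phenotype, hours; defaults to the
#'   config's stressed founder phenotype.
#' @return A tibble `cycle`, `generation`, `mean_D_h`, `sem_D_h`,
#'   `log2_fold_reduction`, `sem_log2_fold_reduction`, `percent_of_max`,
#'   `sem_percent_of_max`. Standard errors are `NA` for a single
#'   replicate.
#' @export
summarize_trajectory <- function(result,
                                 D_floor_h = result$config$D_founder_nostress_h,
                                 D_init_h = result$config$D_founder_stress_h) {
  stopifnot(inherits(result, "sim_result"), nrow(result$trajectory) > 0)
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  result$trajectory |>
    dplyr::mutate(
      lfr = log2(D_init_h / .data$mean_D_h),
      pmax_ = 100 * (D_init_h - .data$mean_D_h) / (D_init_h - D_floor_h)) |>
    dplyr::group_by(.data$cycle, .data$generation) |>
    dplyr::summarise(
      sem_D_h = sem(.data$mean_D_h),
      sem_log2_fold_reduction = sem(.data$lfr),
      sem_percent_of_max = sem(.data$pmax_),
      mean_D_h = mean(.data$mean_D_h),
      log2_fold_reduction = mean(.data$lfr),
      percent_of_max = mean(.data$pmax_),
      .groups = "drop") |>
    dplyr::select("cycle", "generation", "mean_D_h", "sem_D_h",
                  "log2_fold_reduction", "sem_log2_fold_reduction",
                  "percent_of_max", "sem_percent_of_max")
}
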