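founder_cfg <- function(...) {
  sim_config(D_founder_nostress_h = 1.55, D_founder_stress_h = 308 / 60, ...)
}

test_that("diminishing-returns epistasis has its fixed points and floor", {
  Dfs <- 308 / 60; Dfn <- 1.55
  # neutral mutation (no change to the founder's stressed phenotype)
  expect_equal(apply_mutation_effect(4.2, 0, Dfs, Dfn), 4.2)
  # a mutation that alone reaches the floor collapses the whole gap
  Dr_floor <- log2(Dfn / Dfs)
  expect_equal(apply_mutation_effect(4.2, Dr_floor, Dfs, Dfn), Dfn)
  # stronger-than-floor effects are truncated by k = 0
  expect_equal(apply_mutation_effect(4.2, Dr_floor - 1, Dfs, Dfn), Dfn)
  # floor holds for any mutation sequence
  set.seed(1)
  for (i in 1:200) {
    D <- Dfs
    for (Dr in stats::rnorm(5, 0, 0.4)) {
      D <- apply_mutation_effect(D, Dr, Dfs, Dfn)
      expect_gte(D, Dfn)
    }
  }
  expect_error(apply_mutation_effect(2, 0, 1.55, 1.55), "degenerate")
})

test_that("sequential mutations multiply their epistasis factors", {
  Dfs <- 308 / 60; Dfn <- 1.55
  k_of <- function(Dr) max((2^Dr * Dfs - Dfn) / (Dfs - Dfn), 0)
  set.seed(7)
  for (i in 1:50) {
    Dr1 <- stats::rnorm(1, 0, 0.2); Dr2 <- stats::rnorm(1, 0, 0.2)
    D0 <- stats::runif(1, Dfn + 0.1, 2 * Dfs)
    D12 <- apply_mutation_effect(
      apply_mutation_effect(D0, Dr1, Dfs, Dfn), Dr2, Dfs, Dfn)
    gap_expected <- k_of(Dr1) * k_of(Dr2) * (D0 - Dfn)
    expect_equal(D12 - Dfn, gap_expected, tolerance = 1e-12)
  }
})

test_that("absolute-effect convention matches the log2 convention", {
  Dfs <- 308 / 60; Dfn <- 1.55
  Dr <- -0.3
  expect_equal(apply_mutation_effect(4, Dr, Dfs, Dfn, mode = "log2"),
               apply_mutation_effect(4, 2^Dr * Dfs, Dfs, Dfn,
                                     mode = "absolute"))
})

test_that("mutation draws respect rates and exclusion bookkeeping", {
  fx <- gen_effect_tables(synth_effect_config(seed = 2L))
  cell <- list(genes = integer(0), chrom_mask = 0L)
  cfg0 <- founder_cfg(mu_snp = 0, mu_dup = 0)
  set.seed(1)
  expect_length(draw_mutations(cell, cfg0, fx), 0L)
  # all chromosomes already duplicated: no duplication can occur
  cfg_dup <- founder_cfg(mu_snp = 0, mu_dup = 1)
  full <- list(genes = integer(0), chrom_mask = as.integer(2^16 - 1))
  set.seed(1)
  expect_length(draw_mutations(full, cfg_dup, fx), 0L)
  set.seed(2)
  ev <- draw_mutations(cell, cfg_dup, fx)
  expect_identical(ev[[1]]$kind, "duplication")
  # Poisson mean of point mutations: mu_snp * genome_bp = 3.96e-3
  cfg <- founder_cfg()
  expect_equal(cfg$mu_snp * cfg$genome_bp, 3.96e-3)
  set.seed(3)
  n_events <- vapply(1:20000, function(i) {
    length(Filter(function(e) e$kind == "point",
                  draw_mutations(cell, founder_cfg(mu_dup = 0), fx)))
  }, numeric(1))
  se <- stats::sd(n_events) / sqrt(length(n_events))
  expect_lt(abs(mean(n_events) - 3.96e-3), 3 * se + 1e-6)
})

test_that("a mutation-free cycle reaches the exact cap and changes nothing", {
  cfg <- founder_cfg(N = 4L, mu_snp = 0, mu_dup = 0)
  pop <- new_population(4L, cfg$D_founder_stress_h)
  set.seed(1)
  res <- run_cycle(pop, M_t = 2, cfg)
  expect_equal(res$pop_size_at_halt, 16)       # 2^2 * 4
  expect_false(res$extinct)
  expect_equal(unique(res$population$division_time_h),
               cfg$D_founder_stress_h)
  expect_equal(res$mean_D_at_halt, cfg$D_founder_stress_h)
})

test_that("replicative aging caps divisions and can extinguish a cycle", {
  cfg <- founder_cfg(N = 4L, mu_snp = 0, mu_dup = 0, max_divisions = 2L)
  pop <- new_population(4L, cfg$D_founder_stress_h)
  set.seed(1)
  # mothers stop at 2 divisions but their daughters keep the cycle going
  res <- run_cycle(pop, M_t = 5, cfg)
  expect_false(res$extinct)
  expect_true(all(res$population$divisions_used <= 2L))
  # a population already at the age limit cannot divide at all
  aged <- new_population(4L, cfg$D_founder_stress_h)
  aged$divisions_used <- rep(2L, 4L)
  res2 <- run_cycle(aged, M_t = 5, cfg)
  expect_true(res2$extinct)
  expect_equal(res2$pop_size_at_halt, 4)
})

test_that("a faster subclone outgrows the founder as fast as deterministic doubling predicts", {
  cfg <- founder_cfg(N = 1000L, mu_snp = 0, mu_dup = 0,
                     max_divisions = 1000L)
  pop <- new_population(1000L, 1.7)
  pop$division_time_h[1:100] <- 1.0           # 10% fast subclone
  set.seed(5)
  res <- run_cycle(pop, M_t = 4, cfg)
  frac_fast <- mean(res$population$division_time_h < 1.5)
  g <- two_type_growth_oracle(100, 900, 1.0, 1.7, 16000)
  expected <- g[["n1"]] / 16000
  expect_gt(frac_fast, 100 / 1000)            # enrichment happened
  expect_equal(frac_fast, expected, tolerance = 0.15)
})

test_that("no gene or chromosome is mutated twice within a lineage", {
  fx <- gen_effect_tables(synth_effect_config(n_genes = 50L,
                                              effectual_sites_mean = 100,
                                              seed = 4L))
  # absurdly high rates force repeated hits on a tiny genome
  cfg <- founder_cfg(N = 50L, mu_snp = 2e-5, mu_dup = 0.3,
                     genome_bp = 10000, n_cycles = 3L)
  pop <- new_population(50L, cfg$D_founder_stress_h)
  set.seed(6)
  for (cy in 1:3) {
    res <- run_cycle(pop, M_t = 3, cfg, fx)
    pop <- res$population
  }
  expect_true(all(vapply(pop$genes, anyDuplicated, integer(1)) == 0L))
  expect_gt(mean(lengths(pop$genes) > 0 | pop$chrom_mask > 0), 0)
})

test_that("the doubling-time floor is never violated during selection", {
  # every gene strongly beneficial: pressure straight toward the floor
  fx <- gen_effect_tables(synth_effect_config(
    n_genes = 100L, fraction_beneficial_in_stress = 1,
    benefit_mean_min = 200, max_benefit_min = 215, seed = 8L))
  cfg <- founder_cfg(N = 200L, mu_snp = 1e-6, mu_dup = 1e-3,
                     genome_bp = 1e6)
  pop <- new_population(200L, cfg$D_founder_stress_h)
  set.seed(9)
  for (cy in 1:4) {
    res <- run_cycle(pop, M_t = 4, cfg, fx)
    pop <- res$population
    expect_gte(min(pop$division_time_h), cfg$D_founder_nostress_h - 1e-12)
  }
  expect_lt(mean(pop$division_time_h), cfg$D_founder_stress_h)
})

test_that("neutral mutations leave the mean division time flat", {
  fx <- gen_effect_tables(synth_effect_config(seed = 2L))
  fx$genes$D_stress_h <- rep(308 / 60, nrow(fx$genes))   # all D_r = 0
  fx$chroms$D_stress_h <- rep(308 / 60, nrow(fx$chroms))
  cfg <- founder_cfg(N = 200L, n_cycles = 50L, n_replicates = 48L,
                     seed = 31L)
  res <- run_experiment(cfg, fx)
  traj <- summarize_trajectory(res)
  drift <- abs(traj$mean_D_h / cfg$D_founder_stress_h - 1)
  expect_lt(max(drift), 0.01)
})

test_that("experiments are reproducible and zero-rate runs are exactly flat", {
  cfg <- founder_cfg(N = 100L, n_cycles = 3L, n_replicates = 2L,
                     mu_snp = 0, mu_dup = 0, seed = 12L)
  r1 <- run_experiment(cfg)
  r2 <- run_experiment(cfg)
  expect_identical(r1$trajectory, r2$trajectory)
  expect_true(all(r1$trajectory$mean_D_h == cfg$D_founder_stress_h))
  traj <- summarize_trajectory(r1)
  expect_true(all(traj$log2_fold_reduction == 0))
  expect_true(all(traj$percent_of_max == 0))
  expect_equal(traj$generation, cumsum(cfg$M_t[1:3]))
})

test_that("trajectory summaries report SEM only with replication", {
  cfg <- founder_cfg(N = 50L, n_cycles = 2L, n_replicates = 1L,
                     mu_snp = 0, mu_dup = 0, seed = 2L)
  traj <- summarize_trajectory(run_experiment(cfg))
  expect_true(all(is.na(traj$sem_D_h)))
  cfg2 <- founder_cfg(N = 50L, n_cycles = 2L, n_replicates = 3L,
                      mu_snp = 0, mu_dup = 0, seed = 2L)
  traj2 <- summarize_trajectory(run_experiment(cfg2))
  expect_true(all(is.finite(traj2$sem_D_h)))
})
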