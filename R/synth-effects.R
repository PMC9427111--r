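#' Configuration for the synthetic mutation-effect table generator
#'
#' Emulates a genome-wide deletion-collection phenotyping screen plus a
#' per-gene count of effectual sites (possible stop gains and strongly
#' deleterious nonsynonymous substitutions). Per-gene doubling-time effects
#' are drawn around the founder's phenotypes: most gene losses are neutral
#' or deleterious; a configurable minority shortens the stressed doubling
#' time, with single-gene benefits bounded by `max_benefit_min` so the best
#' single effects sit in the range measured for the beneficial whole-
#' chromosome duplications (about 31-38 min on a ~215 min adaptation span).
#'
#' @param n_genes Number of nuclear protein-coding genes (default 4947).
#' @param genome_bp Genome size in bp (default 12e6).
#' @param D_founder_nostress_h Founder doubling time without stress, hours
#'   (default 1.55, i.e. 93 min).
#' @param D_founder_stress_h Founder doubling time under stress, hours
#'   (default 308/60: the 93 min floor plus a ~215 min adaptation span).
#' @param fraction_beneficial_in_stress Fraction of gene deletions that
#'   shorten the stressed doubling time (default 0.1).
#' @param benefit_mean_min Mean of the exponential distribution of stressed
#'   doubling-time reductions among beneficial deletions, minutes (default
#'   8).
#' @param max_benefit_min Upper bound on a single-gene reduction, minutes
#'   (default 38, matching the largest measured single-aneuploidy effect).
#' @param cost_sdlog Log-sd of the log-normal multiplicative cost applied
#'   to non-beneficial deletions (default 0.08).
#' @param effectual_sites_mean,effectual_sites_size Negative-binomial mean
#'   and size of the per-gene count of effectual sites (default mean 300,
#'   size 5).
#' @param chr2_benefit_min,chr5_benefit_min Stressed doubling-time
#'   reductions conferred by duplicating chromosomes II and V, minutes
#'   (defaults 31 and 38, the measured values).
#' @param dup_cost_min Stressed doubling-time cost of every other
#'   duplication, minutes (default 10; chromosome III is neutral).
#' @param seed Integer seed.
#' @return A list of class `synth_effect_config`.
#' @export
synth_effect_config <- function(n_genes = 4947L, genome_bp = 12e6,
                                D_founder_nostress_h = 1.55,
                                D_founder_stress_h = 308 / 60,
                                fraction_beneficial_in_stress = 0.1,
                                benefit_mean_min = 8,
                                max_benefit_min = 38,
                                cost_sdlog = 0.08,
                                effectual_sites_mean = 300,
                                effectual_sites_size = 5,
                                chr2_benefit_min = 31,
                                chr5_benefit_min = 38,
                                dup_cost_min = 10,
                                seed = 1L) {
  stopifnot(n_genes > 0L, genome_bp > 0,
            D_founder_stress_h > D_founder_nostress_h,
            D_founder_nostress_h > 0,
            fraction_beneficial_in_stress >= 0,
            fraction_beneficial_in_stress <= 1,
            benefit_mean_min > 0, max_benefit_min > 0, cost_sdlog >= 0,
            effectual_sites_mean > 0, effectual_sites_size > 0,
            dup_cost_min >= 0)
  structure(as.list(environment())[names(formals(synth_effect_config))],
            class = "synth_effect_config")
}

#' Generate synthetic per-gene and per-chromosome effect tables
#'
#' @param cfg A [synth_effect_config()].
#' @return A list of class `effect_table`:
#'   \describe{
#'     \item{genes}{tibble `gene`, `effectual_sites`, `D_nostress_h`,
#'       `D_stress_h` — the doubling times of the corresponding deletion
#'       strain without and under stress}
#'     \item{chroms}{tibble `chrom`, `D_nostress_h`, `D_stress_h` — the
#'       doubling times conferred by duplicating each chromosome}
#'     \item{config}{the configuration}
#'   }
#' @export
gen_effect_tables <- function(cfg) {
  stopifnot(inherits(cfg, "synth_effect_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  Dfs <- cfg$D_founder_stress_h
  Dfn <- cfg$D_founder_nostress_h

  beneficial <- stats::runif(n) < cfg$fraction_beneficial_in_stress
  benefit_h <- pmin(stats::rexp(n, 1 / cfg$benefit_mean_min),
                    cfg$max_benefit_min) / 60
  cost_mult <- stats::rlnorm(n, 0, cfg$cost_sdlog)
  D_stress <- ifelse(beneficial, pmax(Dfs - benefit_h, Dfn),
                     Dfs * pmax(cost_mult, 1))
  # no-stress phenotypes: independent mild costs, floor preserved
  D_nostress <- Dfn * pmax(stats::rlnorm(n, 0, cfg$cost_sdlog), 1)

  sites <- stats::rnbinom(n, mu = cfg$effectual_sites_mean,
                          size = cfg$effectual_sites_size)
  if (sum(sites) > cfg$genome_bp) {
    stop("generated effectual sites exceed the genome size")
  }

  genes <- tibble::tibble(
    gene = sprintf("GENE%04d", seq_len(n)),
    effectual_sites = sites,
    D_nostress_h = D_nostress,
    D_stress_h = D_stress
  )

  nuc <- setdiff(names(yeast_chrom_lengths()), "chrM")
  d_stress_chr <- rep(Dfs + cfg$dup_cost_min / 60, length(nuc))
  names(d_stress_chr) <- nuc
  d_stress_chr["chrII"] <- Dfs - cfg$chr2_benefit_min / 60
  d_stress_chr["chrV"] <- Dfs - cfg$chr5_benefit_min / 60
  d_stress_chr["chrIII"] <- Dfs
  chroms <- tibble::tibble(
    chrom = nuc,
    D_nostress_h = Dfn + cfg$dup_cost_min / 60,
    D_stress_h = unname(d_stress_chr)
  )

  structure(list(genes = genes, chroms = chroms, config = cfg),
            class = "effect_table")
}

#' @export
print.effect_table <- function(x, ...) {
  cat(sprintf(
    "Effect table: %d genes (%d beneficial in stress), %d chromosomes\n",
    nrow(x$genes),
    sum(x$genes$D_stress_h < x$config$D_founder_stress_h),
    nrow(x$chroms)))
  invisible(x)
}
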