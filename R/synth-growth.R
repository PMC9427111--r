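#' Configuration for the synthetic growth-plate generator
#'
#' Describes a solid-medium phenotyping plate: a grid of colonies with
#' wild-type controls interleaved on a regular subgrid (every
#' `control_rstep` rows and `control_cstep` columns, i.e. every fourth
#' position at the 2 x 2 default), logistic growth from a small inoculum to
#' a carrying-capacity plateau, a smooth spatial gradient that multiplies
#' every colony's apparent doubling time, and multiplicative log-normal
#' count noise.
#'
#' @param n_rows,n_cols Plate grid dimensions (default 16 x 24, a 384
#'   format).
#' @param control_rstep,control_cstep Spacing of the control subgrid
#'   (default 2 and 2: controls at odd rows and odd columns, one position in
#'   four).
#' @param true_doubling_h True genotype doubling time in hours: a single
#'   number for all experimental positions, or an `n_rows` x `n_cols` matrix.
#' @param control_doubling_h Control genotype doubling time (hours).
#' @param gradient_amplitude Fractional amplitude of a linear column-wise
#'   bias on apparent doubling time: column `c` is multiplied by
#'   `1 + gradient_amplitude * (c - 1) / (n_cols - 1)`.
#' @param n0_mean,n0_cv Mean and coefficient of variation of the log-normal
#'   inoculum size.
#' @param carrying_capacity Plateau population size (cells).
#' @param sampling_interval_h Time between images, hours (default 1/3, i.e.
#'   20 min).
#' @param duration_h Total cultivation time, hours. Must cover at least 5
#'   doublings of the slowest position.
#' @param noise_cv Coefficient of variation of multiplicative log-normal
#'   count noise (0 for noiseless curves).
#' @param seed Integer seed; the generator is deterministic given the
#'   configuration.
#' @return A list of class `synth_growth_config`.
#' @export
synth_growth_config <- function(n_rows = 16L, n_cols = 24L,
                                control_rstep = 2L, control_cstep = 2L,
                                true_doubling_h = 1.55,
                                control_doubling_h = 1.55,
                                gradient_amplitude = 0,
                                n0_mean = 5e4, n0_cv = 0.1,
                                carrying_capacity = 5e6,
                                sampling_interval_h = 1 / 3,
                                duration_h = 24,
                                noise_cv = 0.05,
                                seed = 1L) {
  stopifnot(n_rows >= 2L, n_cols >= 2L,
            control_rstep >= 1L, control_cstep >= 1L,
            control_rstep * control_cstep >= 2L,
            all(true_doubling_h > 0), control_doubling_h > 0,
            gradient_amplitude >= 0, n0_mean > 1, n0_cv >= 0,
            carrying_capacity > n0_mean,
            sampling_interval_h > 0, duration_h > 0, noise_cv >= 0)
  if (is.matrix(true_doubling_h)) {
    stopifnot(nrow(true_doubling_h) == n_rows, ncol(true_doubling_h) == n_cols)
  }
  slowest <- max(true_doubling_h, control_doubling_h) *
    (1 + gradient_amplitude)
  if (duration_h < 5 * slowest) {
    stop("duration_h must cover at least 5 doublings of the slowest position")
  }
  structure(as.list(environment())[names(formals(synth_growth_config))],
            class = "synth_growth_config")
}

#' Generate a synthetic growth plate with known ground truth
#'
#' Each position grows logistically in linear cell count,
#' `N(t) = K / (1 + ((K - N0) / N0) * 2^(-t / D))`, which is exponential
#' with doubling time `D` while `N << K` and saturates at the carrying
#' capacity `K`, emulating the stationary-phase plateau of a 72 h growth
#' cycle. The apparent doubling time `D` is the genotype's doubling time
#' (control genotype at control positions) multiplied by the configured
#' spatial gradient. Count noise is multiplicative log-normal with the
#' configured coefficient of variation.
#'
#' @param cfg A [synth_growth_config()].
#' @return A list of class `plate_set` with elements
#'   \describe{
#'     \item{curves}{long tibble `row`, `col`, `time_h`, `cells`}
#'     \item{layout}{tibble `row`, `col`, `is_control`}
#'     \item{truth}{tibble `row`, `col`, `is_control`, `genotype_D_h`,
#'       `gradient_factor`, `apparent_D_h`, `n0`}
#'     \item{config}{the configuration}
#'   }
#' @export
gen_growth_plate <- function(cfg) {
  stopifnot(inherits(cfg, "synth_growth_config"))
  set.seed(cfg$seed)
  rows <- seq_len(cfg$n_rows); cols <- seq_len(cfg$n_cols)
  pos <- expand.grid(row = rows, col = cols, KEEP.OUT.ATTRS = FALSE)
  pos <- pos[order(pos$row, pos$col), , drop = FALSE]

  is_control <- (pos$row - 1L) %% cfg$control_rstep == 0L &
    (pos$col - 1L) %% cfg$control_cstep == 0L

  if (is.matrix(cfg$true_doubling_h)) {
    genotype_D <- cfg$true_doubling_h[cbind(pos$row, pos$col)]
  } else {
    genotype_D <- rep(cfg$true_doubling_h, nrow(pos))
  }
  genotype_D[is_control] <- cfg$control_doubling_h

  grad <- if (cfg$n_cols > 1L) {
    1 + cfg$gradient_amplitude * (pos$col - 1) / (cfg$n_cols - 1)
  } else rep(1, nrow(pos))
  apparent_D <- genotype_D * grad

  sdlog <- sqrt(log(1 + cfg$n0_cv^2))
  n0 <- cfg$n0_mean * stats::rlnorm(nrow(pos), -sdlog^2 / 2, sdlog)

  times <- seq(0, cfg$duration_h, by = cfg$sampling_interval_h)
  K <- cfg$carrying_capacity
  # logistic in linear cell count, base-2 rate parameterization
  counts <- vapply(seq_len(nrow(pos)), function(i) {
    K / (1 + ((K - n0[i]) / n0[i]) * 2^(-times / apparent_D[i]))
  }, numeric(length(times)))

  if (cfg$noise_cv > 0) {
    nsd <- sqrt(log(1 + cfg$noise_cv^2))
    counts <- counts * stats::rlnorm(length(counts), -nsd^2 / 2, nsd)
  }

  curves <- tibble::tibble(
    row = rep(pos$row, each = length(times)),
    col = rep(pos$col, each = length(times)),
    time_h = rep(times, nrow(pos)),
    cells = as.vector(counts)
  )
  layout <- tibble::tibble(row = pos$row, col = pos$col,
                           is_control = is_control)
  truth <- tibble::tibble(row = pos$row, col = pos$col,
                          is_control = is_control,
                          genotype_D_h = genotype_D,
                          gradient_factor = grad,
                          apparent_D_h = apparent_D,
                          n0 = n0)
  structure(list(curves = curves, layout = layout, truth = truth,
                 config = cfg), class = "plate_set")
}

#' @export
print.plate_set <- function(x, ...) {
  cat(sprintf("Synthetic plate: %d x %d positions (%d controls), %d timepoints\n",
              x$config$n_rows, x$config$n_cols, sum(x$layout$is_control),
              length(unique(x$curves$time_h))))
  invisible(x)
}
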