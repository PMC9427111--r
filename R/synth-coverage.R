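#' Reference chromosome lengths for the synthetic genome
#'
#' The 16 nuclear chromosomes of the budding-yeast reference assembly
#' (R64-1-1, ~12.07 Mb total) plus a 77 kb mitochondrial genome, the size of
#' the founder strain's mtDNA in this pipeline.
#'
#' @param mt_bp Length of the mitochondrial genome in bp (default 77,000).
#' @return Named integer vector of chromosome lengths.
#' @export
yeast_chrom_lengths <- function(mt_bp = 77000L) {
  c(chrI = 230218L, chrII = 813184L, chrIII = 316620L, chrIV = 1531933L,
    chrV = 576874L, chrVI = 270161L, chrVII = 1090940L, chrVIII = 562643L,
    chrIX = 439888L, chrX = 745751L, chrXI = 666816L, chrXII = 1078177L,
    chrXIII = 924431L, chrXIV = 784333L, chrXV = 1091291L, chrXVI = 948066L,
    chrM = as.integer(mt_bp))
}

#' Synthetic gene map of the 77 kb mitochondrial genome
#'
#' An approximate, synthetic layout of the major protein- and rRNA-coding
#' mitochondrial genes in their canonical order around the yeast mtDNA,
#' scaled onto a 77 kb molecule. Coordinates are representative, not those
#' of any sequenced strain; they exist so segment calls can be translated
#' into gene-level loss reports on generated data.
#'
#' @return A BED6-style tibble: `chrom`, `start`, `end`, `name`, `score`,
#'   `strand` (0-based half-open coordinates).
#' @export
mtdna_gene_annotation <- function() {
  tibble::tibble(
    chrom = "chrM",
    start = c(6000L, 13000L, 27000L, 28500L, 36000L, 45500L, 47500L,
              54000L, 65000L, 72500L, 75500L),
    end   = c(8000L, 26000L, 27500L, 29300L, 43500L, 46300L, 49500L,
              58500L, 65800L, 74000L, 76000L),
    name  = c("15S_rRNA", "COX1", "ATP8", "ATP6", "COB", "ATP9", "VAR1",
              "21S_rRNA", "COX2", "COX3", "RPM1"),
    score = 0L,
    strand = "+"
  )
}

#' Configuration for the synthetic coverage generator
#'
#' Describes a sequencing depth track over the nuclear genome plus mtDNA:
#' the mtDNA is present at `mt_copy_number` copies per cell except inside
#' configured deleted intervals; whole nuclear chromosomes can be duplicated
#' (2 copies instead of 1); depth per window is Poisson (or
#' negative-binomial) around `mean_depth` times the local copy number.
#'
#' @param chrom_lengths Named vector of chromosome lengths; defaults to
#'   [yeast_chrom_lengths()].
#' @param mt_chrom Name of the mitochondrial chromosome (default `"chrM"`).
#' @param mt_copy_number True mtDNA copies per cell (default 20).
#' @param mt_deleted_intervals List of `c(start, end)` 0-based half-open bp
#'   intervals within the mtDNA carrying `mt_deleted_copy` copies
#'   (default 0). Intervals must be disjoint and lie within the mtDNA.
#' @param mt_deleted_copy Copy number inside deleted intervals (default 0).
#' @param duplicated_chroms Character vector of nuclear chromosomes at 2
#'   copies.
#' @param mean_depth Expected per-bp depth at copy number 1 (default 30).
#' @param window_bp Resolution of the generated track (default 200 bp).
#' @param noise Either `"none"`, `"poisson"` (default) or `"nbinom"`.
#' @param nbinom_size Dispersion parameter when `noise = "nbinom"`.
#' @param seed Integer seed.
#' @return A list of class `synth_coverage_config`.
#' @export
synth_coverage_config <- function(chrom_lengths = yeast_chrom_lengths(),
                                  mt_chrom = "chrM",
                                  mt_copy_number = 20,
                                  mt_deleted_intervals = list(),
                                  mt_deleted_copy = 0,
                                  duplicated_chroms = character(),
                                  mean_depth = 30,
                                  window_bp = 200L,
                                  noise = c("poisson", "none", "nbinom"),
                                  nbinom_size = 10,
                                  seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(!is.null(names(chrom_lengths)), all(chrom_lengths > 0),
            mt_chrom %in% names(chrom_lengths),
            mt_copy_number > 0, mean_depth > 0, window_bp > 0,
            mt_deleted_copy >= 0,
            all(duplicated_chroms %in% setdiff(names(chrom_lengths), mt_chrom)))
  mt_len <- chrom_lengths[[mt_chrom]]
  if (length(mt_deleted_intervals)) {
    iv <- do.call(rbind, mt_deleted_intervals)
    stopifnot(ncol(iv) == 2L, all(iv[, 1] < iv[, 2]),
              all(iv[, 1] >= 0), all(iv[, 2] <= mt_len))
    iv <- iv[order(iv[, 1]), , drop = FALSE]
    if (nrow(iv) > 1L && any(iv[-1L, 1] < iv[-nrow(iv), 2])) {
      stop("deleted intervals must not overlap")
    }
  }
  structure(as.list(environment())[names(formals(synth_coverage_config))],
            class = "synth_coverage_config")
}

#' Generate a synthetic coverage track with known ground truth
#'
#' Produces a tiled, non-overlapping window depth track (bedGraph
#' convention: 0-based half-open coordinates, one record per window) where
#' the expected depth of every window is `mean_depth` times its local copy
#' number, with optional Poisson or negative-binomial noise applied to the
#' window read sums.
#'
#' @param cfg A [synth_coverage_config()].
#' @return A list of class `coverage_set`: `windows` (tibble `chrom`,
#'   `start`, `end`, `depth`), `truth` (tibble of per-window true copy
#'   numbers), and `config`.
#' @export
gen_coverage <- function(cfg) {
  stopifnot(inherits(cfg, "synth_coverage_config"))
  set.seed(cfg$seed)
  pieces <- lapply(names(cfg$chrom_lengths), function(ch) {
    len <- cfg$chrom_lengths[[ch]]
    starts <- seq(0L, len - 1L, by = cfg$window_bp)
    ends <- pmin(starts + cfg$window_bp, len)
    copy <- if (ch == cfg$mt_chrom) {
      cn <- rep(cfg$mt_copy_number, length(starts))
      for (iv in cfg$mt_deleted_intervals) {
        # window copy = length-weighted mean over the interval overlap
        ov <- pmax(0, pmin(ends, iv[2]) - pmax(starts, iv[1]))
        w <- ov / (ends - starts)
        cn <- cn * (1 - w) + cfg$mt_deleted_copy * w
      }
      cn
    } else if (ch %in% cfg$duplicated_chroms) {
      rep(2, length(starts))
    } else {
      rep(1, length(starts))
    }
    tibble::tibble(chrom = ch, start = starts, end = ends, copy = copy)
  })
  truth <- dplyr::bind_rows(pieces)

  lambda <- cfg$mean_depth * truth$copy * (truth$end - truth$start)
  reads <- switch(cfg$noise,
    none = lambda,
    poisson = stats::rpois(length(lambda), lambda),
    nbinom = stats::rnbinom(length(lambda), mu = lambda,
                            size = cfg$nbinom_size)
  )
  windows <- tibble::tibble(chrom = truth$chrom, start = truth$start,
                            end = truth$end,
                            depth = reads / (truth$end - truth$start))
  structure(list(windows = windows, truth = truth, config = cfg),
            class = "coverage_set")
}

#' @export
print.coverage_set <- function(x, ...) {
  cat(sprintf("Synthetic coverage: %d windows over %d chromosomes (%s noise)\n",
              nrow(x$windows), length(unique(x$windows$chrom)),
              x$config$noise))
  invisible(x)
}
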