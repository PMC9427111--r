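#' Re-window a depth track into tiled non-overlapping windows
#'
#' Converts a per-base or run-length depth track (bedGraph convention,
#' 0-based half-open, per chromosome) into mean depths over tiled,
#' non-overlapping windows of `window_bp`. A trailing partial window shorter
#' than half the window size is merged into its left neighbour; longer
#' partial windows are kept as their own (short) window. Upstream alignment
#' filtering (reads with MAPQ < 1 excluded) is a contract of the input
#' track, not re-applied here.
#'
#' @param track Data frame with columns `chrom`, `start`, `end`, `depth`
#'   (intervals non-overlapping and sorted within each chromosome).
#' @param window_bp Window size in bp (> 0).
#' @return A tibble `chrom`, `start`, `end`, `depth` of tiled windows.
#' @export
window_depth <- function(track, window_bp) {
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(track)),
            window_bp > 0)
  if (nrow(track) == 0L) stop("empty depth track")
  window_bp <- as.integer(window_bp)
  track |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$start)
      len <- max(d$end)
      n_full <- len %/% window_bp
      rem <- len - n_full * window_bp
      bounds <- seq(0L, by = window_bp, length.out = n_full + 1L)
      if (rem > 0L) {
        if (rem < window_bp / 2 && n_full >= 1L) {
          bounds[n_full + 1L] <- len   # merge short tail into last window
        } else {
          bounds <- c(bounds, len)     # keep as its own short window
        }
      }
      # split runs at window boundaries, then length-weighted mean per window
      cut_starts <- pmax(rep(d$start, each = length(bounds) - 1L),
                         rep(bounds[-length(bounds)], nrow(d)))
      cut_ends <- pmin(rep(d$end, each = length(bounds) - 1L),
                       rep(bounds[-1L], nrow(d)))
      w_id <- rep(seq_len(length(bounds) - 1L), nrow(d))
      dep <- rep(d$depth, each = length(bounds) - 1L)
      keep <- cut_ends > cut_starts
      bp <- (cut_ends - cut_starts)[keep]
      mass <- rowsum(bp * dep[keep], w_id[keep],
                     reorder = TRUE)
      covered <- rowsum(bp, w_id[keep], reorder = TRUE)
      ids <- as.integer(rownames(mass))
      depth <- rep(0, length(bounds) - 1L)
      width <- diff(bounds)
      depth[ids] <- mass[, 1L] / width[ids]  # uncovered bp count as depth 0
      tibble::tibble(start = bounds[-length(bounds)], end = bounds[-1L],
                     depth = depth)
    }) |>
    dplyr::ungroup()
}

#' mtDNA copy number from windowed coverage
#'
#' Normalizes every window's depth against the median depth of all nuclear
#' windows on euploid chromosomes (`log2(W_i / W_median_euploid)`), and
#' estimates the absolute number of mtDNA molecules per cell as
#' `2^median(log2 ratio)` over the mtDNA windows, assuming one copy of the
#' nuclear genome and no sequencing bias. Windows with zero depth receive a
#' configurable log2 floor in place of minus infinity.
#'
#' @param windows Tiled window depths (`chrom`, `start`, `end`, `depth`),
#'   typically 1 kb windows from [window_depth()].
#' @param mt_chrom Name of the mitochondrial chromosome (default `"chrM"`).
#' @param aneuploid_chroms Chromosomes excluded from the euploid median
#'   (e.g. from [call_aneuploidies()]).
#' @param zero_log2_floor log2 ratio assigned to zero-depth windows
#'   (default -10).
#' @return A list of class `copy_number_profile`: `windows` (input plus
#'   `log2_ratio`), `chrom_median_log2` (named vector),
#'   `mt_copy_number` (the absolute estimate), `euploid_median_depth`.
#' @export
mtdna_copy_number <- function(windows, mt_chrom = "chrM",
                              aneuploid_chroms = character(),
                              zero_log2_floor = -10) {
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(windows)),
            mt_chrom %in% windows$chrom)
  euploid <- windows$chrom != mt_chrom &
    !(windows$chrom %in% aneuploid_chroms)
  if (!any(euploid)) stop("need windows from at least one euploid chromosome")
  med <- stats::median(windows$depth[euploid])
  if (med <= 0) stop("euploid median depth is zero")
  lr <- log2(windows$depth / med)
  lr[!is.finite(lr)] <- zero_log2_floor
  lr <- pmax(lr, zero_log2_floor)
  windows$log2_ratio <- lr
  chrom_median <- tapply(lr, windows$chrom, stats::median)
  mt_cn <- 2^unname(chrom_median[mt_chrom])
  structure(list(windows = tibble::as_tibble(windows),
                 chrom_median_log2 = chrom_median,
                 mt_copy_number = mt_cn,
                 euploid_median_depth = med),
            class = "copy_number_profile")
}

#' @export
print.copy_number_profile <- function(x, ...) {
  cat(sprintf("Copy-number profile: %d windows; mtDNA copy number %.2f\n",
              nrow(x$windows), x$mt_copy_number))
  invisible(x)
}

#' Call whole-chromosome duplications against a founder sample
#'
#' Computes per-window log2 ratios of a sample against a founder sequenced
#' on the same flow cell, after rescaling the sample by
#' `kappa = (total founder depth) / (total sample depth)` so library-size
#' differences cancel, and calls a chromosome duplicated when its median
#' log2 ratio reaches the threshold (default 0.5, halfway to the log2 = 1
#' expected for a haploid gaining one copy).
#'
#' @param sample_windows,founder_windows Window tables on identical
#'   coordinates (`chrom`, `start`, `end`, `depth`).
#' @param threshold_log2 Calling threshold on the per-chromosome median
#'   (default 0.5).
#' @param mt_chrom Chromosome excluded from calling (the mitochondrial
#'   genome; default `"chrM"`).
#' @return A list of class `aneuploidy_calls`: `calls` (tibble `chrom`,
#'   `median_log2`, `call`), `kappa`, `threshold_log2`, and `windows` (the
#'   per-window ratios).
#' @export
call_aneuploidies <- function(sample_windows, founder_windows,
                              threshold_log2 = 0.5, mt_chrom = "chrM") {
  req <- c("chrom", "start", "end", "depth")
  stopifnot(all(req %in% names(sample_windows)),
            all(req %in% names(founder_windows)))
  s <- dplyr::arrange(sample_windows, .data$chrom, .data$start)
  f <- dplyr::arrange(founder_windows, .data$chrom, .data$start)
  if (nrow(s) != nrow(f) ||
      !all(s$chrom == f$chrom & s$start == f$start & s$end == f$end)) {
    stop("sample and founder windows must share identical coordinates")
  }
  width <- s$end - s$start
  kappa <- sum(f$depth * width) / sum(s$depth * width)
  drop <- f$depth <= 0
  if (any(drop)) {
    warning(sprintf("dropping %d windows with zero founder depth", sum(drop)))
  }
  keep <- !drop & s$chrom != mt_chrom
  lr <- log2(kappa * s$depth[keep] / f$depth[keep])
  wtab <- tibble::tibble(chrom = s$chrom[keep], start = s$start[keep],
                         end = s$end[keep], log2_ratio = lr)
  med <- tapply(wtab$log2_ratio, wtab$chrom, stats::median)
  mv <- as.numeric(med)
  calls <- tibble::tibble(
    chrom = names(med),
    median_log2 = mv,
    call = ifelse(mv >= threshold_log2, "duplicated", "euploid")
  )
  structure(list(calls = calls, kappa = kappa,
                 threshold_log2 = threshold_log2, windows = wtab),
            class = "aneuploidy_calls")
}

#' @export
print.aneuploidy_calls <- function(x, ...) {
  dup <- x$calls$chrom[x$calls$call == "duplicated"]
  cat(sprintf("Aneuploidy calls (kappa = %.4f): %s\n", x$kappa,
              if (length(dup)) paste(dup, collapse = ", ") else "none"))
  invisible(x)
}

#' Segment the mtDNA into retained and lost blocks
#'
#' Classifies every mtDNA window as lost when its log2 ratio falls at or
#' below `loss_threshold_log2` (default -2, i.e. 25% or less of the
#' euploid-relative level), merges runs shorter than `min_windows` into
#' their flanking state, and emits maximal runs as segments. Adjacent
#' segments always differ in state and together tile the mtDNA, reflecting
#' the concerted copy-number change of segmental deletions.
#'
#' @param profile A `copy_number_profile` from [mtdna_copy_number()], or a
#'   window tibble with `chrom`, `start`, `end`, `log2_ratio`.
#' @param loss_threshold_log2 Loss classification threshold (default -2).
#' @param min_windows Minimum run length in windows; shorter runs are
#'   absorbed by their neighbours (default 2).
#' @param mt_chrom Mitochondrial chromosome name (default `"chrM"`).
#' @return A tibble of segments: `start`, `end`, `state` (`"retained"` or
#'   `"lost"`), `mean_log2`, `n_windows`.
#' @export
segment_mtdna <- function(profile, loss_threshold_log2 = -2,
                          min_windows = 2L, mt_chrom = "chrM") {
  w <- if (inherits(profile, "copy_number_profile")) profile$windows else profile
  stopifnot(all(c("chrom", "start", "end", "log2_ratio") %in% names(w)))
  w <- w[w$chrom == mt_chrom, , drop = FALSE]
  if (nrow(w) == 0L) stop("profile contains no mtDNA windows")
  w <- w[order(w$start), , drop = FALSE]
  lost <- w$log2_ratio <= loss_threshold_log2

  # absorb runs shorter than min_windows into a flanking run, repeatedly
  repeat {
    r <- rle(lost)
    if (length(r$lengths) <= 1L) break
    short <- which(r$lengths < min_windows)
    if (length(short) == 0L) break
    i <- short[1L]
    r$values[i] <- if (i > 1L) r$values[i - 1L] else r$values[i + 1L]
    lost <- inverse.rle(r)
  }

  r <- rle(lost)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  tibble::tibble(
    start = w$start[idx_start],
    end = w$end[idx_end],
    state = ifelse(r$values, "lost", "retained"),
    mean_log2 = vapply(seq_along(r$lengths), function(i) {
      mean(w$log2_ratio[idx_start[i]:idx_end[i]])
    }, numeric(1)),
    n_windows = r$lengths
  )
}

#' Classify the petite (rho) state from mtDNA segments
#'
#' Petite nomenclature by retained mtDNA span: `rho_plus` for an
#' essentially intact molecule, `rho_minus` for partial retention,
#' `rho_minus_minus` for retention of only a very small segment, and
#' `rho_zero` for complete absence of mtDNA.
#'
#' @param segments Segment tibble from [segment_mtdna()].
#' @param intact_kb Minimum retained span for `rho_plus` (default 70).
#' @param minimal_kb Below this retained span (but above zero) the state is
#'   `rho_minus_minus` (default 2).
#' @return A list of class `rho_class`: `label` and `retained_kb`.
#' @export
classify_rho <- function(segments, intact_kb = 70, minimal_kb = 2) {
  stopifnot(all(c("start", "end", "state") %in% names(segments)),
            intact_kb > minimal_kb, minimal_kb > 0)
  ret <- segments$state == "retained"
  retained_kb <- sum((segments$end - segments$start)[ret]) / 1000
  label <- if (retained_kb >= intact_kb) "rho_plus"
  else if (retained_kb >= minimal_kb) "rho_minus"
  else if (retained_kb > 0) "rho_minus_minus"
  else "rho_zero"
  structure(list(label = label, retained_kb = retained_kb),
            class = "rho_class")
}

#' @export
print.rho_class <- function(x, ...) {
  cat(sprintf("%s (%.1f kb mtDNA retained)\n", x$label, x$retained_kb))
  invisible(x)
}

#' Report per-gene loss from mtDNA segments
#'
#' A gene is reported lost when at least `loss_fraction` of its span
#' overlaps lost segments.
#'
#' @param segments Segment tibble from [segment_mtdna()].
#' @param genes BED-style gene annotation (`chrom`, `start`, `end`, `name`),
#'   e.g. [mtdna_gene_annotation()]. Intervals must lie within the segment
#'   span.
#' @param loss_fraction Overlap fraction required to call a gene lost
#'   (default 0.5).
#' @return A tibble `gene`, `start`, `end`, `lost_fraction`, `state`.
#' @export
map_segments_to_genes <- function(segments, genes, loss_fraction = 0.5) {
  stopifnot(all(c("start", "end", "state") %in% names(segments)),
            all(c("start", "end", "name") %in% names(genes)),
            loss_fraction > 0, loss_fraction <= 1)
  if (any(genes$start >= genes$end) ||
      any(genes$start < min(segments$start)) ||
      any(genes$end > max(segments$end))) {
    stop("malformed annotation: gene intervals must lie within the mtDNA")
  }
  lost_seg <- segments[segments$state == "lost", , drop = FALSE]
  frac <- vapply(seq_len(nrow(genes)), function(i) {
    ov <- pmax(0, pmin(lost_seg$end, genes$end[i]) -
                 pmax(lost_seg$start, genes$start[i]))
    sum(ov) / (genes$end[i] - genes$start[i])
  }, numeric(1))
  tibble::tibble(gene = genes$name, start = genes$start, end = genes$end,
                 lost_fraction = frac,
                 state = ifelse(frac >= loss_fraction, "lost", "retained"))
}
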