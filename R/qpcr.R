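#' Relative copy number from qPCR Ct tables (capped -ddCt)
#'
#' Computes per-gene, per-timepoint log2 relative copy numbers from a Ct
#' table with a nuclear single-copy reference, after capping all Ct values
#' at `cap` (default 30; signal beyond 30 cycles is background). For each
#' record `dCt = Ct_target - Ct_reference`; the result is
#' `-(dCt_t - dCt_0)`, the negative delta-delta-Ct, which equals
#' `log2( 2^-( dCt_t - dCt_0 ) )`. Replicates are averaged after the
#' transform.
#'
#' Records can carry a logical `force_cap` column to push individual
#' replicates to the cap regardless of their measured Ct (for primer pairs
#' with known non-PCR background signal).
#'
#' @param records Tibble with columns `gene`, `timepoint`, `replicate`,
#'   `Ct_target`, `Ct_reference` and optionally `force_cap`.
#' @param cap Ct cap (default 30).
#' @param baseline_timepoint The reference timepoint supplying `dCt_0`
#'   (default 0); every gene must have it.
#' @return A tibble `gene`, `timepoint`, `log2_rel_cn`, `n_replicates`.
#' @export
relative_copy_number <- function(records, cap = 30, baseline_timepoint = 0) {
  req <- c("gene", "timepoint", "replicate", "Ct_target", "Ct_reference")
  stopifnot(all(req %in% names(records)), cap > 0)
  if (any(records$Ct_target <= 0 | records$Ct_reference <= 0)) {
    stop("Ct values must be positive")
  }
  ct_t <- pmin(records$Ct_target, cap)
  ct_r <- pmin(records$Ct_reference, cap)
  if ("force_cap" %in% names(records)) {
    ct_t[records$force_cap] <- cap
  }
  d <- tibble::tibble(gene = records$gene, timepoint = records$timepoint,
                      dct = ct_t - ct_r)
  base <- d |>
    dplyr::filter(.data$timepoint == baseline_timepoint) |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(dct0 = mean(.data$dct), .groups = "drop")
  if (!all(unique(d$gene) %in% base$gene)) {
    stop("every gene needs records at the baseline timepoint")
  }
  d |>
    dplyr::left_join(base, by = "gene") |>
    dplyr::mutate(log2_rel = -(.data$dct - .data$dct0)) |>
    dplyr::group_by(.data$gene, .data$timepoint) |>
    dplyr::summarise(log2_rel_cn = mean(.data$log2_rel),
                     n_replicates = dplyr::n(), .groups = "drop")
}

#' Group adjacent mtDNA genes by concerted copy-number change
#'
#' Segmental deletions remove adjacent genes concomitantly and to the same
#' extent; this groups genes, in their physical order along the mtDNA,
#' whose endpoint log2 changes agree within a tolerance, and labels each
#' group lost or retained.
#'
#' @param trajectories Output of [relative_copy_number()] (columns `gene`,
#'   `timepoint`, `log2_rel_cn`) with at least two timepoints.
#' @param gene_order Character vector giving the genes' physical order
#'   along the mtDNA (e.g. `mtdna_gene_annotation()$name`).
#' @param tolerance_log2 Two adjacent genes join a group when their
#'   endpoint changes differ by at most this much (inclusive; default 0.5).
#' @param loss_threshold_log2 A group is labelled lost when its mean
#'   endpoint change is at or below this (default -2).
#' @return A tibble `segment`, `genes` (list column), `first_gene`,
#'   `last_gene`, `mean_change`, `state`.
#' @export
concerted_change_segments <- function(trajectories, gene_order,
                                      tolerance_log2 = 0.5,
                                      loss_threshold_log2 = -2) {
  stopifnot(all(c("gene", "timepoint", "log2_rel_cn") %in%
                  names(trajectories)),
            length(unique(trajectories$timepoint)) >= 2L,
            tolerance_log2 >= 0)
  endpoint <- max(trajectories$timepoint)
  final <- trajectories[trajectories$timepoint == endpoint, , drop = FALSE]
  final <- final[match(gene_order, final$gene), , drop = FALSE]
  if (anyNA(final$gene)) {
    stop("gene_order contains genes absent from the trajectories")
  }
  chg <- final$log2_rel_cn
  new_group <- c(TRUE, abs(diff(chg)) > tolerance_log2)
  grp <- cumsum(new_group)
  tibble::tibble(gene = gene_order, change = chg, segment = grp) |>
    dplyr::group_by(.data$segment) |>
    dplyr::summarise(genes = list(.data$gene),
                     first_gene = dplyr::first(.data$gene),
                     last_gene = dplyr::last(.data$gene),
                     mean_change = mean(.data$change), .groups = "drop") |>
    dplyr::mutate(state = ifelse(.data$mean_change <= loss_threshold_log2,
                                 "lost", "retained"))
}
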