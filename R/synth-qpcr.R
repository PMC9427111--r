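#' Generate a synthetic qPCR Ct table from true copy-number trajectories
#'
#' Emulates relative quantification against a single-copy nuclear reference
#' gene with 100% amplification efficiency (one Ct unit per twofold
#' difference): `Ct_target = Ct_ref - log2(copy_number) + noise`, where
#' `copy_number` is the target's copy number relative to the reference.
#' Targets flagged absent are emitted at `absent_ct`, above the downstream
#' cap, so capping applies.
#'
#' @param truth Tibble with columns `gene`, `timepoint`, `copy_number`
#'   (relative to the nuclear reference; > 0) and optionally a logical
#'   `absent` column.
#' @param n_replicates Technical replicates per gene/timepoint (default 2).
#' @param ct_ref Reference-gene Ct (default 22).
#' @param noise_sd Gaussian Ct noise, cycles (default 0; must be >= 0).
#' @param absent_ct Ct emitted for absent targets (default 35).
#' @param seed Integer seed.
#' @return A tibble with columns `gene`, `timepoint`, `replicate`,
#'   `Ct_target`, `Ct_reference`.
#' @export
gen_qpcr <- function(truth, n_replicates = 2L, ct_ref = 22,
                     noise_sd = 0, absent_ct = 35, seed = 1L) {
  stopifnot(all(c("gene", "timepoint", "copy_number") %in% names(truth)),
            n_replicates >= 1L, ct_ref > 0)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!"absent" %in% names(truth)) truth$absent <- FALSE
  if (any(!truth$absent & truth$copy_number <= 0)) {
    stop("copy numbers must be positive unless flagged absent")
  }
  set.seed(seed)
  out <- truth[rep(seq_len(nrow(truth)), each = n_replicates), ]
  out$replicate <- rep(seq_len(n_replicates), nrow(truth))
  ct <- ct_ref - log2(out$copy_number)
  ct[out$absent] <- absent_ct
  if (noise_sd > 0) ct <- ct + stats::rnorm(length(ct), 0, noise_sd)
  tibble::tibble(gene = out$gene, timepoint = out$timepoint,
                 replicate = out$replicate,
                 Ct_target = ct, Ct_reference = ct_ref)
}
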