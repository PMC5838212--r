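#' Simulate a qRT-PCR Ct table with planted fold changes
#'
#' Generates calibrator and treated Ct values for a set of target miRNAs
#' and a housekeeping control. The treated Ct of each target is the
#' calibrator Ct minus `log2(planted_fc)` (plus optional Gaussian noise);
#' the housekeeping Ct is constant across groups up to noise, so
#' [ddct_relative_expression()] recovers the planted fold change exactly at
#' zero noise.
#'
#' @param targets character vector of target ids.
#' @param planted_fc numeric vector of fold changes (> 0), one per target.
#' @param hk_id housekeeping target id (must differ from `targets`).
#' @param seed RNG seed.
#' @param n_reps technical replicates per group.
#' @param noise_sd SD of Gaussian Ct noise, cycles.
#' @return A data.frame with columns `sample`, `group`
#'   (`calibrator`/`treated`), `target`, `ct`; the housekeeping id is
#'   attached as attribute `"housekeeping"`.
#' @export
simulate_ct <- function(targets, planted_fc, hk_id, seed = 1,
                        n_reps = 3, noise_sd = 0) {
  if (missing(hk_id) || is.null(hk_id) || !nzchar(hk_id)) {
    stop("missing housekeeping id")
  }
  if (hk_id %in% targets) stop("housekeeping id must not be a target")
  if (length(planted_fc) != length(targets)) {
    stop("planted_fc must have one value per target")
  }
  if (any(planted_fc <= 0)) stop("planted_fc must be > 0")
  with_seed(seed, {
    base_ct <- setNames(runif(length(targets), 22, 28), targets)
    hk_ct <- 18
    rows <- list()
    for (grp in c("calibrator", "treated")) {
      for (r in seq_len(n_reps)) {
        samp <- sprintf("%s_%d", grp, r)
        ct_t <- base_ct -
          if (grp == "treated") log2(planted_fc) else 0
        rows[[length(rows) + 1]] <- data.frame(
          sample = samp, group = grp,
          target = c(targets, hk_id),
          ct = c(ct_t, hk_ct) + rnorm(length(targets) + 1, 0, noise_sd),
          stringsAsFactors = FALSE
        )
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    if (any(!is.finite(out$ct)) || any(out$ct <= 0)) {
      stop("simulated Ct values must be finite and > 0")
    }
    attr(out, "housekeeping") <- hk_id
    out
  })
}

#' Relative expression by the delta-delta-Ct method
#'
#' Within each group, the mean Ct of the target minus the mean Ct of the
#' housekeeping control gives delta-Ct; delta-delta-Ct is the treated
#' delta-Ct minus the calibrator delta-Ct, and relative expression is
#' `2^-ddCt`.
#'
#' @param ct Ct table as produced by [simulate_ct()] (columns `group`,
#'   `target`, `ct`).
#' @param target target id to quantify.
#' @param housekeeping housekeeping id; defaults to the table's
#'   `"housekeeping"` attribute.
#' @return Relative expression (dimensionless), with `ddct` attached as an
#'   attribute.
#' @export
ddct_relative_expression <- function(ct, target,
                                     housekeeping = attr(ct, "housekeeping")) {
  if (is.null(housekeeping)) stop("housekeeping id not specified")
  mean_ct <- function(grp, tgt) {
    v <- ct$ct[ct$group == grp & ct$target == tgt]
    if (length(v) == 0) {
      stop(sprintf("no Ct values for target '%s' in group '%s'", tgt, grp))
    }
    mean(v)
  }
  dct <- function(grp) mean_ct(grp, target) - mean_ct(grp, housekeeping)
  ddct <- dct("treated") - dct("calibrator")
  structure(2^(-ddct), ddct = ddct)
}
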