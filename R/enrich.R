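#' Fold change of each miRNA versus the baseline condition
#'
#' Computes, for every endogenous miRNA and every non-baseline condition,
#' the ratio of the mean normalized count in that condition to the mean in
#' the baseline condition. When the baseline mean is exactly zero a
#' pseudocount (default 0.5) is added to both numerator and denominator for
#' that miRNA only.
#'
#' @param m a [mirna_counts] in `quantile_normalized` state.
#' @param baseline the baseline condition label.
#' @param conditions conditions to compare; default all non-baseline
#'   conditions present.
#' @param pseudocount value added to both means when the baseline mean is 0.
#' @return A data.frame with columns `mirna`, `condition`, `fold_change`.
#' @export
fold_change <- function(m, baseline, conditions = NULL, pseudocount = 0.5) {
  stopifnot(inherits(m, "mirna_counts"))
  if (m$state != "quantile_normalized") {
    stop("fold_change expects a quantile-normalized matrix")
  }
  if (!baseline %in% m$condition) {
    stop("unknown baseline condition: ", baseline)
  }
  conditions <- conditions %||% setdiff(unique(m$condition), baseline)
  if (!all(conditions %in% m$condition)) {
    stop("unknown condition(s): ",
         paste(setdiff(conditions, m$condition), collapse = ", "))
  }
  endo <- endogenous_counts(m)
  base_mean <- rowMeans(endo[, m$condition == baseline, drop = FALSE])
  res <- lapply(conditions, function(cond) {
    cm <- rowMeans(endo[, m$condition == cond, drop = FALSE])
    zero <- base_mean == 0
    fc <- ifelse(zero,
                 (cm + pseudocount) / (base_mean + pseudocount),
                 cm / base_mean)
    data.frame(mirna = rownames(endo), condition = cond,
               fold_change = unname(fc), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "baseline") <- baseline
  out
}

#' Call stimulus-enriched miRNAs
#'
#' A miRNA is enriched in a condition when its fold change versus the
#' baseline is greater than or equal to the threshold (inclusive boundary;
#' default 1.5).
#'
#' @param fc fold-change table from [fold_change()].
#' @param threshold fold-change cutoff (> 0).
#' @return Subset of `fc` with `fold_change >= threshold`, ordered by
#'   condition then decreasing fold change; attribute `"threshold"` records
#'   the cutoff.
#' @export
call_enriched <- function(fc, threshold = 1.5) {
  if (threshold <= 0) stop("threshold must be > 0")
  out <- fc[fc$fold_change >= threshold, , drop = FALSE]
  out <- out[order(out$condition, -out$fold_change), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  attr(out, "baseline") <- attr(fc, "baseline")
  out
}

#' Enriched miRNA ids per condition
#'
#' @param enriched output of [call_enriched()].
#' @param conditions condition labels to report (defaults to those present).
#' @return Named list of character vectors of miRNA ids.
#' @export
enriched_sets <- function(enriched, conditions = NULL) {
  conditions <- conditions %||% unique(enriched$condition)
  setNames(
    lapply(conditions, function(cc) {
      sort(enriched$mirna[enriched$condition == cc])
    }),
    conditions
  )
}

#' Detect expressed miRNAs against the negative-control background
#'
#' A miRNA counts as detected when its value exceeds
#' `mean + multiplier * SD` of the negative-control probes within the same
#' sample, in at least `min_samples` samples. If the matrix carries no
#' negative controls an explicit `floor` must be supplied.
#'
#' @param m a [mirna_counts] (any normalization state; the rule is applied
#'   to the values as stored).
#' @param multiplier SD multiplier of the detection threshold.
#' @param min_samples number of samples the threshold must be exceeded in.
#' @param floor explicit per-sample detection floor, used when no
#'   negative-control probes are present.
#' @return Character vector of detected miRNA ids; the per-sample thresholds
#'   and the rule parameters are attached as attributes.
#' @export
detect_mirnas <- function(m, multiplier = 2, min_samples = 1, floor = NULL) {
  stopifnot(inherits(m, "mirna_counts"))
  neg <- m$counts[m$probe_class == "negative", , drop = FALSE]
  if (nrow(neg) == 0) {
    if (is.null(floor)) {
      stop("no negative-control probes and no explicit floor configured")
    }
    thr <- rep_len(floor, ncol(m$counts))
  } else {
    thr <- apply(neg, 2, function(v) {
      mean(v) + multiplier * (if (length(v) > 1) sd(v) else 0)
    })
  }
  endo <- endogenous_counts(m)
  hits <- sweep(endo, 2, thr, `>`)
  detected <- rownames(endo)[rowSums(hits) >= min_samples]
  structure(detected,
            thresholds = setNames(thr, colnames(m$counts)),
            multiplier = multiplier, min_samples = min_samples)
}
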