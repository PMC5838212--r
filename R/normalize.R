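#' Positive-control spike-in normalization
#'
#' Scales every sample so the summed counts of the positive-control spike-in
#' probes are equal across samples. Each sample's scale factor is the grand
#' geometric mean of per-sample positive-control sums divided by that
#' sample's positive-control sum; after scaling, every sample's
#' positive-control sum equals the geometric mean.
#'
#' @param m a [mirna_counts] in `raw` state with at least one
#'   positive-control probe.
#' @return A [mirna_counts] in `spikein_normalized` state, with the scale
#'   factors attached as attribute `"scale_factors"`.
#' @export
spikein_normalize <- function(m) {
  stopifnot(inherits(m, "mirna_counts"))
  if (m$state != "raw") stop("spikein_normalize expects a raw matrix")
  pos <- m$counts[m$probe_class == "positive", , drop = FALSE]
  if (nrow(pos) == 0) stop("no positive-control probes present")
  sums <- colSums(pos)
  if (any(sums == 0)) {
    stop("zero positive-control counts in sample(s): ",
         paste(names(sums)[sums == 0], collapse = ", "))
  }
  f <- geometric_mean(sums) / sums
  out <- m
  out$counts <- sweep(m$counts, 2, f, `*`)
  out$state <- "spikein_normalized"
  attr(out, "scale_factors") <- f
  out
}

#' Quantile normalization
#'
#' Forces every sample to share one empirical value distribution: the value
#' at rank r in each sample is replaced by the mean, across samples, of each
#' sample's rank-r value. Ties within a sample receive the mean of the
#' reference values at the tied ranks, so the result is independent of input
#' ordering.
#'
#' Control probes are technical, not cargo, so only endogenous probes enter
#' the normalization; control rows are carried through unchanged.
#'
#' @param m a [mirna_counts] in `spikein_normalized` state with >= 2
#'   samples, or a plain numeric matrix (columns = samples).
#' @return Same class as the input; for a [mirna_counts], state becomes
#'   `quantile_normalized`.
#' @export
quantile_normalize <- function(m) {
  if (is.matrix(m)) return(quantile_normalize_matrix(m))
  stopifnot(inherits(m, "mirna_counts"))
  if (m$state != "spikein_normalized") {
    stop("quantile_normalize expects a spike-in-normalized matrix")
  }
  if (ncol(m$counts) < 2) stop("quantile normalization needs >= 2 samples")
  endo <- m$probe_class == "endogenous"
  out <- m
  out$counts[endo, ] <- quantile_normalize_matrix(
    m$counts[endo, , drop = FALSE]
  )
  out$state <- "quantile_normalized"
  out
}

quantile_normalize_matrix <- function(x) {
  if (ncol(x) < 2) stop("quantile normalization needs >= 2 samples")
  ref <- rowMeans(apply(x, 2, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    q <- ref[rank(v, ties.method = "first")]
    # ties: average the reference values assigned within each tied group
    out[, j] <- ave(q, match(v, v), FUN = mean)
  }
  out
}
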