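#' miRNA count matrix with control-probe annotation
#'
#' Container for hybridization-based miRNA counts (NanoString-style): a
#' probe-by-sample matrix with a class label per probe (`endogenous`,
#' `positive`, `negative` control) and a condition label per sample. The
#' `state` field tracks the normalization stage: `raw`,
#' `spikein_normalized`, or `quantile_normalized`.
#'
#' @param counts numeric matrix, probes in rows, samples in columns;
#'   nonnegative. Row and column names are required (probe and sample ids).
#' @param probe_class character vector, one of `"endogenous"`, `"positive"`,
#'   `"negative"` per probe.
#' @param condition character vector of condition labels, one per sample.
#' @param state normalization state of `counts`.
#' @return An object of class `mirna_counts`.
#' @export
mirna_counts <- function(counts, probe_class, condition,
                         state = c("raw", "spikein_normalized",
                                   "quantile_normalized")) {
  state <- match.arg(state)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have probe row names and sample column names")
  }
  if (length(probe_class) != nrow(counts)) {
    stop("probe_class must have one entry per probe")
  }
  if (!all(probe_class %in% c("endogenous", "positive", "negative"))) {
    stop("probe_class entries must be endogenous/positive/negative")
  }
  if (length(condition) != ncol(counts)) {
    stop("condition must have one entry per sample")
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and nonnegative")
  }
  structure(
    list(
      counts = counts,
      probe_class = setNames(as.character(probe_class), rownames(counts)),
      condition = setNames(as.character(condition), colnames(counts)),
      state = state
    ),
    class = "mirna_counts"
  )
}

#' @export
print.mirna_counts <- function(x, ...) {
  cat(sprintf(
    "mirna_counts: %d probes (%d endogenous, %d pos ctrl, %d neg ctrl) x %d samples [%s]\n",
    nrow(x$counts),
    sum(x$probe_class == "endogenous"),
    sum(x$probe_class == "positive"),
    sum(x$probe_class == "negative"),
    ncol(x$counts), x$state
  ))
  cat("conditions:", paste(unique(x$condition), collapse = ", "), "\n")
  invisible(x)
}

endogenous_counts <- function(m) {
  m$counts[m$probe_class == "endogenous", , drop = FALSE]
}

#' Write / read a count matrix as TSV plus a YAML condition map
#'
#' The TSV has columns `probe_id`, `probe_class`, then one column per sample;
#' the YAML file maps each sample id to its condition label and records the
#' normalization state.
#'
#' @param m a [mirna_counts] object.
#' @param counts_path path of the TSV to write/read.
#' @param map_path path of the YAML sample-to-condition map; defaults to
#'   `counts_path` with a `.yaml` extension.
#' @return `write_counts` returns the paths invisibly; `read_counts` returns
#'   a [mirna_counts].
#' @export
write_counts <- function(m, counts_path, map_path = NULL) {
  stopifnot(inherits(m, "mirna_counts"))
  map_path <- map_path %||% sub("\\.[^.]*$", ".yaml", counts_path)
  df <- data.frame(
    probe_id = rownames(m$counts),
    probe_class = unname(m$probe_class),
    m$counts,
    check.names = FALSE,
    stringsAsFactors = FALSE
  )
  write.table(df, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(
    list(state = m$state, condition = as.list(m$condition)),
    map_path
  )
  invisible(c(counts = counts_path, map = map_path))
}

#' @rdname write_counts
#' @export
read_counts <- function(counts_path, map_path = NULL) {
  map_path <- map_path %||% sub("\\.[^.]*$", ".yaml", counts_path)
  df <- read.delim(counts_path, check.names = FALSE,
                   stringsAsFactors = FALSE)
  map <- yaml::read_yaml(map_path)
  counts <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(counts) <- df$probe_id
  cond <- unlist(map$condition)[colnames(counts)]
  mirna_counts(counts, df$probe_class, cond, state = map$state)
}
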