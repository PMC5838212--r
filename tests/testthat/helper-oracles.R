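# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths (and, where possible, the
# algorithms) of the package functions they verify.

# Quantile normalization by explicit per-column rank bookkeeping.
oracle_quantile_normalize <- function(x) {
  ref <- rowMeans(sapply(seq_len(ncol(x)), function(j) sort(x[, j])))
  out <- x
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    o <- order(v)
    assigned <- numeric(length(v))
    assigned[o] <- ref
    for (val in unique(v)) {
      g <- v == val
      assigned[g] <- mean(assigned[g])
    }
    out[, j] <- assigned
  }
  out
}

# Naive window search for canonical seed sites: test every UTR window of
# length 6-8 against the four site strings, then drop windows contained in
# a longer matching window.
oracle_seed_scan <- function(utr, mirna) {
  utr <- toupper(chartr("u", "t", tolower(utr)))
  mirna <- toupper(chartr("u", "t", tolower(mirna)))
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  pats <- list(
    "6mer" = rc(substr(mirna, 2, 7)),
    "7mer-A1" = paste0(rc(substr(mirna, 2, 7)), "A"),
    "7mer-m8" = rc(substr(mirna, 2, 8)),
    "8mer" = paste0(rc(substr(mirna, 2, 8)), "A")
  )
  n <- nchar(utr)
  hits <- list()
  for (ty in names(pats)) {
    w <- nchar(pats[[ty]])
    if (n < w) next
    for (s in 0:(n - w)) {
      if (substr(utr, s + 1, s + w) == pats[[ty]]) {
        hits[[length(hits) + 1]] <-
          data.frame(start = s, end = s + w, site_type = ty,
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), end = integer(0),
                      site_type = character(0), stringsAsFactors = FALSE))
  }
  h <- do.call(rbind, hits)
  len <- h$end - h$start
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    for (j in seq_len(nrow(h))) {
      if (len[j] > len[i] && h$start[j] <= h$start[i] &&
          h$end[j] >= h$end[i]) {
        keep[i] <- FALSE
      }
    }
  }
  h <- h[keep, , drop = FALSE]
  h <- h[order(h$start, h$end), , drop = FALSE]
  rownames(h) <- NULL
  h
}

# Exhaustive burst oracle: enumerate candidate spike subintervals, test the
# consecutive-ISI rule with all(), keep the maximal ones.
oracle_bursts <- function(ts, min_spikes = 4, max_isi = 0.1) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      n_spikes = integer(0))
  n <- length(ts)
  if (n < min_spikes) return(empty)
  isi <- diff(ts)
  res <- list()
  for (i in seq_len(n - min_spikes + 1)) {
    for (j in seq(i + min_spikes - 1, n)) {
      if (all(isi[i:(j - 1)] <= max_isi)) {
        extends_left <- i > 1 && isi[i - 1] <= max_isi
        extends_right <- j < n && isi[j] <= max_isi
        if (!extends_left && !extends_right) {
          res[[length(res) + 1]] <-
            data.frame(start = ts[i], end = ts[j], n_spikes = j - i + 1L)
        }
      } else {
        break  # any longer window from i also contains this violating ISI
      }
    }
  }
  if (!length(res)) return(empty)
  out <- unique(do.call(rbind, res))
  rownames(out) <- NULL
  out
}

# Closed-form one-way ANOVA sums of squares.
oracle_anova <- function(values, groups) {
  groups <- as.character(groups)
  grand <- mean(values)
  lv <- unique(groups)
  ss_b <- sum(vapply(lv, function(g) {
    n <- sum(groups == g)
    n * (mean(values[groups == g]) - grand)^2
  }, numeric(1)))
  ss_w <- sum(vapply(lv, function(g) {
    sum((values[groups == g] - mean(values[groups == g]))^2)
  }, numeric(1)))
  df_b <- length(lv) - 1
  df_w <- length(values) - length(lv)
  f <- (ss_b / df_b) / (ss_w / df_w)
  list(ss_between = ss_b, ss_within = ss_w, ss_total = sum((values - grand)^2),
       F = f, p = pf(f, df_b, df_w, lower.tail = FALSE))
}

# Random spike train with ISI mix that produces both bursty and sparse runs.
random_train <- function(n, seed) {
  set.seed(seed)
  isis <- ifelse(runif(n - 1) < 0.6, runif(n - 1, 0.01, 0.1),
                 runif(n - 1, 0.1001, 0.5))
  cumsum(c(runif(1, 0, 0.1), isis))
}

# Measure a filter's gain at one frequency by least-squares fit of a
# steady-state sinusoid.
sine_rec <- function(freq, fs = 25000, dur = 4) {
  t <- seq(0, dur, by = 1 / fs)
  electrode_recording("E", fs, sin(2 * pi * freq * t))
}

measured_gain <- function(freq, spec, fs = 25000) {
  rec <- sine_rec(freq, fs)
  y <- filter_trace(rec, spec)$samples
  t <- seq(0, rec$duration, by = 1 / fs)
  i <- seq(round(length(y) / 2), length(y))  # steady state only
  co <- coef(lm(y[i] ~ sin(2 * pi * freq * t[i]) +
                  cos(2 * pi * freq * t[i]) - 1))
  sqrt(sum(co^2))
}

# Small raw count matrix builder for normalization unit tests.
toy_counts <- function(endo, pos = NULL, neg = NULL, condition = NULL) {
  pos <- pos %||% matrix(100, 1, ncol(endo),
                         dimnames = list("POS_A", colnames(endo)))
  neg <- neg %||% matrix(2, 1, ncol(endo),
                         dimnames = list("NEG_A", colnames(endo)))
  m <- rbind(endo, pos, neg)
  mirna_counts(
    m,
    probe_class = c(rep("endogenous", nrow(endo)),
                    rep("positive", nrow(pos)),
                    rep("negative", nrow(neg))),
    condition = condition %||% colnames(endo),
    state = "raw"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
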