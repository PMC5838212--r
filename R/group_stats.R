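#' One-way ANOVA on grouped per-unit measurements
#'
#' Standard between/within sums-of-squares decomposition with a two-sided p
#' value from the F distribution, fitted via [stats::lm()]. When every
#' group is a constant the within-group variance is zero and the F statistic
#' is undefined; the result is flagged degenerate with `p = NA`.
#'
#' @param data data.frame with one row per unit.
#' @param value name of the numeric measurement column.
#' @param group name of the group-label column.
#' @return One-row data.frame: `F`, `df_between`, `df_within`, `p`,
#'   `ss_between`, `ss_within`, `degenerate`.
#' @export
one_way_anova <- function(data, value = "value", group = "group") {
  g <- factor(data[[group]])
  y <- data[[value]]
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (any(table(g) < 2)) stop("every group needs >= 2 units")
  fit <- lm(y ~ g)
  # degeneracy (zero within-group variance) is detected and flagged below;
  # silence anova()'s own perfect-fit warning
  a <- suppressWarnings(anova(fit))
  ss_b <- a$`Sum Sq`[1]
  ss_w <- a$`Sum Sq`[2]
  degenerate <- ss_w <= .Machine$double.eps * sum(y^2)
  data.frame(
    F = if (degenerate) NA_real_ else a$`F value`[1],
    df_between = a$Df[1], df_within = a$Df[2],
    p = if (degenerate) NA_real_ else a$`Pr(>F)`[1],
    ss_between = ss_b, ss_within = ss_w,
    degenerate = degenerate
  )
}

#' Tukey HSD post hoc comparisons
#'
#' All pairwise group differences with studentized-range adjusted p values
#' (Tukey-Kramer harmonic-mean correction for unbalanced designs, as
#' provided by [stats::TukeyHSD()]).
#'
#' @inheritParams one_way_anova
#' @param alpha significance level for the reject flag.
#' @return data.frame with `contrast`, `diff`, `lwr`, `upr`, `p_adj`,
#'   `reject`.
#' @export
tukey_hsd <- function(data, value = "value", group = "group", alpha = 0.05) {
  g <- factor(data[[group]])
  y <- data[[value]]
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (any(table(g) < 2)) stop("every group needs >= 2 units")
  fit <- aov(y ~ g)
  tk <- TukeyHSD(fit, conf.level = 1 - alpha)$g
  data.frame(
    contrast = rownames(tk),
    diff = tk[, "diff"], lwr = tk[, "lwr"], upr = tk[, "upr"],
    p_adj = tk[, "p adj"],
    reject = tk[, "p adj"] < alpha,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Simulate per-unit morphometric measurements with a planted group shift
#'
#' Gaussian measurements for `k` groups; group `g` is shifted by
#' `shift[g]` pooled SDs from the first (control) group. Used to exercise
#' the ANOVA/Tukey layer with known ground truth.
#'
#' @param n_per_group units per group (recycled over groups).
#' @param shift per-group mean shift in SD units (first entry is the
#'   control, usually 0).
#' @param mean_control,sd control-group mean and common SD.
#' @param seed RNG seed.
#' @return data.frame with `unit`, `group`, `value`.
#' @export
simulate_morphometrics <- function(n_per_group = 15,
                                   shift = c(control = 0, treated = 2),
                                   mean_control = 100, sd = 10, seed = 1) {
  groups <- names(shift) %||% sprintf("g%d", seq_along(shift))
  n <- rep_len(n_per_group, length(shift))
  with_seed(seed, {
    rows <- lapply(seq_along(shift), function(i) {
      data.frame(
        unit = sprintf("%s_%02d", groups[i], seq_len(n[i])),
        group = groups[i],
        value = rnorm(n[i], mean_control + shift[i] * sd, sd),
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
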