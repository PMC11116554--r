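#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up procedure with running-minimum enforcement, delegated to
#' [stats::p.adjust()] after input validation.
#'
#' @param p Numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be numeric in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Cohen's d effect size
#'
#' (mean(a) - mean(b)) / pooled SD, with the pooled SD built from
#' (n - 1)-weighted group variances.
#'
#' @param a,b Numeric vectors (each at least 2 values).
#' @return Numeric scalar; `NA` with a warning when the pooled SD is zero.
#' @export
cohens_d <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) {
    warning("zero pooled SD; Cohen's d undefined")
    return(NA_real_)
  }
  (mean(a) - mean(b)) / sp
}

#' Differential enrichment between two sample groups
#'
#' Per feature: the group-mean score difference (reported as `delta`, the
#' quantity plotted as "LFC" for enrichment scores — scores may be negative,
#' so a literal log-ratio is undefined and the mean difference is the
#' analogue that linear-model pipelines report), a two-sided Wilcoxon
#' rank-sum test (exact enumeration when n1 + n2 <= 12 and there are no
#' ties, otherwise the normal approximation with tie and continuity
#' correction), and Benjamini-Hochberg adjustment across features. A feature
#' constant across both groups gets delta 0 and p 1.
#'
#' @param scores Features x samples numeric matrix.
#' @param group Binary labels (two levels) per sample; the first sorted
#'   level is group 1.
#' @return Data frame: feature, delta, stat (Wilcoxon W), p, p_adj.
#' @export
differential_enrichment <- function(scores, group) {
  scores <- as.matrix(scores)
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly 2 levels")
  if (length(group) != ncol(scores)) stop("one group label per sample")
  if (any(table(group) < 2L)) stop("each group needs >= 2 samples")
  g1 <- group == levels(group)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  res <- t(apply(scores, 1, function(x) {
    a <- x[g1]; b <- x[!g1]
    delta <- mean(a) - mean(b)
    if (stats::sd(x) == 0) return(c(delta = 0, stat = NA_real_, p = 1))
    exact <- (n1 + n2) <= 12 && !anyDuplicated(x)
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE,
                         alternative = "two.sided"))
    c(delta = delta, stat = unname(wt$statistic), p = wt$p.value)
  }))
  data.frame(feature = rownames(scores), delta = res[, "delta"],
             stat = res[, "stat"], p = res[, "p"],
             p_adj = bh_adjust(res[, "p"]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-group linear-model test on precomputed pathway activities
#'
#' Standardizes the activity vector (mean-centered, unit SD) and tests the
#' group difference with a pooled two-sample t-test (the two-group linear
#' model). Intended for externally computed per-sample pathway activities,
#' e.g. signaling-pathway scores.
#'
#' @param activity Numeric per-sample activity vector.
#' @param group Binary labels per sample.
#' @return List: `t` (statistic), `p` (two-sided), `df`.
#' @export
activity_group_test <- function(activity, group) {
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2L, length(activity) == length(group))
  if (any(table(group) < 2L)) stop("each group needs >= 2 samples")
  if (stats::sd(activity) == 0) stop("activity has zero variance")
  z <- as.numeric(scale(activity))
  a <- z[group == levels(group)[1]]
  b <- z[group == levels(group)[2]]
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) /
    (n1 + n2 - 2)
  if (sp2 == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, p = 1, df = n1 + n2 - 2))
    stop("zero residual variance")
  }
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df), df = df)
}
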