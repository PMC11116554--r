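#' Kernel specification for single-sample enrichment scoring
#'
#' Controls the kernel used to estimate each gene's expression CDF across
#' samples, the rank-weight exponent of the random walk, and how the
#' enrichment score is read off the walk.
#'
#' @param kernel `"poisson"` (count data; discrete kernel with offset 0.5) or
#'   `"gaussian"` (continuous log-scale data; bandwidth s_i/4 per gene).
#' @param tau Non-negative weight exponent on the rank statistic (default 1).
#' @param es_mode `"diff_extremes"` (score = max positive deviation + min
#'   negative deviation of the walk; the conventional default) or
#'   `"max_deviation"` (walk value at its largest absolute deviation).
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(kernel = c("poisson", "gaussian"), tau = 1,
                        es_mode = c("diff_extremes", "max_deviation")) {
  kernel <- match.arg(kernel)
  es_mode <- match.arg(es_mode)
  stopifnot(is.numeric(tau), length(tau) == 1L, is.finite(tau), tau >= 0)
  structure(list(kernel = kernel, tau = tau, es_mode = es_mode),
            class = "kernel_spec")
}

#' Kernel estimate of per-gene expression CDFs
#'
#' For each gene i and sample j, estimates F(x_ij), the cumulative
#' distribution of gene i's expression evaluated at sample j, by averaging a
#' kernel CDF centred at every sample's value:
#' Gaussian: Fhat_ij = mean_k Phi((x_ij - x_ik) / h_i) with bandwidth
#' h_i = s_i / 4 (s_i the sample SD of gene i; a constant gene gets
#' Fhat = 0.5 everywhere). Poisson: Fhat_ij = mean_k F_Pois(floor(x_ij);
#' lambda = x_ik + 0.5); the floor makes the discrete kernel well-defined on
#' non-integer normalized counts.
#'
#' @param expr An [expression_matrix()].
#' @param spec A [kernel_spec()].
#' @return Numeric genes x samples matrix of Fhat values.
#' @export
kernel_cdf <- function(expr, spec = kernel_spec()) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(spec, "kernel_spec"))
  x <- expr$values
  n <- ncol(x)
  if (spec$kernel == "poisson") {
    if (any(x < 0)) stop("poisson kernel requires non-negative values")
    out <- x
    fl <- floor(x)
    for (i in seq_len(nrow(x))) {
      lam <- x[i, ] + 0.5
      # n x n: rows = evaluation points floor(x_ij), cols = kernel centres
      out[i, ] <- rowMeans(stats::ppois(matrix(fl[i, ], n, n),
                                        matrix(lam, n, n, byrow = TRUE)))
    }
  } else {
    if (expr$value_kind == "counts")
      warning("gaussian kernel on count data; consider kernel = 'poisson'")
    out <- x
    for (i in seq_len(nrow(x))) {
      xi <- x[i, ]
      h <- stats::sd(xi) / 4
      if (!is.finite(h) || h == 0) {
        out[i, ] <- 0.5
      } else {
        out[i, ] <- rowMeans(stats::pnorm(outer(xi, xi, "-") / h))
      }
    }
  }
  out
}

#' Rank statistic of the kernel CDF matrix
#'
#' Within each sample, genes are ranked 1..p with rank 1 for the largest
#' Fhat (ties broken by ascending gene index, so results are deterministic),
#' and the rank statistic is r_ij = |p/2 - rank_ij|: largest at the two
#' extremes of the ranking, zero mid-list.
#'
#' @param Fhat Genes x samples matrix from [kernel_cdf()].
#' @return A list with `order` (genes x samples integer matrix; column j
#'   holds the gene indices of sample j's walk order, most enriched first)
#'   and `r` (genes x samples matrix of rank statistics, in gene order).
#' @export
rank_statistic <- function(Fhat) {
  stopifnot(is.matrix(Fhat), all(is.finite(Fhat)))
  p <- nrow(Fhat)
  ord <- matrix(0L, p, ncol(Fhat))
  rnk <- matrix(0, p, ncol(Fhat))
  for (j in seq_len(ncol(Fhat))) {
    o <- order(Fhat[, j], decreasing = TRUE)  # stable: ties by gene index
    ord[, j] <- o
    rank_j <- integer(p)
    rank_j[o] <- seq_len(p)
    rnk[, j] <- abs(p / 2 - rank_j)
  }
  dimnames(rnk) <- dimnames(Fhat)
  list(order = ord, r = rnk)
}

# Enrichment score of one walk. positions: sorted positions (1..p) of the
# set's genes in the walk order; w: their rank-statistic weights r^tau in the
# same order; p: total genes. Between hits the walk decreases linearly, so
# its running extrema occur just after a hit (maxima) or just before the next
# hit / at the end (minima); the final value is exactly 0.
.walk_es <- function(positions, w, p, es_mode) {
  m <- length(positions)
  denom <- sum(w)
  if (denom <= 0) {
    warning("gene set has zero total rank weight; score set to 0")
    return(0)
  }
  miss <- 1 / (p - m)
  cw <- cumsum(w) / denom
  idx <- seq_len(m)
  after <- cw - (positions - idx) * miss
  before <- c(0, cw[-m]) - (positions - 1 - (idx - 1)) * miss
  vmax <- max(after, 0)
  vmin <- min(before, 0)
  if (es_mode == "diff_extremes") {
    max(vmax, 0) + min(vmin, 0)
  } else {
    if (vmax >= -vmin) vmax else vmin
  }
}

#' Single-sample pathway enrichment scores (kernel-CDF random walk)
#'
#' Full reconstruction of the GSVA-style scoring algorithm: per-gene kernel
#' CDF estimation across samples, per-sample ranking, and a weighted
#' Kolmogorov-Smirnov-like random walk over each sample's ranking restricted
#' to each gene set. At walk position l the statistic is
#' nu(l) = sum of in-set weights r^tau up to l (normalized) minus the
#' fraction of out-of-set genes passed, and the enrichment score is read off
#' per `spec$es_mode`. Scores are bounded in [-1, 1].
#'
#' @param expr An [expression_matrix()].
#' @param coll A [gene_set_collection()].
#' @param spec A [kernel_spec()].
#' @param min_size,max_size Effective set-size bounds applied after
#'   intersecting sets with the measured genes (defaults 9 and 300).
#' @return An object of class `enrichment_matrix`: list with `scores`
#'   (pathways x samples), `effective_sizes`, `spec`, and the `dropped` set
#'   report from filtering.
#' @export
gsva_scores <- function(expr, coll, spec = kernel_spec(),
                        min_size = 9, max_size = 300) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(coll, "gene_set_collection"))
  genes <- rownames(expr$values)
  p <- length(genes)
  coll_f <- filter_by_size(coll, genes, min_size = min_size,
                           max_size = max_size)
  if (length(coll_f$sets) == 0L)
    stop("no gene set survives size filtering")
  if (any(lengths(coll_f$sets) >= p))
    stop("a gene set covers all measured genes; out-of-set walk undefined")
  Fhat <- kernel_cdf(expr, spec)
  rk <- rank_statistic(Fhat)
  n <- ncol(expr$values)
  m_sets <- length(coll_f$sets)
  set_idx <- lapply(coll_f$sets, function(g) match(g, genes))
  scores <- matrix(NA_real_, m_sets, n,
                   dimnames = list(names(coll_f$sets),
                                   colnames(expr$values)))
  for (j in seq_len(n)) {
    pos_of_gene <- integer(p)
    pos_of_gene[rk$order[, j]] <- seq_len(p)
    rtau <- rk$r[, j]^spec$tau
    for (s in seq_len(m_sets)) {
      pos <- sort(pos_of_gene[set_idx[[s]]])
      w <- rtau[rk$order[pos, j]]
      scores[s, j] <- .walk_es(pos, w, p, spec$es_mode)
    }
  }
  structure(
    list(scores = scores,
         effective_sizes = lengths(coll_f$sets),
         categories = stats::setNames(coll_f$categories,
                                      names(coll_f$sets)),
         spec = spec,
         dropped = attr(coll_f, "dropped")),
    class = "enrichment_matrix"
  )
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat("Enrichment matrix:", nrow(x$scores), "pathways x", ncol(x$scores),
      "samples; kernel =", x$spec$kernel, ", tau =", x$spec$tau,
      ", es_mode =", x$spec$es_mode, "\n")
  invisible(x)
}

#' Score a single gene signature per sample
#'
#' Identical to [gsva_scores()] on a one-set collection with size bounds
#' (2, p - 1); used for prognostic signatures quantified the same way as
#' pathways.
#'
#' @param expr An [expression_matrix()].
#' @param genes Character vector of signature genes.
#' @param spec A [kernel_spec()].
#' @param name Signature name used in the output.
#' @return Named numeric vector of per-sample scores.
#' @export
score_signature <- function(expr, genes, spec = kernel_spec(),
                            name = "signature") {
  measured <- sum(unique(trimws(genes)) %in% rownames(expr$values))
  if (measured < 2L)
    stop("signature has fewer than 2 measured genes")
  coll <- gene_set_collection(stats::setNames(list(genes), name))
  em <- gsva_scores(expr, coll, spec, min_size = 2,
                    max_size = nrow(expr$values) - 1L)
  em$scores[1, ]
}

#' Pre-ranked gene set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov running sum on genes sorted by
#' decreasing statistic: hit increments proportional to |stat|^weight
#' (normalized), miss increments 1/(p - set size); the enrichment score is
#' the walk value at its maximum absolute deviation. P-values come from
#' seeded gene-label permutations with a sign-matched tail and +1 smoothing
#' in both numerator and denominator; Benjamini-Hochberg adjustment is
#' applied across sets.
#'
#' @param stat Named numeric vector of per-gene ranking statistics.
#' @param coll A [gene_set_collection()].
#' @param weight Exponent on |stat| for hit increments (default 1).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer RNG seed.
#' @param min_size Minimum number of measured set genes (default 2).
#' @return Data frame: set, size, ES, p, p_adj.
#' @export
preranked_gsea <- function(stat, coll, weight = 1, n_perm = 1000, seed = 1,
                           min_size = 2) {
  stopifnot(is.numeric(stat), !is.null(names(stat)), all(is.finite(stat)),
            inherits(coll, "gene_set_collection"))
  if (anyDuplicated(names(stat))) stop("duplicate gene ids in stat")
  p <- length(stat)
  ord <- order(stat, decreasing = TRUE)
  stat_sorted <- stat[ord]
  genes_sorted <- names(stat_sorted)
  absw <- abs(stat_sorted)^weight

  es_for_positions <- function(pos) {
    m <- length(pos)
    hit <- numeric(p)
    hit[pos] <- absw[pos]
    tot <- sum(hit)
    inc_hit <- if (tot > 0) hit / tot else {
      h <- numeric(p); h[pos] <- 1 / m; h
    }
    inc_miss <- numeric(p)
    inc_miss[-pos] <- 1 / (p - m)
    walk <- cumsum(inc_hit - inc_miss)
    walk[which.max(abs(walk))]
  }

  sizes <- integer(0)
  keep <- character(0)
  es <- numeric(0)
  pos_list <- list()
  for (nm in names(coll$sets)) {
    pos <- which(genes_sorted %in% coll$sets[[nm]])
    if (length(pos) < min_size) next
    if (length(pos) >= p) stop("gene set '", nm, "' covers all genes")
    keep <- c(keep, nm)
    sizes <- c(sizes, length(pos))
    pos_list[[nm]] <- pos
    es <- c(es, es_for_positions(pos))
  }
  if (length(keep) == 0L) stop("no set with >= min_size measured genes")

  set.seed(as.integer(seed))
  usz <- sort(unique(sizes))
  perm_by_size <- lapply(usz, function(m)
    vapply(seq_len(n_perm),
           function(b) es_for_positions(sort(sample.int(p, m))), 0))
  names(perm_by_size) <- as.character(usz)

  pval <- vapply(seq_along(keep), function(i) {
    null_es <- perm_by_size[[as.character(sizes[i])]]
    if (es[i] >= 0) {
      (1 + sum(null_es >= es[i])) / (1 + sum(null_es >= 0))
    } else {
      (1 + sum(null_es <= es[i])) / (1 + sum(null_es < 0))
    }
  }, 0)
  data.frame(set = keep, size = sizes, ES = es, p = pval,
             p_adj = bh_adjust(pval), stringsAsFactors = FALSE,
             row.names = NULL)
}
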