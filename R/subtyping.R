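# ---- clustering utilities ----------------------------------------------

#' Seeded k-means with many restarts
#'
#' Thin deterministic wrapper around [stats::kmeans()] with the settings used
#' for subtype discovery: 100 random starts and up to 100 iterations.
#'
#' @param M Observations x features numeric matrix.
#' @param k Number of clusters.
#' @param n_init Number of random initializations (default 100).
#' @param max_iter Iteration cap (default 100).
#' @param seed Integer RNG seed.
#' @return A list: `labels` (integer vector), `centers`, `within_ss`
#'   (total within-cluster sum of squares).
#' @export
mps_kmeans <- function(M, k, n_init = 100, max_iter = 100, seed = 1) {
  M <- as.matrix(M)
  n_distinct <- nrow(unique(M))
  if (k > n_distinct)
    stop("k = ", k, " exceeds the number of distinct observations (",
         n_distinct, ")")
  if (k == n_distinct) {
    centers <- unique(M)
    labels <- apply(M, 1, function(r)
      which.min(colSums((t(centers) - r)^2)))
    return(list(labels = as.integer(labels), centers = centers,
                within_ss = 0))
  }
  set.seed(as.integer(seed))
  km <- suppressWarnings(
    stats::kmeans(M, centers = k, iter.max = max_iter, nstart = n_init)
  )
  list(labels = as.integer(km$cluster), centers = km$centers,
       within_ss = km$tot.withinss)
}

# total within-cluster sum of squares of a labeled partition
.wss <- function(M, labels) {
  s <- 0
  for (g in unique(labels)) {
    X <- M[labels == g, , drop = FALSE]
    if (nrow(X) > 1L) {
      c0 <- colMeans(X)
      s <- s + sum(sweep(X, 2, c0)^2)
    }
  }
  s
}

# between-cluster sum of squares
.bss <- function(M, labels) {
  c_all <- colMeans(M)
  s <- 0
  for (g in unique(labels)) {
    X <- M[labels == g, , drop = FALSE]
    s <- s + nrow(X) * sum((colMeans(X) - c_all)^2)
  }
  s
}

# ---- cluster-validity index registry -----------------------------------

.index_silhouette <- function(M, labels, D) {
  n <- nrow(M)
  k <- length(unique(labels))
  if (k < 2L || k >= n) return(NA_real_)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(g) mean(D[i, labels == g]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

.index_ch <- function(M, labels) {
  n <- nrow(M); k <- length(unique(labels))
  if (k < 2L || k >= n) return(NA_real_)
  W <- .wss(M, labels)
  if (W == 0) return(Inf)
  (.bss(M, labels) / (k - 1)) / (W / (n - k))
}

.index_db <- function(M, labels) {
  gs <- sort(unique(labels))
  k <- length(gs)
  if (k < 2L) return(NA_real_)
  cent <- t(vapply(gs, function(g) colMeans(M[labels == g, , drop = FALSE]),
                   numeric(ncol(M))))
  S <- vapply(seq_len(k), function(i) {
    X <- M[labels == gs[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(X, 2, cent[i, ])^2)))
  }, 0)
  Dc <- as.matrix(stats::dist(cent))
  mean(vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i),
               function(j) (S[i] + S[j]) / Dc[i, j], 0))
  }, 0))
}

.index_dunn <- function(M, labels, D) {
  gs <- sort(unique(labels))
  if (length(gs) < 2L) return(NA_real_)
  diam <- max(vapply(gs, function(g) {
    idx <- which(labels == g)
    if (length(idx) < 2L) 0 else max(D[idx, idx])
  }, 0))
  if (diam == 0) return(Inf)
  sep <- min(vapply(utils::combn(gs, 2, simplify = FALSE), function(pr) {
    min(D[labels == pr[1], labels == pr[2], drop = FALSE])
  }, 0))
  sep / diam
}

.index_ptbiserial <- function(M, labels, D) {
  n <- nrow(M)
  dv <- D[upper.tri(D)]
  between <- outer(labels, labels, "!=")[upper.tri(D)]
  if (length(unique(between)) < 2L) return(NA_real_)
  stats::cor(dv, as.numeric(between))
}

.index_mcclain <- function(M, labels, D) {
  ut <- upper.tri(D)
  dv <- D[ut]
  same <- outer(labels, labels, "==")[ut]
  nw <- sum(same); nb <- sum(!same)
  if (nw == 0 || nb == 0) return(NA_real_)
  sb <- sum(dv[!same])
  if (sb == 0) return(NA_real_)
  (sum(dv[same]) / nw) / (sb / nb)
}

.index_sd_scat_dis <- function(M, labels) {
  gs <- sort(unique(labels))
  k <- length(gs)
  var_all <- apply(M, 2, stats::var)
  scat <- mean(vapply(gs, function(g) {
    X <- M[labels == g, , drop = FALSE]
    v <- if (nrow(X) > 1L) apply(X, 2, stats::var) else rep(0, ncol(M))
    sqrt(sum(v^2))
  }, 0)) / sqrt(sum(var_all^2))
  cent <- t(vapply(gs, function(g) colMeans(M[labels == g, , drop = FALSE]),
                   numeric(ncol(M))))
  Dc <- as.matrix(stats::dist(cent))
  dmax <- max(Dc); dmin <- min(Dc[Dc > 0])
  dis <- (dmax / dmin) * sum(1 / colSums(Dc))
  c(scat = scat, dis = dis)
}

#' Cluster-validity indices over a range of k
#'
#' Computes the 10-index core registry (silhouette, Calinski-Harabasz,
#' Davies-Bouldin, Dunn, Hartigan, Krzanowski-Lai, gap statistic,
#' point-biserial, McClain-Rao, SD index) on a set of partitions of the same
#' data, one per candidate k. Indices whose definition needs a neighbouring
#' partition (Hartigan, Krzanowski-Lai) are NA at grid boundaries where the
#' neighbour is missing; `k - 1 = 1` uses the trivial one-cluster partition.
#'
#' @param M Observations x features matrix.
#' @param labels_by_k Named list mapping each k (as character) to an integer
#'   label vector of `nrow(M)` entries.
#' @param seed Seed for the gap statistic's uniform reference draws.
#' @param n_ref Number of gap reference data sets (default 20).
#' @return Numeric matrix index x k of values, with attribute `rules`
#'   (named character vector of best-k rules).
#' @export
validity_indices <- function(M, labels_by_k, seed = 1, n_ref = 20) {
  M <- as.matrix(M)
  ks <- sort(as.integer(names(labels_by_k)))
  stopifnot(all(ks >= 2), all(vapply(labels_by_k, length, 0L) == nrow(M)))
  D <- as.matrix(stats::dist(M))
  n <- nrow(M); d <- ncol(M)
  kc <- as.character(ks)

  W <- stats::setNames(vapply(kc, function(k) .wss(M, labels_by_k[[k]]), 0), kc)
  W1 <- .wss(M, rep(1L, n))

  idx_names <- c("silhouette", "calinski_harabasz", "davies_bouldin", "dunn",
                 "hartigan", "krzanowski_lai", "gap", "point_biserial",
                 "mcclain_rao", "sd_index")
  out <- matrix(NA_real_, length(idx_names), length(ks),
                dimnames = list(idx_names, kc))

  sd_parts <- lapply(kc, function(k) .index_sd_scat_dis(M, labels_by_k[[k]]))
  names(sd_parts) <- kc
  alpha <- sd_parts[[kc[length(kc)]]]["dis"]

  # gap statistic: uniform reference over the ranges of each feature,
  # clustered with the same algorithm at each k
  set.seed(as.integer(seed))
  rngs <- apply(M, 2, range)
  log_wstar <- matrix(NA_real_, n_ref, length(ks), dimnames = list(NULL, kc))
  for (b in seq_len(n_ref)) {
    R <- vapply(seq_len(d),
                function(j) stats::runif(n, rngs[1, j], rngs[2, j]),
                numeric(n))
    for (k in kc) {
      kmref <- suppressWarnings(
        stats::kmeans(R, centers = as.integer(k), iter.max = 100, nstart = 5))
      log_wstar[b, k] <- log(kmref$tot.withinss)
    }
  }
  gap <- colMeans(log_wstar) - log(pmax(W, .Machine$double.xmin))
  gap_se <- apply(log_wstar, 2, stats::sd) * sqrt(1 + 1 / n_ref)

  for (i in seq_along(ks)) {
    k <- kc[i]; lab <- labels_by_k[[k]]
    nk <- length(unique(lab))
    singleton_only <- all(tabulate(lab) <= 1L)
    out["silhouette", k] <- .index_silhouette(M, lab, D)
    out["calinski_harabasz", k] <- .index_ch(M, lab)
    out["davies_bouldin", k] <- if (singleton_only) NA_real_ else
      .index_db(M, lab)
    out["dunn", k] <- .index_dunn(M, lab, D)
    out["point_biserial", k] <- .index_ptbiserial(M, lab, D)
    out["mcclain_rao", k] <- .index_mcclain(M, lab, D)
    out["sd_index", k] <- alpha * sd_parts[[k]]["scat"] +
      sd_parts[[k]]["dis"]
    out["gap", k] <- gap[k]
    if (i < length(ks) && ks[i + 1] == ks[i] + 1L && W[kc[i + 1]] > 0)
      out["hartigan", k] <- (W[k] / W[kc[i + 1]] - 1) * (n - ks[i] - 1)
    # Krzanowski-Lai needs W at k-1, k, k+1
    Wm1 <- if (ks[i] == 2L) W1 else if (i > 1 && ks[i - 1] == ks[i] - 1L)
      W[kc[i - 1]] else NA_real_
    Wp1 <- if (i < length(ks) && ks[i + 1] == ks[i] + 1L) W[kc[i + 1]] else
      NA_real_
    if (is.finite(Wm1) && is.finite(Wp1)) {
      diff_k <- (ks[i] - 1)^(2 / d) * Wm1 - ks[i]^(2 / d) * W[k]
      diff_k1 <- ks[i]^(2 / d) * W[k] - (ks[i] + 1)^(2 / d) * Wp1
      out["krzanowski_lai", k] <- if (diff_k1 != 0)
        abs(diff_k / diff_k1) else NA_real_
    }
  }
  attr(out, "gap_se") <- gap_se
  attr(out, "rules") <- c(
    silhouette = "max", calinski_harabasz = "max", davies_bouldin = "min",
    dunn = "max", hartigan = "hartigan", krzanowski_lai = "max",
    gap = "gap_1se", point_biserial = "max", mcclain_rao = "min",
    sd_index = "min"
  )
  out
}

# modal vote; ties resolved toward the smallest tied k
.consensus_vote <- function(votes) {
  cnt <- table(votes)
  min(as.integer(names(cnt)[cnt == max(cnt)]))
}

# apply one index's best-k rule; returns chosen k or NA
.best_k <- function(vals, rule, ks, gap_se = NULL) {
  ok <- is.finite(vals)
  if (!any(ok)) return(NA_integer_)
  switch(rule,
    max = ks[which(vals == max(vals[ok]) & ok)[1L]],
    min = ks[which(vals == min(vals[ok]) & ok)[1L]],
    hartigan = {
      low <- which(ok & vals <= 10)
      if (length(low)) ks[low[1L]] else ks[which.min(replace(vals, !ok, Inf))]
    },
    gap_1se = {
      for (i in seq_along(ks)) {
        if (!ok[i]) next
        if (i == length(ks)) return(ks[i])
        if (is.finite(vals[i + 1]) &&
            vals[i] >= vals[i + 1] - gap_se[i + 1]) return(ks[i])
      }
      ks[which.max(replace(vals, !ok, -Inf))]
    },
    stop("unknown rule: ", rule)
  )
}

#' Consensus selection of the number of clusters
#'
#' Runs seeded k-means for each k in `[k_min, k_max]`, computes the validity
#' index registry, lets each index cast one vote for its preferred k via its
#' own rule, and returns the modal k (ties resolved toward the smallest tied
#' k). Indices undefined over the whole grid abstain.
#'
#' @param M Observations x features matrix.
#' @param k_min,k_max Grid bounds (defaults 2 and 10).
#' @param seed Integer RNG seed (drives k-means restarts and gap references).
#' @param n_init Random starts per k-means run.
#' @return A list: `k` (chosen k), `votes` (named integer vector of per-index
#'   votes), `index_values` (the registry table), `labels_by_k`.
#' @export
select_optimal_k <- function(M, k_min = 2, k_max = 10, seed = 1,
                             n_init = 100) {
  stopifnot(k_max >= k_min, k_min >= 2)
  M <- as.matrix(M)
  k_max <- min(k_max, nrow(unique(M)) - 1L)
  if (k_max < k_min) stop("too few distinct observations for k_min")
  ks <- k_min:k_max
  labels_by_k <- lapply(ks, function(k)
    mps_kmeans(M, k, n_init = n_init, seed = seed + k)$labels)
  names(labels_by_k) <- as.character(ks)
  tab <- validity_indices(M, labels_by_k, seed = seed)
  rules <- attr(tab, "rules")
  gap_se <- attr(tab, "gap_se")
  votes <- vapply(rownames(tab), function(ix)
    .best_k(tab[ix, ], rules[[ix]], ks, gap_se), 0L)
  votes <- votes[!is.na(votes)]
  if (length(votes) == 0L) stop("all validity indices undefined")
  list(k = .consensus_vote(votes), votes = votes, index_values = tab,
       labels_by_k = labels_by_k)
}

# ---- subtype model ------------------------------------------------------

#' Discover metabolic pathway-based subtypes
#'
#' Clusters samples on their pathway enrichment profiles with k-means. When
#' `k` is not forced, the number of clusters is chosen by the consensus vote
#' of the validity-index registry over `[k_min, k_max]`. Cluster identities
#' are mapped to stable subtype names deterministically: the cluster with the
#' highest centroid value of the `anchor` pathway (or the highest mean over a
#' category's pathways) becomes MPS1, and the remaining clusters are ordered
#' by decreasing overall centroid mean (MPS2 before MPS3, ...). Without an
#' anchor all clusters are ordered by decreasing overall centroid mean.
#'
#' @param E An `enrichment_matrix` from [gsva_scores()], or a plain
#'   pathways x samples numeric matrix.
#' @param k Optional forced number of clusters (>= 2). When `NULL` the
#'   consensus vote decides.
#' @param anchor Pathway id or category label anchoring the MPS1 name;
#'   `NULL` for ordering by overall centroid mean only.
#' @param seed Integer RNG seed.
#' @param k_min,k_max Consensus grid when `k` is `NULL`.
#' @return An object of class `mps_model`: `k`, `labels` (named character,
#'   MPS1..MPSk), `centroids` (pathways x subtypes), `votes`, `seed`,
#'   `anchor`, `within_ss`.
#' @export
discover_subtypes <- function(E, k = NULL, anchor = NULL, seed = 1,
                              k_min = 2, k_max = 10) {
  scores <- if (inherits(E, "enrichment_matrix")) E$scores else as.matrix(E)
  if (nrow(scores) < 1L || ncol(scores) < 2L) stop("empty enrichment matrix")
  categories <- if (inherits(E, "enrichment_matrix")) E$categories else NULL
  M <- t(scores)  # samples x pathways
  votes <- NULL
  if (is.null(k)) {
    sel <- select_optimal_k(M, k_min = k_min, k_max = k_max, seed = seed)
    k <- sel$k
    votes <- sel$votes
    km <- list(labels = sel$labels_by_k[[as.character(k)]])
    km$within_ss <- .wss(M, km$labels)
  } else {
    if (k < 2) stop("subtyping requires k >= 2")
    km <- mps_kmeans(M, k, seed = seed + k)
  }
  raw <- km$labels
  cent <- vapply(seq_len(k), function(g)
    colMeans(M[raw == g, , drop = FALSE]), numeric(ncol(M)))
  rownames(cent) <- rownames(scores)

  anchor_val <- NULL
  if (!is.null(anchor)) {
    if (anchor %in% rownames(scores)) {
      anchor_val <- cent[anchor, ]
    } else if (!is.null(categories) && anchor %in% categories) {
      anchor_val <- colMeans(cent[names(categories)[categories == anchor], ,
                                  drop = FALSE])
    } else {
      stop("anchor '", anchor, "' is neither a pathway nor a category")
    }
  }
  overall <- colMeans(cent)
  if (is.null(anchor_val)) {
    ord <- order(overall, decreasing = TRUE)
  } else {
    first <- which.max(anchor_val)
    rest <- setdiff(seq_len(k), first)
    ord <- c(first, rest[order(overall[rest], decreasing = TRUE)])
  }
  new_names <- paste0("MPS", seq_len(k))
  relabel <- character(k)
  relabel[ord] <- new_names
  labels <- stats::setNames(relabel[raw], colnames(scores))
  centroids <- cent[, ord, drop = FALSE]
  colnames(centroids) <- new_names

  structure(
    list(k = k, labels = labels, centroids = centroids,
         votes = if (is.null(votes)) "bypassed (k forced)" else votes,
         seed = seed, anchor = anchor, within_ss = km$within_ss),
    class = "mps_model"
  )
}

#' @export
print.mps_model <- function(x, ...) {
  cat("MPS subtype model: k =", x$k, "over", nrow(x$centroids),
      "pathways,", length(x$labels), "samples\n")
  print(table(x$labels))
  if (!is.character(x$votes)) {
    cat("Consensus votes:\n")
    print(x$votes)
  } else cat("Consensus:", x$votes, "\n")
  invisible(x)
}

#' @export
summary.mps_model <- function(object, ...) {
  cat("Subtype sizes:\n"); print(table(object$labels))
  cat("\nTop discriminating pathways (range of centroid values):\n")
  rng <- apply(object$centroids, 1, function(z) diff(range(z)))
  print(utils::head(object$centroids[order(rng, decreasing = TRUE), ,
                                     drop = FALSE], 10))
  invisible(object)
}

#' Merge enrichment matrices from several batches
#'
#' Column-concatenates score matrices after aligning pathway rows; sample ids
#' must be disjoint across batches. Batch provenance is kept per sample in
#' the `batch` element so a merged matrix can be split back.
#'
#' @param ... Two or more `enrichment_matrix` objects (or a single list of
#'   them). Empty (0-sample) matrices are allowed and ignored.
#' @return A merged `enrichment_matrix` with a `batch` character vector.
#' @export
merge_score_matrices <- function(...) {
  args <- list(...)
  if (length(args) == 1L && !inherits(args[[1]], "enrichment_matrix"))
    args <- args[[1]]
  stopifnot(length(args) >= 1L,
            all(vapply(args, inherits, TRUE, "enrichment_matrix")))
  nonempty <- args[vapply(args, function(e) ncol(e$scores) > 0L, TRUE)]
  if (length(nonempty) == 0L) stop("all batches are empty")
  ref <- nonempty[[1]]
  ref_paths <- rownames(ref$scores)
  for (e in nonempty[-1]) {
    pths <- rownames(e$scores)
    if (!setequal(pths, ref_paths)) {
      diffs <- c(setdiff(ref_paths, pths), setdiff(pths, ref_paths))
      stop("pathway sets differ between batches: ",
           paste(utils::head(diffs, 10), collapse = ", "))
    }
  }
  all_samples <- unlist(lapply(nonempty, function(e) colnames(e$scores)))
  if (anyDuplicated(all_samples))
    stop("sample ids must be disjoint across batches")
  scores <- do.call(cbind, lapply(nonempty, function(e)
    e$scores[ref_paths, , drop = FALSE]))
  batch <- unlist(lapply(seq_along(nonempty), function(i)
    rep(paste0("batch", i), ncol(nonempty[[i]]$scores))))
  names(batch) <- all_samples
  out <- ref
  out$scores <- scores
  out$batch <- batch
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples;
#' 1 for identical partitions, around 0 for independent ones.
#'
#' @param a,b Label vectors of equal length (any types coercible to factor).
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  mx <- (si + sj) / 2
  if (mx == expected) return(0)
  (sij - expected) / (mx - expected)
}
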