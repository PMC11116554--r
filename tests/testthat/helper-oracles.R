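# Independent naive-loop oracles used to cross-check the package's
# implementations. Deliberately written as plain loops over the defining
# formulas, sharing no code with the package internals.

oracle_kcdf <- function(x, kernel = c("poisson", "gaussian")) {
  kernel <- match.arg(kernel)
  p <- nrow(x); n <- ncol(x)
  out <- matrix(0, p, n)
  for (i in seq_len(p)) {
    for (j in seq_len(n)) {
      acc <- 0
      if (kernel == "poisson") {
        for (k in seq_len(n))
          acc <- acc + ppois(floor(x[i, j]), lambda = x[i, k] + 0.5)
      } else {
        h <- sd(x[i, ]) / 4
        if (h == 0) { acc <- n * 0.5 } else {
          for (k in seq_len(n)) acc <- acc + pnorm((x[i, j] - x[i, k]) / h)
        }
      }
      out[i, j] <- acc / n
    }
  }
  dimnames(out) <- dimnames(x)
  out
}

# full random-walk enrichment scores by brute force (per-position cumsum)
oracle_gsva <- function(x, sets, kernel = "poisson", tau = 1,
                        es_mode = "diff_extremes") {
  Fhat <- oracle_kcdf(x, kernel)
  p <- nrow(x); n <- ncol(x)
  out <- matrix(0, length(sets), n,
                dimnames = list(names(sets), colnames(x)))
  for (j in seq_len(n)) {
    ord <- order(Fhat[, j], decreasing = TRUE)
    rank_of <- integer(p); rank_of[ord] <- seq_len(p)
    r <- abs(p / 2 - rank_of)
    for (s in seq_along(sets)) {
      in_set <- rownames(x) %in% sets[[s]]
      m <- sum(in_set)
      denom <- sum(r[in_set]^tau)
      nu <- numeric(p)
      run <- 0
      for (l in seq_len(p)) {
        g <- ord[l]
        run <- run + if (in_set[g]) r[g]^tau / denom else -1 / (p - m)
        nu[l] <- run
      }
      out[s, j] <- if (es_mode == "diff_extremes") {
        max(c(nu, 0)[c(nu, 0) >= 0]) + min(c(nu, 0)[c(nu, 0) <= 0])
      } else {
        nu[which.max(abs(nu))]
      }
    }
  }
  out
}

# weighted KS enrichment score for a set of positions in a sorted gene list
oracle_preranked_es <- function(stat_sorted, pos, weight = 1) {
  p <- length(stat_sorted)
  m <- length(pos)
  run <- 0; best <- 0
  tot <- sum(abs(stat_sorted[pos])^weight)
  for (l in seq_len(p)) {
    run <- run + if (l %in% pos) abs(stat_sorted[l])^weight / tot else
      -1 / (p - m)
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# Efron partial log-likelihood for a single covariate, by direct summation
oracle_efron_loglik <- function(beta, times, events, x) {
  eta <- exp(beta * x)
  ll <- 0
  for (tt in sort(unique(times[events == 1]))) {
    D <- which(times == tt & events == 1)
    R <- which(times >= tt)
    d <- length(D)
    sR <- sum(eta[R]); sD <- sum(eta[D])
    ll <- ll + beta * sum(x[D])
    for (l in 0:(d - 1)) ll <- ll - log(sR - (l / d) * sD)
  }
  ll
}

# log-rank statistic summing hypergeometric moments term by term
oracle_logrank <- function(times, events, group) {
  g1 <- group == sort(unique(group))[1]
  O <- 0; E <- 0; V <- 0
  for (tt in sort(unique(times[events == 1]))) {
    at_risk <- times >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(times == tt & events == 1)
    d1 <- sum(times == tt & events == 1 & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Harrell's C by explicit pair loop
oracle_cindex <- function(risk, times, events) {
  n <- length(risk)
  conc <- 0; usable <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (times[i] < times[j] && events[i] == 1) {
      usable <- usable + 1
      if (risk[i] > risk[j]) conc <- conc + 1
      else if (risk[i] == risk[j]) conc <- conc + 0.5
    }
  }
  list(c = conc / usable, n_pairs = usable)
}

# samples x features Gaussian blobs with known labels
make_blobs <- function(n_per, centers, sd = 1, seed = 1) {
  set.seed(seed)
  k <- nrow(centers)
  X <- do.call(rbind, lapply(seq_len(k), function(i)
    matrix(rnorm(n_per * ncol(centers), 0, sd), n_per) +
      matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)))
  list(X = X, labels = rep(seq_len(k), each = n_per))
}

# small random expression_matrix with named genes/samples
make_expr <- function(p, n, seed = 1, kind = "counts") {
  set.seed(seed)
  v <- if (kind == "counts")
    matrix(rnbinom(p * n, size = 3, mu = 60), p, n) else
    matrix(rnorm(p * n, 5, 2), p, n)
  dimnames(v) <- list(sprintf("g%03d", 1:p), sprintf("s%02d", 1:n))
  expression_matrix(v, value_kind = kind)
}
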