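test_that("gaussian kernel CDF is symmetric and monotone within a gene", {
  v <- matrix(c(-1, 1, 0, 2), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  e <- expression_matrix(v, value_kind = "continuous")
  Fh <- kernel_cdf(e, kernel_spec("gaussian"))
  expect_equal(Fh["g1", "s1"] + Fh["g1", "s2"], 1)  # symmetry around the mean

  e2 <- make_expr(15, 8, seed = 3, kind = "continuous")
  Fh2 <- kernel_cdf(e2, kernel_spec("gaussian"))
  for (i in 1:15) {
    o <- order(e2$values[i, ])
    expect_true(all(diff(Fh2[i, o]) >= 0))  # x_ij <= x_ik => Fhat_ij <= Fhat_ik
  }
  # constant gene is mid-ranked
  v3 <- rbind(g1 = c(1, 1, 1), g2 = c(0, 1, 2))
  colnames(v3) <- paste0("s", 1:3)
  Fh3 <- kernel_cdf(expression_matrix(v3, value_kind = "continuous"),
                    kernel_spec("gaussian"))
  expect_equal(unname(Fh3["g1", ]), rep(0.5, 3))
})

test_that("poisson kernel CDF matches the direct-summation oracle", {
  v <- rbind(g1 = c(0, 2, 5), g2 = c(7, 1, 3))
  colnames(v) <- paste0("s", 1:3)
  e <- expression_matrix(v, value_kind = "counts")
  Fh <- kernel_cdf(e, kernel_spec("poisson"))
  expect_equal(Fh, oracle_kcdf(v, "poisson"), tolerance = 1e-14)
  # spot value from first principles: F(0) with lambdas 0.5, 2.5, 5.5
  expect_equal(Fh["g1", "s1"],
               mean(ppois(0, c(0.5, 2.5, 5.5))), tolerance = 1e-14)
  vn <- rbind(g1 = c(-1, 2), g2 = c(0, 1))
  colnames(vn) <- c("s1", "s2")
  neg <- expression_matrix(vn, value_kind = "continuous")
  expect_error(kernel_cdf(neg, kernel_spec("poisson")), "non-negative")
})

test_that("rank statistic uses rank 1 = largest Fhat and r = |p/2 - rank|", {
  Fh <- matrix(c(0.9, 0.7, 0.5, 0.1), 4, 1,
               dimnames = list(paste0("g", 1:4), "s1"))
  rs <- rank_statistic(cbind(Fh, Fh))
  expect_equal(unname(rs$r[, 1]), c(1, 0, 1, 2))
  # all-tied column: ranks by ascending gene index, deterministic
  tied <- matrix(0.5, 4, 2, dimnames = list(paste0("g", 1:4), c("a", "b")))
  rs2 <- rank_statistic(tied)
  expect_equal(rs2$order[, 1], 1:4)
  expect_identical(rank_statistic(tied)$r, rs2$r)
  # r maximal at the two extremes of the ranking
  p <- 9
  r <- abs(p / 2 - seq_len(p))
  expect_equal(which(r == max(r)), p)  # bottom extreme for odd p
  expect_gte(r[1], r[ceiling(p / 2)])
})

test_that("random-walk scores match the brute-force oracle to 1e-12", {
  # seeded 12 x 3 counts matrix, one 4-gene set, tau = 1
  e <- make_expr(12, 3, seed = 7, kind = "counts")
  sets <- list(S1 = rownames(e$values)[c(2, 5, 8, 11)])
  coll <- gene_set_collection(sets)
  for (mode in c("diff_extremes", "max_deviation")) {
    em <- gsva_scores(e, coll, kernel_spec("poisson", tau = 1, es_mode = mode),
                      min_size = 2, max_size = 11)
    expect_equal(em$scores, oracle_gsva(e$values, sets, "poisson", 1, mode),
                 tolerance = 1e-12)
  }
  # gaussian kernel, several sets, 20 x 6
  e2 <- make_expr(20, 6, seed = 11, kind = "continuous")
  sets2 <- list(A = rownames(e2$values)[1:5],
                B = rownames(e2$values)[c(3, 9, 14, 18, 20)],
                C = rownames(e2$values)[6:17])
  em2 <- gsva_scores(e2, gene_set_collection(sets2),
                     kernel_spec("gaussian"), min_size = 2, max_size = 19)
  expect_equal(em2$scores,
               oracle_gsva(e2$values, sets2, "gaussian", 1, "diff_extremes"),
               tolerance = 1e-12)
})

test_that("tau = 0 with the set at the top of the ranking gives ES = 1", {
  # in sample s1 the set genes sit at the top of their own distributions
  # (Fhat high) while every other gene sits at the bottom, so s1's ranking
  # starts with the whole set and the unweighted walk climbs straight to 1
  v <- rbind(matrix(rep(c(10, 1, 2), each = 4), 4, 3),
             matrix(rep(c(0, 5, 6), each = 6), 6, 3))
  dimnames(v) <- list(paste0("g", 1:10), c("s1", "s2", "s3"))
  e <- expression_matrix(v, value_kind = "continuous")
  coll <- gene_set_collection(list(top = paste0("g", 1:4)))
  for (mode in c("diff_extremes", "max_deviation")) {
    em <- gsva_scores(e, coll, kernel_spec("gaussian", tau = 0, es_mode = mode),
                      min_size = 2, max_size = 9)
    expect_equal(unname(em$scores[1, "s1"]), 1)
  }
})

test_that("scores stay in [-1, 1] and size filtering shapes the output", {
  e <- make_expr(60, 10, seed = 5)
  genes <- rownames(e$values)
  coll <- gene_set_collection(list(
    tiny = genes[1:3],           # below min size 9
    ok = genes[4:20],
    ok2 = genes[21:40]))
  em <- gsva_scores(e, coll, kernel_spec("poisson"))
  expect_setequal(rownames(em$scores), c("ok", "ok2"))
  expect_true(all(em$scores >= -1 & em$scores <= 1))
  expect_true("tiny" %in% em$dropped$set)
  # a set covering every gene is rejected
  expect_error(
    gsva_scores(e, gene_set_collection(list(all = genes)),
                kernel_spec("poisson"), min_size = 2, max_size = 300),
    "covers all")
})

test_that("scores are invariant to sample and gene order", {
  e <- make_expr(18, 6, seed = 9, kind = "continuous")
  coll <- gene_set_collection(list(A = rownames(e$values)[c(1, 4, 7, 10, 13)]))
  spec <- kernel_spec("gaussian")
  em <- gsva_scores(e, coll, spec, min_size = 2, max_size = 17)
  perm <- c(4, 1, 6, 2, 5, 3)
  e_s <- expression_matrix(e$values[, perm], value_kind = "continuous")
  em_s <- gsva_scores(e_s, coll, spec, min_size = 2, max_size = 17)
  expect_equal(em_s$scores[, colnames(em$scores), drop = FALSE], em$scores)
  gperm <- sample(1:18)
  e_g <- expression_matrix(e$values[gperm, ], value_kind = "continuous")
  em_g <- gsva_scores(e_g, coll, spec, min_size = 2, max_size = 17)
  expect_equal(em_g$scores, em$scores, tolerance = 1e-12)
})

test_that("a gene set independent of expression scores near zero on average", {
  set.seed(21)
  e <- make_expr(120, 40, seed = 13, kind = "continuous")
  coll <- gene_set_collection(list(rand = sample(rownames(e$values), 15)))
  em <- gsva_scores(e, coll, kernel_spec("gaussian"), min_size = 2,
                    max_size = 119)
  expect_lt(abs(mean(em$scores)), 0.12)
})

test_that("signature scoring is gsva on a one-set collection", {
  e <- make_expr(30, 5, seed = 17)
  genes <- rownames(e$values)[3:14]
  coll <- gene_set_collection(list(sig = genes))
  em <- gsva_scores(e, coll, kernel_spec("poisson"), min_size = 2,
                    max_size = 29)
  expect_equal(score_signature(e, genes, kernel_spec("poisson")),
               em$scores["sig", ])
  expect_error(score_signature(e, c("nope1", "nope2"), kernel_spec("poisson")),
               "fewer than 2")
  # complementary signatures partitioning all genes score with opposite signs
  a <- rownames(e$values)[1:12]
  b <- rownames(e$values)[13:30]
  sa <- score_signature(e, a, kernel_spec("poisson"))
  sb <- score_signature(e, b, kernel_spec("poisson"))
  expect_true(all(sign(sa) == -sign(sb) | (sa == 0 & sb == 0)))
})

test_that("pre-ranked GSEA: top-loaded set, determinism, enumeration oracle", {
  stat <- setNames(seq(4, -4, length.out = 9), paste0("g", 1:9))
  coll <- gene_set_collection(list(top = paste0("g", 1:3)))
  res <- preranked_gsea(stat, coll, weight = 0, n_perm = 200, seed = 5)
  expect_equal(res$ES, 1)  # hit sum completes before any miss

  res2 <- preranked_gsea(stat, coll, weight = 0, n_perm = 200, seed = 5)
  expect_identical(res$p, res2$p)

  # exhaustive oracle: all C(8,3) placements of a 3-gene set on 8 genes
  set.seed(33)
  stat8 <- setNames(rnorm(8), paste0("h", 1:8))
  sorted <- sort(stat8, decreasing = TRUE)
  combos <- combn(8, 3)
  null_es <- apply(combos, 2, function(pos)
    oracle_preranked_es(sorted, sort(pos), weight = 1))
  myset <- names(sorted)[c(1, 2, 5)]
  res3 <- preranked_gsea(stat8, gene_set_collection(list(s = myset)),
                         weight = 1, n_perm = 4000, seed = 2)
  es_obs <- oracle_preranked_es(sorted, c(1, 2, 5), weight = 1)
  expect_equal(res3$ES, es_obs, tolerance = 1e-12)
  p_exact <- if (es_obs >= 0)
    sum(null_es >= es_obs) / sum(null_es >= 0) else
    sum(null_es <= es_obs) / sum(null_es < 0)
  expect_lt(abs(res3$p - p_exact), 0.04)  # Monte-Carlo + smoothing slack
  expect_error(
    preranked_gsea(stat8, gene_set_collection(list(all = names(stat8)))),
    "covers all")
})

test_that("diff_extremes equals max_deviation when the walk keeps one sign", {
  # in s1 the set leads the ranking, so s1's walk never goes negative and
  # the two readouts coincide there
  v <- rbind(matrix(rep(c(9, 1, 2), each = 5), 5, 3),
             matrix(rep(c(0, 4, 6), each = 15), 15, 3))
  dimnames(v) <- list(paste0("g", 1:20), c("s1", "s2", "s3"))
  e <- expression_matrix(v, value_kind = "continuous")
  coll <- gene_set_collection(list(top = paste0("g", 1:5)))
  em1 <- gsva_scores(e, coll, kernel_spec("gaussian", es_mode = "diff_extremes"),
                     min_size = 2, max_size = 19)
  em2 <- gsva_scores(e, coll, kernel_spec("gaussian", es_mode = "max_deviation"),
                     min_size = 2, max_size = 19)
  expect_equal(em1$scores[1, "s1"], em2$scores[1, "s1"])
  expect_gt(em1$scores[1, "s1"], 0.9)
})
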