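#' Train a nearest shrunken centroids classifier
#'
#' For feature i and class k, the standardized centroid deviation is
#' d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s0)) with m_k =
#' sqrt(1/n_k - 1/n), s_i the pooled within-class SD and s0 the median of
#' the s_i (the fudge factor). Soft-thresholding at Delta gives
#' d'_ik = sign(d_ik) max(0, |d_ik| - Delta) and shrunken centroids
#' xbar'_ik = xbar_i + m_k (s_i + s0) d'_ik. The whole family over the
#' threshold grid is returned; [nsc_cv()] picks the operating Delta.
#'
#' @param M Features x samples numeric matrix (e.g. pathway scores).
#' @param labels Class label per sample (character or factor).
#' @param delta_grid Numeric vector of thresholds; default 30 values evenly
#'   spaced from 0 to max |d_ik|.
#' @param priors Class priors; default the training proportions.
#' @return Object of class `nsc_model`: centroids, SDs, `s0`, priors,
#'   `d` (raw deviations), `delta_grid`, and `delta` (operating threshold,
#'   initialized to 0; set it from [nsc_cv()]).
#' @export
nsc_train <- function(M, labels, delta_grid = NULL, priors = NULL) {
  M <- as.matrix(M)
  labels <- as.character(labels)
  stopifnot(ncol(M) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least 2 classes")
  nk <- table(factor(labels, classes))
  if (any(nk < 2L))
    stop("class with fewer than 2 samples: ",
         paste(names(nk)[nk < 2], collapse = ", "))
  n <- ncol(M)
  xbar <- rowMeans(M)
  cent <- vapply(classes, function(cl)
    rowMeans(M[, labels == cl, drop = FALSE]), numeric(nrow(M)))
  # pooled within-class SD per feature
  ss <- rowSums(vapply(classes, function(cl) {
    X <- M[, labels == cl, drop = FALSE]
    rowSums((X - cent[, cl])^2)
  }, numeric(nrow(M))))
  s <- sqrt(ss / (n - length(classes)))
  s0 <- stats::median(s)
  mk <- sqrt(1 / as.numeric(nk) - 1 / n)
  names(mk) <- classes
  d <- sweep(cent - xbar, 2, mk, "/") / (s + s0)
  if (is.null(delta_grid))
    delta_grid <- seq(0, max(abs(d)), length.out = 30)
  if (is.null(priors)) priors <- as.numeric(nk) / n
  if (any(priors <= 0) || abs(sum(priors) - 1) > 1e-8)
    stop("priors must be positive and sum to 1")
  structure(
    list(classes = classes, xbar = xbar, centroids = cent, s = s, s0 = s0,
         priors = stats::setNames(priors, classes),
         mk = mk, d = d, delta_grid = delta_grid, delta = 0,
         features = rownames(M), cv = NULL),
    class = "nsc_model"
  )
}

# shrunken class centroids at a given threshold
.nsc_shrunken <- function(model, delta) {
  dprime <- sign(model$d) * pmax(abs(model$d) - delta, 0)
  model$xbar + sweep(dprime, 2, model$mk, "*") * (model$s + model$s0)
}

#' @export
print.nsc_model <- function(x, ...) {
  nz <- sum(rowSums(abs(x$d) > x$delta) > 0)
  cat("Nearest shrunken centroids model:", length(x$classes), "classes,",
      length(x$features), "features\n")
  cat("Operating threshold Delta =", format(x$delta, digits = 4),
      "(", nz, "features with a surviving deviation )\n")
  invisible(x)
}

#' Cross-validated threshold selection for NSC
#'
#' Stratified k-fold cross-validation of misclassification error over the
#' threshold grid; the chosen Delta is the largest threshold attaining the
#' minimum error (the most parsimonious among ties). Degenerate folds that
#' leave a training class with fewer than 2 samples are re-drawn with a new
#' seed, at most 10 times.
#'
#' @param M,labels As in [nsc_train()].
#' @param delta_grid Threshold grid; default from the full-data fit.
#' @param folds Number of folds (default 10; reduced to the smallest class
#'   size when needed).
#' @param seed Integer RNG seed.
#' @return The input model structure refitted on all data, with `delta` set
#'   to the chosen threshold and `cv` holding the error curve.
#' @export
nsc_cv <- function(M, labels, delta_grid = NULL, folds = 10, seed = 1) {
  M <- as.matrix(M)
  labels <- as.character(labels)
  full <- nsc_train(M, labels, delta_grid = delta_grid)
  delta_grid <- full$delta_grid
  nk <- table(factor(labels, full$classes))
  folds <- max(2L, min(folds, min(nk)))
  n <- ncol(M)

  assign_folds <- function(s) {
    set.seed(s)
    f <- integer(n)
    for (cl in full$classes) {
      idx <- which(labels == cl)
      f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    f
  }
  fold_id <- NULL
  for (attempt in 0:9) {
    cand <- assign_folds(as.integer(seed) + attempt)
    ok <- all(vapply(seq_len(folds), function(f) {
      tr <- labels[cand != f]
      length(unique(tr)) == length(full$classes) && all(table(tr) >= 2)
    }, TRUE))
    if (ok) { fold_id <- cand; break }
  }
  if (is.null(fold_id)) stop("could not build non-degenerate CV folds")

  err <- matrix(0, folds, length(delta_grid))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit <- nsc_train(M[, tr, drop = FALSE], labels[tr],
                     delta_grid = delta_grid)
    for (g in seq_along(delta_grid)) {
      fit$delta <- delta_grid[g]
      pred <- nsc_predict(fit, M[, !tr, drop = FALSE])$labels
      err[f, g] <- mean(pred != labels[!tr])
    }
  }
  cv_err <- colMeans(err)
  best <- max(delta_grid[cv_err == min(cv_err)])
  full$delta <- best
  full$cv <- data.frame(delta = delta_grid, error = cv_err)
  full
}

#' Predict classes with a trained NSC model
#'
#' Discriminant score for class k at a new profile x*:
#' delta_k(x*) = sum_i (x*_i - xbar'_ik)^2 / (s_i + s0)^2 - 2 log pi_k,
#' using the shrunken centroids at the model's operating threshold; the
#' predicted class is the argmin (ties resolved toward the class listed
#' first).
#'
#' @param model An `nsc_model` (typically from [nsc_cv()]).
#' @param M_new Features x samples matrix; must contain every model feature.
#' @param delta Optional threshold overriding `model$delta`.
#' @return List: `labels` (named character vector) and `scores`
#'   (classes x samples discriminant matrix; smaller is closer).
#' @export
nsc_predict <- function(model, M_new, delta = NULL) {
  stopifnot(inherits(model, "nsc_model"))
  M_new <- as.matrix(M_new)
  missing_feat <- setdiff(model$features, rownames(M_new))
  if (length(missing_feat))
    stop("features missing from new data: ",
         paste(utils::head(missing_feat, 10), collapse = ", "))
  M_new <- M_new[model$features, , drop = FALSE]
  if (is.null(delta)) delta <- model$delta
  cent <- .nsc_shrunken(model, delta)
  denom <- (model$s + model$s0)^2
  disc <- matrix(0, length(model$classes), ncol(M_new),
                 dimnames = list(model$classes, colnames(M_new)))
  for (cl in model$classes)
    disc[cl, ] <- colSums((M_new - cent[, cl])^2 / denom) -
      2 * log(model$priors[[cl]])
  labels <- model$classes[apply(disc, 2, which.min)]
  list(labels = stats::setNames(labels, colnames(M_new)), scores = disc)
}

#' @export
predict.nsc_model <- function(object, newdata, ...) {
  nsc_predict(object, newdata, ...)$labels
}

#' Classification consistency rate
#'
#' Exact agreement fraction between two labelings of the same samples under
#' fixed label names (no label matching is attempted).
#'
#' @param labels_a,labels_b Named label vectors over the same sample ids.
#' @return Fraction in [0, 1].
#' @export
consistency_rate <- function(labels_a, labels_b) {
  if (is.null(names(labels_a)) || is.null(names(labels_b)))
    stop("labels must be named by sample id")
  if (!setequal(names(labels_a), names(labels_b)))
    stop("sample ids differ between the two labelings")
  labels_b <- labels_b[names(labels_a)]
  mean(as.character(labels_a) == as.character(labels_b))
}

#' Pearson congruence of subtype centroids across cohorts
#'
#' Entry (s, t) is the Pearson correlation between centroid s of cohort A
#' and centroid t of cohort B, computed over the shared pathways.
#'
#' @param C_a,C_b Pathways x subtypes centroid matrices (e.g.
#'   `mps_model$centroids`).
#' @return Subtypes(A) x subtypes(B) correlation matrix; entries involving a
#'   zero-variance centroid are NA.
#' @export
centroid_congruence <- function(C_a, C_b) {
  shared <- intersect(rownames(C_a), rownames(C_b))
  if (length(shared) < 3L) stop("fewer than 3 shared pathways")
  A <- C_a[shared, , drop = FALSE]
  B <- C_b[shared, , drop = FALSE]
  out <- matrix(NA_real_, ncol(A), ncol(B),
                dimnames = list(colnames(A), colnames(B)))
  for (i in seq_len(ncol(A))) for (j in seq_len(ncol(B))) {
    if (stats::sd(A[, i]) > 0 && stats::sd(B[, j]) > 0)
      out[i, j] <- stats::cor(A[, i], B[, j])
  }
  out
}

#' Serialize an NSC model to JSON
#'
#' Writes every component needed to reapply the classifier in another
#' cohort: centroids, overall centroid, SDs, fudge factor, priors, threshold.
#'
#' @param model An `nsc_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
nsc_to_json <- function(model, path) {
  stopifnot(inherits(model, "nsc_model"))
  obj <- list(
    classes = model$classes, features = model$features,
    xbar = unname(model$xbar),
    centroids = lapply(model$classes, function(cl) unname(model$centroids[, cl])),
    s = unname(model$s), s0 = model$s0,
    priors = unname(model$priors), mk = unname(model$mk),
    delta = model$delta, delta_grid = model$delta_grid
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an NSC model back from JSON
#'
#' @param path Path written by [nsc_to_json()].
#' @return An `nsc_model`.
#' @export
nsc_from_json <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  cent <- if (is.list(o$centroids))
    do.call(cbind, lapply(o$centroids, as.numeric)) else
    t(as.matrix(o$centroids))   # jsonlite simplifies to classes x features
  colnames(cent) <- o$classes
  rownames(cent) <- o$features
  structure(
    list(classes = o$classes, xbar = stats::setNames(o$xbar, o$features),
         centroids = cent, s = stats::setNames(o$s, o$features), s0 = o$s0,
         priors = stats::setNames(o$priors, o$classes),
         mk = stats::setNames(o$mk, o$classes),
         d = sweep(cent - o$xbar, 2, o$mk, "/") / (o$s + o$s0),
         delta_grid = o$delta_grid, delta = o$delta,
         features = o$features, cv = NULL),
    class = "nsc_model"
  )
}
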