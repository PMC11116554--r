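# The 12 main KEGG metabolic category labels used for synthetic collections.
.kegg_categories <- c(
  "amino acid metabolism",
  "biosynthesis of other secondary metabolites",
  "carbohydrate metabolism",
  "energy metabolism",
  "glycan biosynthesis and metabolism",
  "lipid metabolism",
  "metabolism of cofactors and vitamins",
  "metabolism of other amino acids",
  "metabolism of terpenoids and polyketides",
  "not included in regular maps",
  "nucleotide metabolism",
  "xenobiotics biodegradation and metabolism"
)

#' Synthetic stand-in for the KEGG metabolic pathway collection
#'
#' Builds, deterministically, a synthetic gene-set collection with the same
#' accounting geometry as the curated KEGG metabolic pathway compilation
#' used for MPS subtyping: 95 pathways over exactly 1659 unique gene symbols
#' in the 12 main metabolic categories, pathway sizes between 10 and 40 with
#' overlapping membership, and a chondroitin/dermatan-sulfate anchor pathway
#' in the glycan category. The real compilation is built from KEGG; this
#' object is synthetic (gene symbols are placeholders) and exists so the
#' accounting and I/O paths are testable offline. It is shipped as
#' `inst/extdata/kegg_metabolic_synthetic.gmt`.
#'
#' @param n_sets Number of pathways (default 95).
#' @param n_unique_genes Size of the gene universe (default 1659).
#' @param size_range Pathway size bounds (default c(10, 40)).
#' @return A [gene_set_collection()].
#' @export
synthetic_kegg_collection <- function(n_sets = 95, n_unique_genes = 1659,
                                      size_range = c(10, 40)) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(19590L)
  pool <- sprintf("MGENE%04d", seq_len(n_unique_genes))
  sizes <- sample(size_range[1]:size_range[2], n_sets, replace = TRUE)
  # enlarge sizes if the pool cannot be covered
  while (sum(sizes) < n_unique_genes)
    sizes <- pmin(sizes + 1L, size_range[2])
  categories <- rep_len(.kegg_categories, n_sets)
  nm <- sprintf("synthetic pathway %02d (%s)", seq_len(n_sets),
                vapply(strsplit(categories, " "), `[[`, "", 1L))
  nm[1] <- "glycosaminoglycan biosynthesis - chondroitin sulfate / dermatan sulfate (synthetic)"
  categories[1] <- "glycan biosynthesis and metabolism"
  # every pool gene appears at least once; extra slots are seeded duplicates
  sets <- vector("list", n_sets)
  cursor <- 1L
  for (i in seq_len(n_sets)) {
    take <- min(sizes[i], max(0L, n_unique_genes - cursor + 1L))
    g <- if (take > 0) pool[cursor:(cursor + take - 1L)] else character(0)
    cursor <- cursor + take
    if (take < sizes[i])
      g <- c(g, sample(setdiff(pool, g), sizes[i] - take))
    sets[[i]] <- g
  }
  names(sets) <- nm
  gene_set_collection(sets, categories,
                      source = "synthetic KEGG metabolic stand-in")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Configuration of a synthetic cohort simulation
#'
#' The stated world of the generator: a cohort of `n_samples` tumors in
#' `length(subtype_props)` planted subtypes; genes are partitioned into
#' `n_pathways` disjoint pathways (sizes drawn from `pathway_size_range`,
#' categories cycling through the 12 metabolic category labels) plus
#' `n_background` unassigned genes; for a sample of subtype s the genes of
#' pathway q are location-shifted by `effect_map[s, q]` per-gene SD units;
#' survival times are exponential with per-subtype hazard ratios and
#' independent exponential censoring calibrated to `censor_rate`.
#'
#' @param n_samples Cohort size (default 200).
#' @param subtype_props Subtype proportions, summing to 1 (default
#'   c(0.5, 0.5)).
#' @param n_pathways Number of disjoint pathways (default 95).
#' @param pathway_size_range Pathway sizes (default c(10, 40)).
#' @param n_background Genes in no pathway (default 300).
#' @param effect_map Subtypes x pathways matrix of shifts delta in per-gene
#'   SD units; `NULL` builds the default: the first subtype (MPS1 analog)
#'   elevated by `delta` on the glycan-category pathways (including the
#'   anchor), the second subtype elevated by `delta` on the amino-acid and
#'   lipid category pathways, further subtypes on successive categories.
#' @param delta Effect size for the default map (default 1).
#' @param expression_model `"counts"` (negative binomial; scored with the
#'   Poisson kernel) or `"continuous"` (log-normal; Gaussian kernel).
#' @param dispersion NB dispersion (default 0.3).
#' @param base_mean Median baseline NB mean (default 200).
#' @param survival_hr Per-subtype hazard ratios vs the reference subtype
#'   (default: 1.75 for the MPS1 analog, 1 for the others).
#' @param baseline_rate Baseline exponential event rate per day (default
#'   log(2)/730: two-year median survival).
#' @param censor_rate Expected censoring fraction in [0, 1) (default 0.3).
#' @param seed Integer RNG seed (default 1).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 200, subtype_props = c(0.5, 0.5),
                              n_pathways = 95,
                              pathway_size_range = c(10, 40),
                              n_background = 300, effect_map = NULL,
                              delta = 1,
                              expression_model = c("counts", "continuous"),
                              dispersion = 0.3, base_mean = 200,
                              survival_hr = NULL,
                              baseline_rate = log(2) / 730,
                              censor_rate = 0.3, seed = 1) {
  expression_model <- match.arg(expression_model)
  stopifnot(abs(sum(subtype_props) - 1) < 1e-8, all(subtype_props > 0),
            dispersion > 0, censor_rate >= 0, censor_rate < 1,
            baseline_rate > 0, n_pathways >= 2)
  n_sub <- length(subtype_props)
  if (is.null(survival_hr)) survival_hr <- c(1.75, rep(1, n_sub - 1))
  stopifnot(length(survival_hr) == n_sub, all(survival_hr > 0))
  structure(
    list(n_samples = n_samples, subtype_props = subtype_props,
         n_pathways = n_pathways, pathway_size_range = pathway_size_range,
         n_background = n_background, effect_map = effect_map, delta = delta,
         expression_model = expression_model, dispersion = dispersion,
         base_mean = base_mean, survival_hr = survival_hr,
         baseline_rate = baseline_rate, censor_rate = censor_rate,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# disjoint pathway collection over the simulated gene universe
.sim_collection <- function(n_pathways, size_range) {
  sizes <- if (size_range[1] == size_range[2])
    rep(size_range[1], n_pathways) else
    sample(size_range[1]:size_range[2], n_pathways, replace = TRUE)
  categories <- rep_len(.kegg_categories, n_pathways)
  nm <- sprintf("pathway_%03d", seq_len(n_pathways))
  nm[categories == "glycan biosynthesis and metabolism"][1] <- "glycan_cs_ds"
  starts <- cumsum(c(1L, sizes[-n_pathways]))
  genes <- sprintf("G%05d", seq_len(sum(sizes)))
  sets <- lapply(seq_len(n_pathways), function(i)
    genes[starts[i]:(starts[i] + sizes[i] - 1L)])
  names(sets) <- nm
  gene_set_collection(sets, categories, source = "simulated")
}

.default_effect_map <- function(coll, n_sub, delta) {
  nm <- names(coll$sets)
  cats <- coll$categories
  em <- matrix(0, n_sub, length(nm), dimnames = list(NULL, nm))
  blocks <- list(
    "glycan biosynthesis and metabolism",
    c("amino acid metabolism", "lipid metabolism"),
    "energy metabolism", "carbohydrate metabolism",
    "nucleotide metabolism"
  )
  for (s in seq_len(n_sub)) {
    b <- blocks[[((s - 1) %% length(blocks)) + 1]]
    em[s, cats %in% b] <- delta
  }
  em
}

#' Simulate a synthetic cohort with planted subtypes and coupled survival
#'
#' Bit-reproducible given the config (which carries the seed). See
#' [simulation_config()] for the generative model.
#'
#' @param config A [simulation_config()].
#' @return Object of class `synthetic_cohort`: `expr`
#'   ([expression_matrix()]), `collection` ([gene_set_collection()]),
#'   `truth` (named subtype labels, MPS1...), `clinical` (data frame:
#'   sample_id, OS_time, OS_event), `effect_map`, `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  coll <- .sim_collection(config$n_pathways, config$pathway_size_range)
  n_sub <- length(config$subtype_props)
  em <- config$effect_map
  if (is.null(em)) {
    em <- .default_effect_map(coll, n_sub, config$delta)
  } else {
    em <- as.matrix(em)
    if (is.null(colnames(em))) colnames(em) <- names(coll$sets)
    unknown <- setdiff(colnames(em), names(coll$sets))
    if (length(unknown))
      stop("effect map references unknown pathway(s): ",
           paste(utils::head(unknown, 5), collapse = ", "))
    full <- matrix(0, n_sub, length(coll$sets),
                   dimnames = list(NULL, names(coll$sets)))
    full[, colnames(em)] <- em
    em <- full
  }

  n <- config$n_samples
  # deterministic subtype counts matching the proportions, then shuffled
  counts <- diff(round(cumsum(c(0, config$subtype_props)) * n))
  truth <- sample(rep(paste0("MPS", seq_len(n_sub)), counts))
  sample_ids <- sprintf("S%04d", seq_len(n))
  names(truth) <- sample_ids

  pathway_genes <- unlist(coll$sets, use.names = FALSE)
  all_genes <- c(pathway_genes,
                 if (config$n_background > 0)
                   sprintf("BG%05d", seq_len(config$n_background)))
  p <- length(all_genes)
  # per-gene delta by subtype (background genes: 0)
  gene_delta <- matrix(0, n_sub, p, dimnames = list(NULL, all_genes))
  for (q in seq_along(coll$sets))
    gene_delta[, coll$sets[[q]]] <- em[, q]
  sub_idx <- as.integer(sub("MPS", "", truth))

  if (config$expression_model == "counts") {
    sd_ln <- sqrt(log(1 + config$dispersion))  # log-scale SD implied by NB
    lmu <- stats::rnorm(p, log(config$base_mean), 1)
    shift <- t(gene_delta[sub_idx, , drop = FALSE]) * sd_ln  # p x n
    mu <- exp(lmu + shift)
    values <- matrix(
      stats::rnbinom(p * n, size = 1 / config$dispersion, mu = mu), p, n)
    kind <- "counts"
  } else {
    mu <- stats::rnorm(p, 5, 2)
    sds <- stats::runif(p, 0.8, 1.2)
    shift <- t(gene_delta[sub_idx, , drop = FALSE]) * sds
    values <- mu + shift +
      matrix(stats::rnorm(p * n, 0, 1), p, n) * sds
    kind <- "continuous"
  }
  dimnames(values) <- list(all_genes, sample_ids)
  expr <- expression_matrix(values, value_kind = kind)

  hr_map <- stats::setNames(config$survival_hr, paste0("MPS", seq_len(n_sub)))
  surv <- simulate_survival(truth, hr_map, config$baseline_rate,
                            config$censor_rate,
                            seed = config$seed + 104729L)
  clinical <- data.frame(sample_id = sample_ids, OS_time = surv$times,
                         OS_event = surv$events, subtype = unname(truth),
                         stringsAsFactors = FALSE)
  structure(
    list(expr = expr, collection = coll, truth = truth, clinical = clinical,
         effect_map = em, config = config),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", x$config$n_samples, "samples,",
      nrow(x$expr$values), "genes,", length(x$collection$sets),
      "pathways;", length(unique(x$truth)), "planted subtypes\n")
  invisible(x)
}

#' Simulate survival outcomes from subtype labels
#'
#' Event times are exponential with rate `baseline_rate * hr_map[label]`;
#' censoring times are exponential with a single rate calibrated so the
#' expected censoring fraction over the cohort equals `censor_rate`
#' (`censor_rate = 0` yields all events). Observed time is the minimum.
#'
#' @param labels Subtype label per sample.
#' @param hr_map Named hazard-ratio vector covering every label.
#' @param baseline_rate Positive baseline event rate.
#' @param censor_rate Target censoring fraction in [0, 1).
#' @param seed Integer RNG seed.
#' @return List: `times` (positive), `events` (0/1).
#' @export
simulate_survival <- function(labels, hr_map, baseline_rate = log(2) / 730,
                              censor_rate = 0.3, seed = 1) {
  labels <- as.character(labels)
  if (!all(labels %in% names(hr_map)))
    stop("hr_map does not cover all labels")
  if (baseline_rate <= 0 || any(hr_map <= 0)) stop("rates must be positive")
  stopifnot(censor_rate >= 0, censor_rate < 1)
  set.seed(as.integer(seed))
  lam <- baseline_rate * as.numeric(hr_map[labels])
  t_event <- stats::rexp(length(lam), rate = lam)
  if (censor_rate == 0)
    return(list(times = t_event, events = rep(1, length(lam))))
  # P(censored | lambda_i) = rc / (rc + lambda_i); calibrate rc numerically
  f <- function(rc) mean(rc / (rc + lam)) - censor_rate
  rc <- stats::uniroot(f, lower = 1e-12, upper = 1e6 * max(lam),
                       tol = 1e-12)$root
  t_cens <- stats::rexp(length(lam), rate = rc)
  list(times = pmin(t_event, t_cens),
       events = as.numeric(t_event <= t_cens))
}
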