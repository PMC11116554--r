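#' Pipeline run configuration
#'
#' Bundles the file paths and parameters for one end-to-end run:
#' score -> subtype -> differential -> survival.
#'
#' @param expression Path to the expression TSV (genes x samples).
#' @param gmt Path to the gene-set GMT file.
#' @param clinical Optional path to the clinical TSV (must contain
#'   `sample_id` and `<endpoint>_time` / `<endpoint>_event` columns); when
#'   `NULL` the survival stage is skipped.
#' @param out_dir Output directory (created if missing).
#' @param value_kind `"counts"` or `"continuous"`.
#' @param kernel,tau,es_mode Passed to [kernel_spec()]; `kernel = NULL`
#'   picks poisson for counts and gaussian for continuous input.
#' @param min_size,max_size Gene-set size bounds.
#' @param k Forced cluster number, or `NULL` for the consensus vote.
#' @param k_min,k_max Consensus grid.
#' @param anchor Anchor pathway/category for subtype naming (optional).
#' @param endpoint Endpoint name prefix in the clinical table (default "OS").
#' @param seed Integer RNG seed, stamped into every output.
#' @param verbose Log stage progress to stderr.
#' @return A list of class `run_config`.
#' @export
run_config <- function(expression, gmt, clinical = NULL, out_dir = ".",
                       value_kind = c("counts", "continuous"),
                       kernel = NULL, tau = 1,
                       es_mode = c("diff_extremes", "max_deviation"),
                       min_size = 9, max_size = 300, k = NULL,
                       k_min = 2, k_max = 10, anchor = NULL,
                       endpoint = "OS", seed = 1, verbose = TRUE) {
  value_kind <- match.arg(value_kind)
  es_mode <- match.arg(es_mode)
  if (is.null(kernel))
    kernel <- if (value_kind == "counts") "poisson" else "gaussian"
  for (pth in c(expression, gmt, clinical))
    if (!file.exists(pth)) stop("input path does not exist: ", pth)
  structure(
    list(expression = expression, gmt = gmt, clinical = clinical,
         out_dir = out_dir, value_kind = value_kind, kernel = kernel,
         tau = tau, es_mode = es_mode, min_size = min_size,
         max_size = max_size, k = k, k_min = k_min, k_max = k_max,
         anchor = anchor, endpoint = endpoint, seed = as.integer(seed),
         verbose = isTRUE(verbose)),
    class = "run_config"
  )
}

.pipe_log <- function(cfg, ...) {
  if (cfg$verbose) message("[mpsuite] ", ...)
  invisible(NULL)
}

#' Run the full subtyping pipeline
#'
#' Stages: read inputs, score pathways per sample, discover subtypes,
#' differential enrichment between the first two subtypes, and (when a
#' clinical table is supplied) subtype survival association. Every artifact
#' is written under `config$out_dir` and stamped with the seed and a config
#' hash; any stage error writes a FAILED marker naming the stage and
#' re-raises.
#'
#' @param config A [run_config()].
#' @return The run report (also written as `report.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_plain <- unclass(config)
  cfg_str <- paste(names(cfg_plain),
                   vapply(cfg_plain, function(v)
                     paste(format(v), collapse = ","), ""),
                   sep = "=", collapse = ";")
  chars <- utf8ToInt(cfg_str)
  cfg_hash <- sprintf("%08x",
                      sum(chars * (seq_along(chars) %% 97 + 1)) %% 2^31)
  report <- list(
    package = "mpsuite",
    version = as.character(utils::packageVersion("mpsuite")),
    seed = config$seed, config = cfg_plain[!vapply(cfg_plain, is.null, TRUE)],
    config_hash = format(cfg_hash), stages = list()
  )
  stage <- "setup"
  t_all <- proc.time()[["elapsed"]]
  on_fail <- function(e) {
    writeLines(paste("FAILED at stage:", stage, "-", conditionMessage(e)),
               file.path(config$out_dir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    stage <- "read"
    t0 <- proc.time()[["elapsed"]]
    expr <- read_expression_tsv(config$expression, config$value_kind)
    coll <- read_gmt(config$gmt)
    clin <- if (!is.null(config$clinical))
      utils::read.delim(config$clinical, stringsAsFactors = FALSE) else NULL
    report$stages$read <- list(
      seconds = proc.time()[["elapsed"]] - t0,
      n_genes = nrow(expr$values), n_samples = ncol(expr$values),
      n_sets = length(coll$sets))

    stage <- "score"
    t0 <- proc.time()[["elapsed"]]
    spec <- kernel_spec(config$kernel, config$tau, config$es_mode)
    em <- gsva_scores(expr, coll, spec, config$min_size, config$max_size)
    write_matrix_tsv(em$scores, file.path(config$out_dir, "scores.tsv"),
                     id_col = "pathway")
    report$stages$score <- list(
      seconds = proc.time()[["elapsed"]] - t0,
      n_pathways = nrow(em$scores),
      dropped_sets = em$dropped$set)
    .pipe_log(config, "scored ", nrow(em$scores), " pathways")

    stage <- "subtype"
    t0 <- proc.time()[["elapsed"]]
    model <- discover_subtypes(em, k = config$k, anchor = config$anchor,
                               seed = config$seed, k_min = config$k_min,
                               k_max = config$k_max)
    utils::write.table(
      data.frame(sample_id = names(model$labels), subtype = model$labels),
      file.path(config$out_dir, "labels.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    write_matrix_tsv(model$centroids,
                     file.path(config$out_dir, "centroids.tsv"),
                     id_col = "pathway")
    report$stages$subtype <- list(
      seconds = proc.time()[["elapsed"]] - t0, k = model$k,
      sizes = as.list(table(model$labels)),
      votes = if (is.character(model$votes)) model$votes else
        as.list(model$votes))
    .pipe_log(config, "k = ", model$k)

    stage <- "differential"
    t0 <- proc.time()[["elapsed"]]
    in12 <- model$labels %in% c("MPS1", "MPS2")
    diff_tab <- differential_enrichment(
      em$scores[, in12, drop = FALSE],
      factor(model$labels[in12], levels = c("MPS1", "MPS2")))
    utils::write.table(diff_tab, file.path(config$out_dir, "diff.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$differential <- list(
      seconds = proc.time()[["elapsed"]] - t0,
      n_significant = sum(diff_tab$p_adj < 0.05))

    stage <- "survival"
    if (is.null(clin)) {
      report$stages$survival <- "skipped (no clinical table)"
    } else {
      t0 <- proc.time()[["elapsed"]]
      tc <- paste0(config$endpoint, "_time")
      ec <- paste0(config$endpoint, "_event")
      if (!all(c("sample_id", tc, ec) %in% names(clin)))
        stop("clinical table lacks sample_id/", tc, "/", ec)
      clin <- clin[clin$sample_id %in% names(model$labels), ]
      lab <- model$labels[clin$sample_id]
      is1 <- as.numeric(lab == "MPS1")
      lr <- logrank_test(clin[[tc]], clin[[ec]], is1)
      cx <- coxph_fit(data.frame(MPS1 = is1), clin[[tc]], clin[[ec]])
      surv_out <- list(
        endpoint = config$endpoint, logrank_chisq = lr$chisq,
        logrank_p = lr$p, hr_mps1 = unname(cx$hr[1]),
        ci = c(unname(cx$ci_lower[1]), unname(cx$ci_upper[1])),
        p = unname(cx$p[1]))
      jsonlite::write_json(surv_out,
                           file.path(config$out_dir, "survival.json"),
                           auto_unbox = TRUE, digits = NA)
      report$stages$survival <- c(
        list(seconds = proc.time()[["elapsed"]] - t0), surv_out)
    }
  }, error = on_fail)
  report$total_seconds <- proc.time()[["elapsed"]] - t_all
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(report)
}
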