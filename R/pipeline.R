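# End-to-end orchestration: simulate/load -> classify -> BRCA-like predict
# -> methylation -> aggregation test -> report.

#' Run the full familial-subtype analysis pipeline
#'
#' Executes the stages in a fixed order — simulate (or load), classify,
#' BRCA-like prediction, methylation, aggregation test, clustering — and
#' writes each stage's outputs plus a combined JSON study report to the
#' output directory. Identical configuration and seed yield identical
#' outputs (the report carries a timestamp field; everything else is
#' deterministic).
#'
#' @param config A nested list (or path to a YAML/JSON file with the same
#'   structure):
#'   \describe{
#'     \item{seed}{master integer seed, recorded in every report.}
#'     \item{out_dir}{output directory.}
#'     \item{stages}{logical toggles: `simulate`, `classify`, `brca`,
#'       `methylation`, `aggregation`, `cluster`.}
#'     \item{inputs}{paths used when a stage is not simulated:
#'       `expression`, `centroids`, `families`, `labels`, `ratios`,
#'       `signature`.}
#'     \item{simulate}{arguments for [synthetic_config()], plus optional
#'       `methylation_gene`.}
#'     \item{classify}{`method` (spearman/pearson), `min_overlap`.}
#'     \item{aggregation}{`n_replicates`, `pool_policy`, `method`.}
#'     \item{methylation}{`threshold`, `gene`.}
#'     \item{cluster}{`k_genes`, `metric`, `linkage`, `cut_k`.}
#'   }
#' @return A `study_report` list with one element per executed stage.
#' @export
#' @examples
#' cfg <- list(seed = 7, out_dir = tempfile(),
#'             stages = list(simulate = TRUE, classify = TRUE,
#'                           aggregation = TRUE),
#'             simulate = list(n_genes = 60, sigma = 0.5,
#'                             family_sizes = c(rep(2, 6), 3), rho = 1))
#' rep <- run_pipeline(cfg)
#' rep$aggregation$observed_statistic # all 7 families concordant
run_pipeline <- function(config) {
  config <- load_pipeline_config(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  on_off <- function(s) isTRUE(stages[[s]])
  report <- list(provenance = list(
    seed = seed,
    package_version = as.character(utils::packageVersion("famagg")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))

  expression <- NULL; centroids <- NULL
  families <- NULL; labels <- NULL; ratios <- NULL
  annotation <- NULL

  if (on_off("simulate")) {
    sim_args <- config$simulate
    meth_gene <- sim_args$methylation_gene
    sim_args$methylation_gene <- NULL
    sim_args$seed <- seed
    cfg <- do.call(synthetic_config, sim_args)
    cohort <- generate_cohort(cfg)
    if (!is.null(meth_gene))
      cohort <- generate_methylation(cfg, cohort, meth_gene)
    write_cohort(cohort, file.path(out_dir, "simulated"))
    expression <- cohort$expression
    centroids <- cohort$centroids
    families <- cohort$families
    annotation <- cohort$annotation
    labels <- stats::setNames(annotation$subtype, annotation$sample_id)
    ratios <- cohort$methylation
    report$simulate <- list(n_samples = ncol(expression),
                            n_genes = nrow(expression),
                            n_families = length(unique(families$family_id)))
  } else {
    inp <- config$inputs
    if (!is.null(inp$expression)) expression <- load_expression(inp$expression)
    if (!is.null(inp$centroids)) centroids <- load_centroids(inp$centroids)
    if (!is.null(inp$families)) families <- load_families(inp$families)
    if (!is.null(inp$labels)) labels <- load_labels(inp$labels)
    if (!is.null(inp$ratios)) ratios <- load_ratios(inp$ratios)
  }

  calls <- NULL
  if (on_off("classify")) {
    if (is.null(expression) || is.null(centroids))
      stop("classify stage needs an expression matrix and centroids",
           call. = FALSE)
    cl_args <- config$classify
    calls <- classify_cohort(expression, centroids,
                             method = if (is.null(cl_args$method)) "spearman"
                                      else cl_args$method,
                             min_overlap = if (is.null(cl_args$min_overlap))
                               0.5 else cl_args$min_overlap)
    write.csv(calls, file.path(out_dir, "subtype_calls.csv"),
              row.names = FALSE)
    labels <- stats::setNames(calls$assigned_subtype, calls$sample_id)
    report$classify <- list(
      n_classified = nrow(calls),
      distribution = as.list(table(calls$assigned_subtype)))
  }

  if (on_off("brca")) {
    sig_path <- config$inputs$signature
    if (is.null(sig_path) || is.null(calls))
      stop("brca stage needs inputs$signature and the classify stage",
           call. = FALSE)
    model <- load_signature(sig_path)
    preds <- predict_brca_like(model, expression, calls)
    write.csv(preds, file.path(out_dir, "brca_like_calls.csv"),
              row.names = FALSE)
    report$brca <- list(n_scored = nrow(preds),
                        n_positive = sum(preds$predicted_class ==
                                           model$class_labels["positive"]))
  }

  if (on_off("methylation")) {
    if (is.null(ratios))
      stop("methylation stage needs ratios (simulated or inputs$ratios)",
           call. = FALSE)
    m_args <- config$methylation
    thr <- if (is.null(m_args$threshold)) 0.2 else m_args$threshold
    mcalls <- call_methylation(ratios, threshold = thr)
    write.csv(mcalls, file.path(out_dir, "methylation_calls.csv"),
              row.names = FALSE)
    report$methylation <- list(threshold = thr,
                               n_positive = sum(mcalls$positive),
                               n_probes = nrow(mcalls))
    gene <- m_args$gene
    if (is.null(gene) && !is.null(ratios))
      gene <- sub("_promoter$", "", ratios$probe_id[1])
    if (!is.null(expression) && gene %in% rownames(expression)) {
      status <- promoter_positive(mcalls)
      if (sum(status) >= 2L && sum(!status) >= 2L) {
        assoc <- expression_association(expression[gene, ], mcalls)
        report$methylation$association <- assoc
      }
    }
  }

  if (on_off("aggregation")) {
    if (is.null(families) || is.null(labels))
      stop("aggregation stage needs families and subtype labels",
           call. = FALSE)
    a_args <- config$aggregation
    agg <- run_aggregation_test(
      families, labels,
      n_replicates = if (is.null(a_args$n_replicates)) 1e5
                     else a_args$n_replicates,
      seed = seed,
      pool_policy = if (is.null(a_args$pool_policy)) "multicase_only"
                    else a_args$pool_policy,
      method = if (is.null(a_args$method)) "monte_carlo" else a_args$method)
    write_report(agg, file.path(out_dir, "aggregation_report.json"))
    report$aggregation <- agg
  }

  if (on_off("cluster")) {
    if (is.null(expression))
      stop("cluster stage needs an expression matrix", call. = FALSE)
    c_args <- config$cluster
    ex <- explore_structure(
      expression,
      k_genes = if (is.null(c_args$k_genes)) 500 else c_args$k_genes,
      metric = if (is.null(c_args$metric)) "euclidean" else c_args$metric,
      linkage = if (is.null(c_args$linkage)) "complete" else c_args$linkage,
      cut_k = c_args$cut_k)
    writeLines(ex$clustering$newick, file.path(out_dir, "sample_tree.nwk"))
    report$cluster <- list(k_genes = length(ex$genes),
                           newick = ex$clustering$newick)
  }

  class(report) <- "study_report"
  write_report(report, file.path(out_dir, "study_report.json"))
  report
}

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("reading YAML configs needs the suggested package 'yaml'",
             call. = FALSE)
      config <- yaml::read_yaml(config)
    } else {
      config <- jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stop("config must be a list or a file path",
                             call. = FALSE)
  config
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report (seed", x$provenance$seed, ")\n")
  for (s in setdiff(names(x), "provenance")) {
    cat(" -", s, "\n")
    if (s == "aggregation") {
      cat("     observed:", x$aggregation$observed_statistic,
          " p:", signif(x$aggregation$p_value, 3), "\n")
    }
  }
  invisible(x)
}
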