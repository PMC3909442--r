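# Readers and writers for the plain-text artifact formats, with strict
# schema validation.

#' Load a gene-by-sample expression matrix from TSV
#'
#' Expected layout: tab-separated, header row of sample ids, first column
#' gene identifiers. Duplicate sample ids are an error. Duplicate gene ids
#' (multiple probes per symbol) are collapsed by keeping the probe with the
#' highest variance across samples — the common convention — unless
#' `collapse_duplicates = FALSE`, in which case they are an error.
#' Genes containing non-finite values are dropped with a message.
#'
#' @param path TSV file path.
#' @param collapse_duplicates Keep the most variant probe per duplicated
#'   gene id (default TRUE).
#' @return Numeric matrix, genes x samples.
#' @export
load_expression <- function(path, collapse_duplicates = TRUE) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("expression file '", path, "' needs a gene column plus at least ",
         "one sample column", call. = FALSE)
  genes <- as.character(df[[1]])
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  colnames(mat) <- names(df)[-1] # subsetting silently de-duplicates names
  if (anyDuplicated(colnames(mat)))
    stop("duplicate sample id(s) in '", path, "': ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]),
               collapse = ", "), call. = FALSE)
  rownames(mat) <- genes
  if (anyDuplicated(genes)) {
    if (!collapse_duplicates)
      stop("duplicate gene id(s) in '", path, "': ",
           paste(unique(genes[duplicated(genes)]), collapse = ", "),
           call. = FALSE)
    rv <- rowSums((mat - rowMeans(mat, na.rm = TRUE))^2, na.rm = TRUE) /
      max(1L, ncol(mat) - 1L)
    rv[!is.finite(rv)] <- -Inf
    keep <- unlist(lapply(split(seq_along(genes), genes), function(idx) {
      idx[which.max(rv[idx])]
    }), use.names = FALSE)
    message("collapsed ", length(genes) - length(keep),
            " duplicate probe(s) to the most variant per gene")
    mat <- mat[sort(keep), , drop = FALSE]
  }
  bad <- !apply(is.finite(mat), 1, all)
  if (any(bad)) {
    message("dropped ", sum(bad), " gene(s) with missing or non-finite ",
            "values")
    mat <- mat[!bad, , drop = FALSE]
  }
  mat
}

#' Write an expression matrix as TSV
#'
#' @param expression Numeric matrix, genes x samples.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_expression <- function(expression, path) {
  df <- data.frame(gene = rownames(expression), expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_columns <- function(df, need, path) {
  if (!all(need %in% names(df)))
    stop("'", path, "' needs columns: ", paste(need, collapse = ", "),
         " (found: ", paste(names(df), collapse = ", "), ")", call. = FALSE)
  invisible(df)
}

#' Load a family membership table (CSV: family_id, sample_id)
#' @param path CSV file path.
#' @return Data.frame with character `family_id` and `sample_id`.
#' @export
load_families <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("family_id", "sample_id"), path)
  df$family_id <- as.character(df$family_id)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id(s) in '", path, "': ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "), call. = FALSE)
  df
}

#' Load a subtype label table (CSV: sample_id, subtype)
#' @param path CSV file path.
#' @return Named character vector mapping sample id to subtype.
#' @export
load_labels <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("sample_id", "subtype"), path)
  as_label_vector(df)
}

#' Load a combined family/subtype table (CSV: family_id, sample_id, subtype)
#'
#' The format of the bundled `table3.csv` and `table4.csv` fixtures: one row
#' per tumor with its family and molecular subtype.
#'
#' @param path CSV file path.
#' @return List with `families` (data.frame) and `labels` (named vector),
#'   ready for [run_aggregation_test()].
#' @export
#' @examples
#' t3 <- load_family_subtypes(famagg_example("table3.csv"))
#' concordance_statistic(t3$families, t3$labels)
load_family_subtypes <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("family_id", "sample_id", "subtype"), path)
  list(families = df[, c("family_id", "sample_id")],
       labels = as_label_vector(df))
}

#' Load a sample annotation table (CSV with sample_id plus metadata)
#' @param path CSV file path.
#' @return Data.frame keyed by unique `sample_id`.
#' @export
load_annotation <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, "sample_id", path)
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id(s) in '", path, "': ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]),
               collapse = ", "), call. = FALSE)
  df
}

#' Load a subtype centroid table (CSV: gene, one column per subtype)
#' @param path CSV file path.
#' @return Numeric matrix, genes x subtypes, gene ids as row names.
#' @export
load_centroids <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1] != "gene")
    stop("centroid file '", path, "' needs header 'gene,<subtype>,...'",
         call. = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(df$gene)
  if (nrow(mat) < 2L) stop("centroid table needs >= 2 genes", call. = FALSE)
  if (anyDuplicated(colnames(mat)))
    stop("duplicate subtype name(s) in '", path, "'", call. = FALSE)
  if (anyDuplicated(rownames(mat)))
    stop("duplicate gene id(s) in '", path, "'", call. = FALSE)
  mat
}

#' Write a centroid table as CSV
#' @param centroids Numeric matrix, genes x subtypes.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_centroids <- function(centroids, path) {
  df <- data.frame(gene = rownames(centroids), centroids,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load an MS-MLPA methylation ratio table (CSV: sample_id, probe_id, ratio)
#' @param path CSV file path.
#' @return Data.frame with validated nonnegative ratios.
#' @export
load_ratios <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("sample_id", "probe_id", "ratio"), path)
  if (any(!is.finite(df$ratio) | df$ratio < 0))
    stop("negative or non-finite ratio(s) in '", path, "'", call. = FALSE)
  df
}

#' Load a linear signature model from CSV
#'
#' Format: comment header lines `#positive_class=`, `#negative_class=`,
#' `#intercept=`, `#subtype=`, followed by CSV columns `gene,weight`.
#'
#' @param path CSV file path.
#' @return A `signature_model`.
#' @export
load_signature <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#", "", ln), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  need <- c("positive_class", "negative_class", "intercept", "subtype")
  if (!all(need %in% names(meta)))
    stop("signature file '", path, "' must carry header lines: ",
         paste0("#", need, "=", collapse = ", "), call. = FALSE)
  df <- read.csv(textConnection(grep("^#", lines, value = TRUE,
                                     invert = TRUE)),
                 stringsAsFactors = FALSE)
  check_columns(df, c("gene", "weight"), path)
  new_signature_model(df$gene, df$weight,
                      as.numeric(meta$intercept),
                      meta$positive_class, meta$negative_class,
                      meta$subtype)
}

#' Write a linear signature model as CSV
#' @param model A `signature_model`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_signature <- function(model, path) {
  stopifnot(inherits(model, "signature_model"))
  header <- c(
    paste0("#positive_class=", model$class_labels["positive"]),
    paste0("#negative_class=", model$class_labels["negative"]),
    paste0("#intercept=", format(model$intercept, digits = 17)),
    paste0("#subtype=", model$applicable_subtype))
  body <- c("gene,weight",
            paste(model$signature_gene_ids,
                  format(unname(model$weights), digits = 17), sep = ","))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write an analysis report as JSON
#'
#' Serializes a report (e.g. an `aggregation_report` or the pipeline's
#' study report) to pretty-printed JSON with full numeric precision.
#'
#' @param report A list-like report object.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_report <- function(report, path) {
  ser <- rapply(unclass(report), function(x) {
    if (inherits(x, "table")) as.list(stats::setNames(as.integer(x),
                                                      names(x))) else x
  }, how = "replace")
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(path)
}
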