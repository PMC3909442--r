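# Nearest-centroid subtype classification and subtype distribution
# summaries.

#' Align an expression matrix with a centroid table on shared genes
#'
#' Restricts both objects to their shared genes, in centroid order, and
#' reports the overlap as a fraction of the centroid genes. Classification
#' quality degrades as centroid genes go missing, so an overlap below
#' `min_overlap` is a hard error naming the missing genes.
#'
#' @param expression Numeric matrix, genes x samples, with gene row names.
#' @param centroids Numeric matrix, genes x subtypes, with gene row names.
#' @param min_overlap Minimum tolerated fraction of centroid genes present
#'   in the expression matrix (default 0.5).
#' @return List: `expression` and `centroids` restricted to the shared
#'   genes (identical row order), and `overlap`, the fraction of centroid
#'   genes found.
#' @export
match_genes <- function(expression, centroids, min_overlap = 0.5) {
  shared <- intersect(rownames(centroids), rownames(expression))
  overlap <- length(shared) / nrow(centroids)
  if (overlap < min_overlap) {
    missing <- setdiff(rownames(centroids), rownames(expression))
    stop("only ", length(shared), "/", nrow(centroids),
         " centroid genes present (overlap ", signif(overlap, 3),
         " < ", min_overlap, "); missing: ",
         paste(head(missing, 10), collapse = ", "),
         if (length(missing) > 10) ", ...", call. = FALSE)
  }
  list(expression = expression[shared, , drop = FALSE],
       centroids = centroids[shared, , drop = FALSE],
       overlap = overlap)
}

#' Classify one expression profile by nearest centroid
#'
#' Correlates a single sample's profile with each subtype centroid and
#' assigns the subtype with the highest correlation. The default rank-based
#' (Spearman) correlation makes the call invariant to strictly monotone
#' transforms of the profile. Ties are broken deterministically in favour of
#' the first subtype in the centroid column order.
#'
#' @param profile Numeric vector, one expression value per gene, named or
#'   aligned with the centroid rows.
#' @param centroids Numeric matrix, genes x subtypes, gene-aligned with
#'   `profile`.
#' @param method Correlation kind: `"spearman"` (default) or `"pearson"`.
#' @param sample_id Optional sample identifier carried into the call.
#' @return A `subtype_call` list: `sample_id`, `assigned_subtype`, `scores`
#'   (named per-subtype correlations in \[-1, 1\]).
#' @export
classify_sample <- function(profile, centroids,
                            method = c("spearman", "pearson"),
                            sample_id = NA_character_) {
  method <- match.arg(method)
  if (length(profile) != nrow(centroids))
    stop("profile length (", length(profile),
         ") does not match centroid gene count (", nrow(centroids), ")",
         call. = FALSE)
  if (nrow(centroids) < 3L)
    stop("at least 3 genes are required for correlation-based assignment",
         call. = FALSE)
  if (stats::sd(profile) == 0)
    stop("profile has zero variance; correlation with the centroids is ",
         "undefined. Check that the sample column holds real expression ",
         "values (not a constant fill).", call. = FALSE)
  zero_var <- apply(centroids, 2, stats::sd) == 0
  if (any(zero_var))
    stop("centroid column(s) with zero variance: ",
         paste(colnames(centroids)[zero_var], collapse = ", "),
         call. = FALSE)
  scores <- drop(stats::cor(profile, centroids, method = method))
  names(scores) <- colnames(centroids)
  structure(list(sample_id = sample_id,
                 assigned_subtype = colnames(centroids)[which.max(scores)],
                 scores = scores),
            class = "subtype_call")
}

#' @export
print.subtype_call <- function(x, ...) {
  cat("Sample", x$sample_id, "->", x$assigned_subtype,
      sprintf("(score %.3f)\n", max(x$scores)))
  invisible(x)
}

#' Classify every sample of a cohort by nearest centroid
#'
#' Vectorized [classify_sample()] over the columns of an expression matrix,
#' after aligning genes with [match_genes()].
#'
#' @inheritParams match_genes
#' @inheritParams classify_sample
#' @return A data.frame with one row per sample: `sample_id`,
#'   `assigned_subtype`, and one `score_<subtype>` column per subtype.
#' @export
#' @examples
#' cfg <- synthetic_config(n_genes = 50, sigma = 0.5,
#'                         family_sizes = rep(1, 20))
#' co <- generate_cohort(cfg)
#' calls <- classify_cohort(co$expression, co$centroids)
#' mean(calls$assigned_subtype == co$annotation$subtype)
classify_cohort <- function(expression, centroids,
                            method = c("spearman", "pearson"),
                            min_overlap = 0.5) {
  method <- match.arg(method)
  aligned <- match_genes(expression, centroids, min_overlap = min_overlap)
  calls <- lapply(colnames(aligned$expression), function(s) {
    classify_sample(aligned$expression[, s], aligned$centroids,
                    method = method, sample_id = s)
  })
  scores <- do.call(rbind, lapply(calls, `[[`, "scores"))
  colnames(scores) <- paste0("score_", colnames(aligned$centroids))
  out <- data.frame(
    sample_id = vapply(calls, `[[`, character(1), "sample_id"),
    assigned_subtype = vapply(calls, `[[`, character(1), "assigned_subtype"),
    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(scores))
}

#' Per-group subtype counts and percentages
#'
#' Tabulates assigned subtypes within groups, with percentages rounded
#' half-away-from-zero to integer percent (the convention of clinical
#' summary tables). Groups with no samples are reported with zero counts
#' and flagged in the `empty` column.
#'
#' @param calls Data.frame of calls (needs `sample_id` and
#'   `assigned_subtype`), as returned by [classify_cohort()].
#' @param groups Named character (or factor) vector mapping sample id to
#'   group; every call's sample must be present. Factor levels with no
#'   samples yield flagged zero rows.
#' @return Data.frame: `group`, `subtype`, `count`, `total`, `percent`,
#'   `empty`.
#' @export
subtype_distribution <- function(calls, groups) {
  missing <- setdiff(calls$sample_id, names(groups))
  if (length(missing))
    stop("no group for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  g <- groups[calls$sample_id]
  if (!is.factor(g)) g <- factor(g)
  subtype <- factor(calls$assigned_subtype,
                    levels = sort(unique(calls$assigned_subtype)))
  tab <- table(group = g, subtype = subtype)
  totals <- rowSums(tab)
  out <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(out) <- c("group", "subtype", "count")
  out$total <- totals[out$group]
  out$percent <- ifelse(out$total > 0,
                        round_half_away(100 * out$count / out$total), 0)
  out$empty <- out$total == 0
  out[order(out$group, out$subtype), , drop = FALSE]
}

#' Exact test of subtype enrichment between two groups
#'
#' Two-sided Fisher's exact test on the 2x2 table (subtype vs not, group A
#' vs group B): the probability, under fixed margins, of tables as or less
#' likely than the observed one.
#'
#' @param count_a,total_a Subtype count and group size in group A.
#' @param count_b,total_b Subtype count and group size in group B.
#' @return Two-sided exact p-value in (0, 1].
#' @export
#' @examples
#' subtype_enrichment_test(5, 10, 5, 10) # identical proportions -> 1
subtype_enrichment_test <- function(count_a, total_a, count_b, total_b) {
  counts <- c(count_a, total_a, count_b, total_b)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts and totals must be nonnegative integers", call. = FALSE)
  if (count_a > total_a || count_b > total_b)
    stop("counts cannot exceed group totals", call. = FALSE)
  tab <- matrix(c(count_a, total_a - count_a,
                  count_b, total_b - count_b), nrow = 2)
  stats::fisher.test(tab)$p.value
}
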