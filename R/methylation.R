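# Promoter methylation calling from MS-MLPA ratios and association with
# expression of the silenced gene.

#' Call promoter methylation from MS-MLPA ratios
#'
#' A probe is called positive when its methylation ratio strictly exceeds
#' the threshold (default 0.2, the conventional MS-MLPA positivity cutoff);
#' a ratio exactly at the threshold is negative.
#'
#' @param ratios Data.frame with columns `sample_id`, `probe_id`, `ratio`
#'   (nonnegative reals, typically in \[0, 1.5\]).
#' @param threshold Positivity cutoff (default 0.2), strict inequality.
#' @return The input data.frame with an added logical `positive` column.
#' @export
#' @examples
#' r <- data.frame(sample_id = c("s1", "s2", "s3"),
#'                 probe_id = "BRCA1_promoter",
#'                 ratio = c(0.25, 0.20, 0.0))
#' call_methylation(r)$positive # TRUE FALSE FALSE
call_methylation <- function(ratios, threshold = 0.2) {
  need <- c("sample_id", "probe_id", "ratio")
  if (!all(need %in% names(ratios)))
    stop("ratio table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (threshold < 0) stop("threshold must be >= 0", call. = FALSE)
  bad <- !is.finite(ratios$ratio) | ratios$ratio < 0
  if (any(bad))
    stop("negative or non-finite methylation ratio(s) for sample(s): ",
         paste(unique(ratios$sample_id[bad]), collapse = ", "),
         call. = FALSE)
  ratios$positive <- ratios$ratio > threshold
  ratios
}

#' Per-sample promoter positivity under the any-probe rule
#'
#' A sample is promoter-positive when any of its probes is positive.
#' MS-MLPA kits carry several probes per promoter; how they are summarized
#' into one call per sample is a reporting choice, and the any-probe rule
#' is the sensitive (and here documented) one.
#'
#' @param calls Output of [call_methylation()].
#' @return Named logical vector, one entry per sample.
#' @export
promoter_positive <- function(calls) {
  if (!"positive" %in% names(calls))
    stop("expected calls from call_methylation() (missing 'positive')",
         call. = FALSE)
  out <- tapply(calls$positive, calls$sample_id, any)
  stats::setNames(as.logical(out), names(out))
}

#' Association between promoter methylation and gene expression
#'
#' Two-sample t-test of the silenced gene's expression in methylated versus
#' unmethylated samples. Welch's unequal-variance form is the default — the
#' methylated group is typically far smaller than the unmethylated one —
#' with Student's pooled-variance form behind `var_equal = TRUE`.
#'
#' @param expression_values Named numeric vector: the gene's expression per
#'   sample.
#' @param calls Output of [call_methylation()] (summarized per sample with
#'   the any-probe rule), or a named logical vector of per-sample
#'   methylation status.
#' @param var_equal Use the pooled-variance (Student) form (default FALSE,
#'   i.e. Welch).
#' @return List: `statistic` (t), `p_value` (two-sided), `mean_methylated`,
#'   `mean_unmethylated`, `n_methylated`, `n_unmethylated`, `method`.
#' @export
expression_association <- function(expression_values, calls,
                                   var_equal = FALSE) {
  status <- if (is.logical(calls) && !is.null(names(calls))) calls
            else promoter_positive(calls)
  shared <- intersect(names(expression_values), names(status))
  pos <- expression_values[shared][status[shared]]
  neg <- expression_values[shared][!status[shared]]
  if (length(pos) < 2L || length(neg) < 2L)
    stop("each group needs >= 2 samples for the t-test (methylated n = ",
         length(pos), ", unmethylated n = ", length(neg), ")",
         call. = FALSE)
  tt <- stats::t.test(pos, neg, var.equal = var_equal)
  list(statistic = unname(tt$statistic),
       p_value = tt$p.value,
       mean_methylated = mean(pos),
       mean_unmethylated = mean(neg),
       n_methylated = length(pos),
       n_unmethylated = length(neg),
       method = if (var_equal) "student" else "welch")
}
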