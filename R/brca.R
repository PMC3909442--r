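# Subtype-restricted linear signature classifiers for BRCA1-like /
# BRCA2-like phenotype calls.

new_signature_model <- function(signature_gene_ids, weights, intercept,
                                positive_class, negative_class,
                                applicable_subtype, scaled = FALSE) {
  weights <- as.numeric(weights)
  if (length(weights) != length(signature_gene_ids))
    stop("one weight per signature gene is required", call. = FALSE)
  if (all(weights == 0))
    stop("signature weights cannot all be zero", call. = FALSE)
  structure(
    list(signature_gene_ids = as.character(signature_gene_ids),
         class_labels = c(positive = positive_class,
                          negative = negative_class),
         weights = stats::setNames(weights, signature_gene_ids),
         intercept = as.numeric(intercept),
         applicable_subtype = applicable_subtype,
         scaled = scaled),
    class = "signature_model")
}

#' @export
print.signature_model <- function(x, ...) {
  cat("Linear signature model (", length(x$signature_gene_ids), " genes)\n",
      sep = "")
  cat("  classes:", x$class_labels["positive"], "(score > 0) vs",
      x$class_labels["negative"], "\n")
  cat("  applicable subtype:", x$applicable_subtype, "\n")
  invisible(x)
}

#' Train a linear signature classifier on a gene subset
#'
#' Fits a maximum-margin linear decision rule (soft-margin support vector
#' machine, linear kernel) on the signature-gene subspace. By default each
#' gene is z-scored with its training mean and standard deviation; the
#' standardization is folded back into the returned weights and intercept,
#' so the model scores raw expression directly. Intended as a convenience
#' for synthetic experiments — published signature models are loaded as
#' data via [load_signature()].
#'
#' @param expression Numeric matrix, genes x samples.
#' @param class_of Named character vector mapping sample id to class label;
#'   exactly two classes, each with at least two samples.
#' @param signature_genes Gene ids defining the signature subspace; all must
#'   be present in `expression`.
#' @param applicable_subtype Subtype the model is valid for (used by
#'   [predict_brca_like()] to gate predictions).
#' @param positive_class Which class label maps to positive decision scores
#'   (default: the first class in sorted order).
#' @param cost Soft-margin regularization constant (default 1).
#' @param scale_genes Z-score genes with training statistics (default TRUE).
#' @return A `signature_model`: gene ids, weights, intercept, class labels,
#'   applicable subtype. `decision score = sum(weights * expression) +
#'   intercept`, positive scores meaning `positive_class`.
#' @export
train_signature_model <- function(expression, class_of, signature_genes,
                                  applicable_subtype,
                                  positive_class = NULL, cost = 1,
                                  scale_genes = TRUE) {
  missing_genes <- setdiff(signature_genes, rownames(expression))
  if (length(missing_genes))
    stop("signature gene(s) absent from the expression matrix: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  samples <- names(class_of)
  missing_samples <- setdiff(samples, colnames(expression))
  if (length(missing_samples))
    stop("labelled sample(s) absent from the expression matrix: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  classes <- sort(unique(as.character(class_of)))
  if (length(classes) != 2L)
    stop("exactly two classes are required, got: ",
         paste(classes, collapse = ", "), call. = FALSE)
  if (any(table(class_of) < 2L))
    stop("each class needs at least two samples (got ",
         paste(sprintf("%s=%d", names(table(class_of)), table(class_of)),
               collapse = ", "), ")", call. = FALSE)
  if (is.null(positive_class)) positive_class <- classes[1]
  if (!positive_class %in% classes)
    stop("positive_class '", positive_class, "' is not one of the training ",
         "classes", call. = FALSE)
  negative_class <- setdiff(classes, positive_class)

  x <- t(expression[signature_genes, samples, drop = FALSE])
  if (scale_genes) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    if (any(scl == 0))
      stop("zero-variance signature gene(s) in the training data: ",
           paste(signature_genes[scl == 0], collapse = ", "), call. = FALSE)
    xs <- scale(x, center = ctr, scale = scl)
  } else {
    xs <- x
  }
  y <- factor(as.character(class_of), levels = classes)
  fit <- e1071::svm(xs, y, kernel = "linear", cost = cost, scale = FALSE,
                    type = "C-classification")
  w <- drop(crossprod(fit$coefs, fit$SV))
  b <- -fit$rho
  # e1071 orients decision values so that > 0 means fit$levels[1]
  if (fit$levels[1] != positive_class) {
    w <- -w
    b <- -b
  }
  if (scale_genes) {
    b <- b - sum(w * ctr / scl)
    w <- w / scl
  }
  new_signature_model(signature_genes, w, b, positive_class, negative_class,
                      applicable_subtype, scaled = scale_genes)
}

#' Score eligible samples with a signature model
#'
#' Applies a linear signature model to the samples whose assigned subtype
#' matches the model's `applicable_subtype`; all other samples are omitted
#' (with a message). The decision score is the weighted sum of the
#' signature genes' expression plus the intercept; a strictly positive
#' score yields the positive (BRCA-like) class, and a score of exactly zero
#' is assigned the negative (sporadic-like) class — the conservative
#' boundary convention.
#'
#' @param model A `signature_model` (trained or loaded).
#' @param expression Numeric matrix, genes x samples.
#' @param calls Data.frame of subtype calls (needs `sample_id` and
#'   `assigned_subtype`), as from [classify_cohort()].
#' @return Data.frame: `sample_id`, `decision_score`, `predicted_class`,
#'   one row per eligible sample (possibly zero rows, with a warning).
#' @export
predict_brca_like <- function(model, expression, calls) {
  stopifnot(inherits(model, "signature_model"))
  missing_genes <- setdiff(model$signature_gene_ids, rownames(expression))
  if (length(missing_genes))
    stop("signature gene(s) absent from the expression matrix: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  eligible <- calls$sample_id[calls$assigned_subtype ==
                                model$applicable_subtype]
  skipped <- setdiff(calls$sample_id, eligible)
  if (length(skipped))
    message(length(skipped), " sample(s) outside subtype '",
            model$applicable_subtype, "' omitted from signature scoring")
  empty <- data.frame(sample_id = character(0),
                      decision_score = numeric(0),
                      predicted_class = character(0),
                      stringsAsFactors = FALSE)
  if (!length(eligible)) {
    warning("no samples with subtype '", model$applicable_subtype,
            "'; returning empty prediction set", call. = FALSE)
    return(empty)
  }
  xs <- expression[model$signature_gene_ids, eligible, drop = FALSE]
  score <- drop(crossprod(xs, model$weights)) + model$intercept
  data.frame(sample_id = eligible,
             decision_score = unname(score),
             predicted_class = ifelse(score > 0,
                                      model$class_labels["positive"],
                                      model$class_labels["negative"]),
             stringsAsFactors = FALSE, row.names = NULL)
}
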