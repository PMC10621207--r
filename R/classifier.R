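#' Log-likelihood of a mutation catalog under a cluster template
#'
#' The likelihood of observing a sample's n mutations given membership of a
#' cluster is the product over mutations of the per-category template
#' probabilities; in count form this is `sum_j count_j * log(p_j)`,
#' evaluated in log space because products of thousands of sub-1 terms
#' underflow. An empty catalog contributes 0 by convention (callers reject
#' empty catalogs before classification).
#'
#' @param counts Numeric vector of category counts.
#' @param template Probability vector over the same categories; must be
#'   strictly positive (apply the model's smoothing floor first).
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(counts, template) {
  if (length(counts) != length(template)) {
    stop("counts and template lengths differ", call. = FALSE)
  }
  if (any(template <= 0)) {
    stop("template contains zero probabilities; apply the smoothing floor ",
         "before computing likelihoods", call. = FALSE)
  }
  sum(as.numeric(counts) * log(as.numeric(template)))
}

#' Posterior cluster assignment for one catalog row
#'
#' Bayes' theorem over the model's K clusters:
#' `P(cluster_i | S) = P(S | cluster_i) P(cluster_i) / P(S)`, with the
#' evidence `P(S)` the prior-weighted sum of the per-cluster likelihoods.
#' Computed in log space and normalized by log-sum-exp. The assigned
#' phenotype is the argmax-posterior cluster (ties broken toward the lowest
#' cluster index).
#'
#' @param counts Numeric vector of 179 category counts with at least one
#'   classifiable mutation.
#' @param model `hrd_cluster_model`.
#' @return List of class `hrd_posterior`: `posteriors` (named, sums to 1),
#'   `log_evidence`, `p_hrd` (posterior mass on HRD-flagged clusters),
#'   `assigned_phenotype`, `n_mutations`.
#' @export
posterior <- function(counts, model) {
  counts <- as.numeric(counts)
  if (sum(counts) <= 0) {
    stop("no classifiable mutations: posterior is undefined for an empty ",
         "catalog", call. = FALSE)
  }
  loglik <- vapply(
    seq_along(model$cluster_ids),
    function(i) log_likelihood(counts, model$templates[i, ]),
    numeric(1)
  )
  logpost <- loglik + log(model$priors)
  m <- max(logpost)
  log_evidence <- m + log(sum(exp(logpost - m)))
  post <- exp(logpost - log_evidence)
  names(post) <- model$cluster_ids
  structure(
    list(
      posteriors = post,
      log_evidence = log_evidence,
      p_hrd = if (any(model$hrd_flags)) sum(post[model$hrd_flags]) else NA_real_,
      assigned_phenotype = model$cluster_ids[which.max(post)],
      n_mutations = sum(counts)
    ),
    class = "hrd_posterior"
  )
}

#' Probability that a sample is HRD
#'
#' The posterior mass a sample places on the HRD-flagged clusters (in the
#' reference model, 7 of the 20 signature phenotypes).
#'
#' @param result `hrd_posterior` from [posterior()].
#' @param model The model used to produce it.
#' @return Scalar in \[0, 1\].
#' @export
hrd_probability <- function(result, model) {
  if (!any(model$hrd_flags)) {
    stop("model has no HRD-flagged clusters", call. = FALSE)
  }
  # guard against one-ulp excursions outside [0, 1] from the normalization
  min(1, max(0, sum(result$posteriors[model$hrd_flags])))
}

#' Call HRD status from p(HRD)
#'
#' Strict threshold: a sample is HR-deficient iff its probability exceeds
#' the cutoff. The default 0.79 maximises the F-score against HR-gene-defect
#' labels in the exome cohort the classifier was calibrated on; 0.5 is the
#' natural alternative cutoff.
#'
#' @param p_hrd Numeric vector of probabilities in \[0, 1\].
#' @param threshold Scalar cutoff in \[0, 1\].
#' @return Logical vector: `TRUE` = HR-deficient.
#' @export
call_hrd <- function(p_hrd, threshold = 0.79) {
  if (any(is.na(p_hrd)) || any(p_hrd < 0) || any(p_hrd > 1)) {
    stop("p_hrd must lie in [0, 1]", call. = FALSE)
  }
  if (length(threshold) != 1L || is.na(threshold) || threshold < 0 || threshold > 1) {
    stop("threshold must lie in [0, 1]", call. = FALSE)
  }
  p_hrd > threshold
}

#' Reweight the indel channel of a cluster model
#'
#' Multiplies the 83 indel entries of every template by `factor`. In the
#' default `"renormalize"` mode each template is rescaled to sum to 1
#' afterwards, keeping the generative interpretation valid; `"raw"` leaves
#' the templates unnormalized, multiplying the raw per-mutation likelihood
#' terms instead. Factor 1 is an exact identity in both modes.
#'
#' @param model `hrd_cluster_model`.
#' @param factor Positive scalar (the sweep in the simulation study uses
#'   1/5, 1/4, 1/3, 1/2, 1, 2, 3, 4, 5).
#' @param mode `"renormalize"` or `"raw"`.
#' @param mask Logical vector marking the indel columns; defaults to the
#'   canonical 179-category channel mask (toy models with other widths must
#'   supply their own).
#' @return A new `hrd_cluster_model`.
#' @export
reweight_indels <- function(model, factor, mode = c("renormalize", "raw"),
                            mask = NULL) {
  mode <- match.arg(mode)
  if (length(factor) != 1L || is.na(factor) || factor <= 0) {
    stop("indel weight factor must be > 0", call. = FALSE)
  }
  if (factor == 1) return(model)      # exact identity, bit for bit
  templates <- model$templates
  if (is.null(mask)) {
    if (ncol(templates) != N_CAT) {
      stop("model is not on the canonical 179 categories; supply `mask`",
           call. = FALSE)
    }
    mask <- indel_channel_mask()
  }
  templates[, mask] <- templates[, mask] * factor
  if (mode == "renormalize") {
    templates <- templates / rowSums(templates)
  }
  out <- model
  out$templates <- templates
  out
}

#' Classify every sample of a catalog
#'
#' Runs [posterior()] on each catalog row and assembles the classifier
#' output table: one row per sample with the K posterior columns, `p_hrd`,
#' `assigned_phenotype`, `hrd_call` and `n_mutations`. Samples without
#' classifiable mutations are an error unless `drop_empty = TRUE`, in which
#' case they are excluded and counted in the `n_empty` attribute (an empty
#' catalog never silently becomes an HR-proficient call).
#'
#' @param catalog Catalog matrix.
#' @param model `hrd_cluster_model` with at least one HRD-flagged cluster.
#' @param threshold HRD call cutoff (see [call_hrd()]).
#' @param drop_empty Exclude mutation-free samples instead of failing.
#' @return `data.frame` with columns `sample_id`, one per cluster id,
#'   `p_hrd`, `assigned_phenotype`, `hrd_call`, `n_mutations`.
#' @export
classify_catalog <- function(catalog, model, threshold = 0.79,
                             drop_empty = FALSE) {
  catalog <- as_catalog(catalog)
  empty <- rowSums(catalog) == 0
  if (any(empty) && !drop_empty) {
    stop("sample(s) without classifiable mutations: ",
         paste(rownames(catalog)[empty], collapse = ", "),
         " (use drop_empty = TRUE to exclude them)", call. = FALSE)
  }
  keep <- which(!empty)
  post <- matrix(NA_real_, nrow = length(keep), ncol = length(model$cluster_ids),
                 dimnames = list(rownames(catalog)[keep], model$cluster_ids))
  p_hrd <- numeric(length(keep))
  phen <- character(length(keep))
  for (j in seq_along(keep)) {
    r <- posterior(catalog[keep[j], ], model)
    post[j, ] <- r$posteriors
    p_hrd[j] <- hrd_probability(r, model)
    phen[j] <- r$assigned_phenotype
  }
  out <- data.frame(
    sample_id = rownames(catalog)[keep],
    post,
    p_hrd = p_hrd,
    assigned_phenotype = phen,
    hrd_call = call_hrd(p_hrd, threshold),
    n_mutations = as.integer(rowSums(catalog)[keep]),
    check.names = FALSE, stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "n_empty") <- sum(empty)
  out
}

# vectorized posterior evaluation for a whole catalog: one matrix product
# instead of a per-sample loop (the simulation studies call this hot path)
posterior_matrix <- function(catalog, model) {
  logpost <- catalog %*% t(log(model$templates)) +
    matrix(log(model$priors), nrow = nrow(catalog),
           ncol = length(model$priors), byrow = TRUE)
  m <- apply(logpost, 1L, max)
  post <- exp(logpost - m)
  post <- post / rowSums(post)
  colnames(post) <- model$cluster_ids
  post
}

#' Write / read classifier output tables
#'
#' @param calls Output of [classify_catalog()].
#' @param path TSV path.
#' @export
write_calls <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
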