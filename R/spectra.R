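#' Normalize a catalog row into a probability spectrum
#'
#' Applies per-category exome/genome frequency ratios (whole-genome spectra
#' are rescaled by the relative frequency of each mutation type within the
#' exome) and renormalizes to a probability vector. With all-ones factors
#' this is simply the row's empirical proportions.
#'
#' @param counts Numeric vector of 179 category counts (or any length
#'   matching `factors`).
#' @param factors Positive numeric vector of per-category exome/genome
#'   ratios; defaults to all ones.
#' @return Numeric probability vector summing to 1.
#' @export
normalize_spectrum <- function(counts, factors = NULL) {
  counts <- as.numeric(counts)
  if (is.null(factors)) factors <- rep(1, length(counts))
  if (length(factors) != length(counts)) {
    stop("factors length (", length(factors), ") != counts length (",
         length(counts), ")", call. = FALSE)
  }
  if (any(factors <= 0)) stop("normalization factors must be > 0", call. = FALSE)
  if (sum(counts) <= 0) stop("empty catalog row: no positive counts", call. = FALSE)
  w <- counts * factors
  w / sum(w)
}

#' Read a normalization-factor table
#'
#' TSV with columns `category` and `ratio`; categories must cover the
#' canonical enumeration. The exome/genome ratio tables are genome-build
#' artifacts supplied by the user; [uniform_factors()] gives the all-ones
#' default (no renormalization beyond proportions).
#'
#' @param path TSV path.
#' @return Named numeric vector of 179 ratios in canonical order.
#' @export
read_normalization_factors <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("category", "ratio") %in% colnames(tab))) {
    stop("factor TSV needs 'category' and 'ratio' columns", call. = FALSE)
  }
  canon <- catalog_categories()
  missing <- setdiff(canon, tab$category)
  if (length(missing) > 0L) {
    stop("factor table missing ", length(missing), " categories", call. = FALSE)
  }
  out <- tab$ratio[match(canon, tab$category)]
  if (any(out <= 0)) stop("ratios must be positive", call. = FALSE)
  names(out) <- canon
  out
}

#' @rdname read_normalization_factors
#' @export
uniform_factors <- function() {
  out <- rep(1, N_CAT)
  names(out) <- catalog_categories()
  out
}

#' Fit reference-signature exposures by non-negative least squares
#'
#' Decomposes a spectrum onto a set of reference signatures (rows summing to
#' 1) by minimizing the Euclidean reconstruction error subject to
#' non-negative weights, then renormalizes the weights to proportions.
#' SBS and indel signature sets are typically fitted separately on the
#' corresponding channel of the spectrum and the exposures concatenated
#' (see [fit_exposures_catalog()]).
#'
#' @param spectrum Numeric vector over the reference's category space.
#' @param refs Numeric matrix, signatures x categories, rows summing to 1.
#' @return List with `weights` (named proportions), `raw_weights` (NNLS
#'   solution) and `residual` (Euclidean reconstruction error).
#' @export
fit_exposures <- function(spectrum, refs) {
  refs <- as.matrix(refs)
  if (length(spectrum) != ncol(refs)) {
    stop("spectrum length does not match reference category space", call. = FALSE)
  }
  rs <- rowSums(refs)
  if (any(abs(rs - 1) > 1e-6) || any(refs < 0)) {
    stop("reference signature rows must be non-negative and sum to 1",
         call. = FALSE)
  }
  fit <- pracma::lsqnonneg(t(refs), as.numeric(spectrum))
  w <- fit$x
  names(w) <- rownames(refs)
  total <- sum(w)
  list(
    weights = if (total > 0) w / total else w,
    raw_weights = w,
    residual = sqrt(sum((as.numeric(spectrum) - as.numeric(t(refs) %*% w))^2))
  )
}

#' Fit SBS and indel exposures separately for every catalog sample
#'
#' Each sample's catalog row is split into its SBS and indel channels, each
#' channel normalized to proportions and fitted against the matching
#' reference set, and the two exposure vectors concatenated.
#'
#' @param catalog Catalog matrix ([as_catalog()]).
#' @param sbs_refs,id_refs Reference signature matrices over the 96 SBS /
#'   83 indel categories (rows summing to 1). Either may be `NULL` to skip
#'   that channel.
#' @param factors Optional 179-long normalization ratios applied before
#'   fitting.
#' @return Samples x signatures matrix of exposure proportions (each
#'   channel's block sums to 1 for samples with events in that channel).
#' @export
fit_exposures_catalog <- function(catalog, sbs_refs = NULL, id_refs = NULL,
                                  factors = NULL) {
  catalog <- as_catalog(catalog)
  if (is.null(factors)) factors <- uniform_factors()
  mask <- indel_channel_mask()
  blocks <- list()
  if (!is.null(sbs_refs)) {
    blocks$sbs <- channel_exposures(catalog[, !mask, drop = FALSE],
                                    factors[!mask], sbs_refs)
  }
  if (!is.null(id_refs)) {
    blocks$id <- channel_exposures(catalog[, mask, drop = FALSE],
                                   factors[mask], id_refs)
  }
  if (length(blocks) == 0L) stop("supply at least one reference set", call. = FALSE)
  do.call(cbind, unname(blocks))
}

channel_exposures <- function(counts, factors, refs) {
  refs <- as.matrix(refs)
  out <- matrix(0, nrow = nrow(counts), ncol = nrow(refs),
                dimnames = list(rownames(counts), rownames(refs)))
  for (i in seq_len(nrow(counts))) {
    if (sum(counts[i, ]) == 0) next   # no events in this channel
    spec <- normalize_spectrum(counts[i, ], factors)
    out[i, ] <- fit_exposures(spec, refs)$weights
  }
  out
}

#' Cluster exposure profiles by Gaussian mixture modelling
#'
#' Finite-mixture clustering of per-sample exposure vectors with the number
#' of clusters and covariance structure (spherical, diagonal or full)
#' selected jointly by BIC, as implemented in \pkg{mclust}. Singleton
#' clusters are flagged: phenotype templates built from one sample are not
#' meaningful and callers typically discard them.
#'
#' @param exposures Samples x signatures numeric matrix.
#' @param k_range Integer vector of candidate cluster counts.
#' @param seed Integer seed (mixture initialisation is seeded for
#'   reproducibility).
#' @return List with `labels` (integer cluster per sample), `k`, `model_name`
#'   (mclust covariance code), `bic`, and `singletons` (cluster ids of size
#'   1).
#' @import mclust
#' @export
cluster_exposures <- function(exposures, k_range = 1:9, seed = 1L) {
  exposures <- as.matrix(exposures)
  if (nrow(exposures) < 2L) stop("need at least 2 samples to cluster", call. = FALSE)
  if (length(k_range) == 0L || any(k_range < 1) || any(k_range > nrow(exposures))) {
    stop("k_range must be non-empty and within [1, n_samples]", call. = FALSE)
  }
  models <- if (ncol(exposures) == 1L) c("E", "V") else
    c("EII", "VII", "EEI", "VVI", "EEE", "VVV")
  set.seed(seed)
  fit <- mclust::Mclust(exposures, G = k_range, modelNames = models,
                        verbose = FALSE)
  if (is.null(fit)) stop("mixture model failed to fit for all k in range",
                         call. = FALSE)
  sizes <- table(fit$classification)
  list(
    labels = as.integer(fit$classification),
    k = fit$G,
    model_name = fit$modelName,
    bic = fit$bic,
    singletons = as.integer(names(sizes)[sizes == 1L])
  )
}

#' Build a cluster model of mean spectra and priors
#'
#' The phenotype template of each cluster is the arithmetic mean of its
#' member samples' normalized spectra (mean of per-sample proportion
#' vectors, not pooled counts, so hypermutated samples do not dominate),
#' floored at a small smoothing constant and renormalized; the prior of each
#' cluster is its share of the cohort.
#'
#' @param catalog Catalog matrix.
#' @param labels Cluster label per catalog row (character or integer).
#' @param hrd_clusters Labels of the HRD-associated clusters.
#' @param factors Optional 179-long normalization ratios.
#' @param floor Smoothing floor applied to templates (must be > 0 when the
#'   model will be used for likelihood evaluation; see
#'   [log_likelihood()]).
#' @return An object of class `hrd_cluster_model`: list with `cluster_ids`,
#'   `templates` (K x 179 row-stochastic matrix), `priors`, `hrd_flags`,
#'   `smoothing_floor`.
#' @export
build_model <- function(catalog, labels, hrd_clusters = character(0),
                        factors = NULL, floor = 1e-6) {
  catalog <- as_catalog(catalog)
  if (length(labels) != nrow(catalog)) {
    stop("labels length must equal number of catalog samples", call. = FALSE)
  }
  if (floor < 0) stop("smoothing floor must be >= 0", call. = FALSE)
  ids <- sort(unique(as.character(labels)))
  labels <- as.character(labels)
  templates <- matrix(0, nrow = length(ids), ncol = ncol(catalog),
                      dimnames = list(ids, colnames(catalog)))
  for (k in ids) {
    members <- which(labels == k)
    specs <- t(vapply(members, function(i) normalize_spectrum(catalog[i, ], factors),
                      numeric(ncol(catalog))))
    templates[k, ] <- colMeans(specs)
  }
  if (floor > 0) {
    templates <- pmax(templates, floor)
    templates <- templates / rowSums(templates)
  }
  priors <- as.numeric(table(factor(labels, levels = ids))) / length(labels)
  names(priors) <- ids
  new_cluster_model(ids, templates, priors, ids %in% as.character(hrd_clusters),
                    floor)
}

#' Construct a cluster model directly
#'
#' Low-level constructor used by [build_model()] and the synthetic
#' generators; also handy for toy models in examples and tests. Validates
#' that priors sum to 1 and dimensions agree.
#'
#' @param cluster_ids Character vector of K cluster names.
#' @param templates K x C row-stochastic template matrix.
#' @param priors K prior probabilities summing to 1.
#' @param hrd_flags K logicals marking HRD-associated clusters.
#' @param smoothing_floor Floor already applied to the templates.
#' @return `hrd_cluster_model`.
#' @export
new_cluster_model <- function(cluster_ids, templates, priors, hrd_flags,
                              smoothing_floor) {
  stopifnot(
    nrow(templates) == length(cluster_ids),
    length(priors) == length(cluster_ids),
    length(hrd_flags) == length(cluster_ids)
  )
  if (abs(sum(priors) - 1) > 1e-8) stop("priors must sum to 1", call. = FALSE)
  structure(
    list(
      cluster_ids = as.character(cluster_ids),
      templates = templates,
      priors = as.numeric(priors),
      hrd_flags = as.logical(hrd_flags),
      smoothing_floor = smoothing_floor
    ),
    class = "hrd_cluster_model"
  )
}

#' @export
print.hrd_cluster_model <- function(x, ...) {
  cat("hrd_cluster_model:", length(x$cluster_ids), "clusters over",
      ncol(x$templates), "categories;",
      sum(x$hrd_flags), "flagged HRD; floor =", x$smoothing_floor, "\n")
  invisible(x)
}

#' Serialize / restore a cluster model
#'
#' A single TSV bundle: a comment line records the smoothing floor, then one
#' row per cluster with its prior, HRD flag and 179 template entries, so
#' classification runs are reproducible bit-for-bit.
#'
#' @param model `hrd_cluster_model`.
#' @param path File path.
#' @export
write_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# smoothing_floor=", format(model$smoothing_floor, digits = 17)),
             con)
  tab <- data.frame(cluster_id = model$cluster_ids, prior = model$priors,
                    hrd_flag = model$hrd_flags, model$templates,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  first <- readLines(path, n = 1L)
  floor <- as.numeric(sub("^# smoothing_floor=", "", first))
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  templates <- as.matrix(tab[, setdiff(colnames(tab),
                                       c("cluster_id", "prior", "hrd_flag")),
                             drop = FALSE])
  rownames(templates) <- tab$cluster_id
  new_cluster_model(tab$cluster_id, templates, tab$prior,
                    as.logical(tab$hrd_flag), floor)
}
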