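#' Simulation study configuration
#'
#' Bundles the grids of the downsampling experiments: target mutation loads,
#' constrained indel proportions, iteration count and the indel-likelihood
#' weight factors.
#'
#' @param sizes Target mutation loads per downsampled sample.
#' @param indel_props Constrained indel proportions.
#' @param n_iterations Iterations per grid cell.
#' @param weight_factors Indel-likelihood multipliers for the weight sweep.
#' @param seed Root seed; every grid cell derives its own child stream so
#'   partial reruns reproduce exactly.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(sizes = c(25L, 50L, 100L),
                              indel_props = seq(0, 0.5, by = 0.05),
                              n_iterations = 100L,
                              weight_factors = c(1/5, 1/4, 1/3, 1/2, 1, 2, 3, 4, 5),
                              seed = 1L) {
  stopifnot(all(sizes > 0), all(indel_props >= 0 & indel_props <= 1),
            n_iterations > 0, all(weight_factors > 0))
  structure(
    list(sizes = as.integer(sizes), indel_props = indel_props,
         n_iterations = as.integer(n_iterations),
         weight_factors = weight_factors, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# deterministic child seed per (root, index tuple); kept below 2^31
child_seed <- function(root, ...) {
  idx <- c(...)
  s <- as.double(root) %% 2147483629
  for (v in idx) {
    s <- (s * 48271 + as.double(v) * 95831 + 1) %% 2147483629
  }
  as.integer(s) + 1L
}

#' Downsample a catalog row with replacement
#'
#' Emulates shallow exome coverage of a deeply characterised sample: draws
#' `n` mutation events with replacement from the row's empirical category
#' proportions. With `indel_prop` set, exactly `round(n * indel_prop)` events
#' (round-half-to-even) are drawn from the indel channel and the remainder
#' from the SBS channel, each multinomially on its within-channel
#' proportions.
#'
#' @param counts Numeric vector of 179 category counts.
#' @param n Target number of events.
#' @param indel_prop Constrained indel proportion, or `NULL` for an
#'   unconstrained multinomial over all 179 categories.
#' @return Integer vector of 179 counts summing to `n`.
#' @export
downsample_catalog <- function(counts, n, indel_prop = NULL) {
  counts <- as.numeric(counts)
  if (length(counts) != N_CAT) stop("expected a 179-category row", call. = FALSE)
  out <- integer(N_CAT)
  mask <- indel_channel_mask()
  if (is.null(indel_prop)) {
    if (sum(counts) <= 0) stop("cannot downsample an empty row", call. = FALSE)
    return(as.integer(stats::rmultinom(1, n, counts)))
  }
  n_indel <- round(n * indel_prop)        # round-half-to-even (base round)
  n_sbs <- n - n_indel
  if (n_indel > 0) {
    if (sum(counts[mask]) <= 0) {
      stop("indel channel is empty but ", n_indel, " indel events requested",
           call. = FALSE)
    }
    out[mask] <- as.integer(stats::rmultinom(1, n_indel, counts[mask]))
  }
  if (n_sbs > 0) {
    if (sum(counts[!mask]) <= 0) {
      stop("SBS channel is empty but ", n_sbs, " SBS events requested",
           call. = FALSE)
    }
    out[!mask] <- as.integer(stats::rmultinom(1, n_sbs, counts[!mask]))
  }
  out
}

#' Label signature-enriched samples by hierarchical clustering
#'
#' Ward-linkage hierarchical clustering of the exposure vectors, cut at two
#' groups; the group with the higher mean exposure of `signature_id` is
#' labeled enriched. This mirrors generating simulation truth labels from
#' SBS-signature contributions alone.
#'
#' @param exposures Samples x signatures matrix of exposure proportions.
#' @param signature_id Column name of the signature of interest.
#' @return Logical vector: `TRUE` = enriched.
#' @export
label_enriched <- function(exposures, signature_id) {
  exposures <- as.matrix(exposures)
  if (!signature_id %in% colnames(exposures)) {
    stop("signature '", signature_id, "' not present in exposures", call. = FALSE)
  }
  if (nrow(exposures) < 3L) stop("need at least 3 samples", call. = FALSE)
  d <- stats::dist(exposures)
  if (all(d == 0)) {
    stop("all exposure profiles identical: enrichment labels undefined",
         call. = FALSE)
  }
  groups <- stats::cutree(stats::hclust(d, method = "ward.D2"), k = 2L)
  means <- tapply(exposures[, signature_id], groups, mean)
  enriched_group <- as.integer(names(means)[which.max(means)])
  unname(groups == enriched_group)
}

#' Downsampling experiment: AUC by load and constrained indel proportion
#'
#' For every (size, indel proportion, iteration) grid cell, every catalog
#' row is downsampled with [downsample_catalog()], classified against the
#' model, and the AUC of p(HRD) (posterior mass on the flagged clusters)
#' against the truth labels recorded. Fully reproducible from the config
#' seed. Companion rank-sum comparisons of the per-iteration AUC between
#' consecutive proportion levels are returned alongside.
#'
#' @param catalog Catalog matrix (the deeply sequenced source samples).
#' @param truth Logical truth labels, one per catalog row, both classes
#'   present.
#' @param model `hrd_cluster_model` with flagged clusters.
#' @param cfg `simulation_config`.
#' @return List with `results` (size, indel_prop, iteration, auc) and
#'   `comparisons` (size, prop_a, prop_b, p_value, p_adjusted).
#' @export
run_downsampling_experiment <- function(catalog, truth, model, cfg) {
  catalog <- as_catalog(catalog)
  truth <- as.logical(truth)
  if (all(truth) || !any(truth)) {
    stop("truth must contain both classes", call. = FALSE)
  }
  grid <- expand.grid(size = cfg$sizes, indel_prop = cfg$indel_props,
                      iteration = seq_len(cfg$n_iterations))
  grid$auc <- NA_real_
  for (g in seq_len(nrow(grid))) {
    set.seed(child_seed(cfg$seed, match(grid$size[g], cfg$sizes),
                        match(grid$indel_prop[g], cfg$indel_props),
                        grid$iteration[g]))
    ds <- t(apply(catalog, 1L, downsample_catalog, n = grid$size[g],
                  indel_prop = grid$indel_prop[g]))
    post <- posterior_matrix(ds, model)
    p_hrd <- rowSums(post[, model$hrd_flags, drop = FALSE])
    grid$auc[g] <- auc(p_hrd, truth)
  }
  list(results = grid, comparisons = compare_prop_levels(grid))
}

compare_prop_levels <- function(grid) {
  props <- sort(unique(grid$indel_prop))
  if (length(props) < 2L) return(NULL)
  out <- do.call(rbind, lapply(unique(grid$size), function(s) {
    do.call(rbind, lapply(seq_len(length(props) - 1L), function(i) {
      a <- grid$auc[grid$size == s & grid$indel_prop == props[i]]
      b <- grid$auc[grid$size == s & grid$indel_prop == props[i + 1L]]
      data.frame(size = s, prop_a = props[i], prop_b = props[i + 1L],
                 p_value = rank_sum_test(a, b))
    }))
  }))
  out$p_adjusted <- bh_adjust(out$p_value)
  out
}

#' Indel-likelihood weight sweep
#'
#' Repeats the downsampling experiment at a fixed load (default 50 events,
#' unconstrained indel proportion) while multiplying the indel entries of
#' the model templates by each factor via [reweight_indels()].
#'
#' @inheritParams run_downsampling_experiment
#' @param size Fixed downsampling load.
#' @param reweight_mode Passed to [reweight_indels()].
#' @return `data.frame` with columns factor, iteration, auc.
#' @export
run_weight_sweep <- function(catalog, truth, model, cfg, size = 50L,
                             reweight_mode = "renormalize") {
  catalog <- as_catalog(catalog)
  truth <- as.logical(truth)
  if (all(truth) || !any(truth)) {
    stop("truth must contain both classes", call. = FALSE)
  }
  grid <- expand.grid(factor = cfg$weight_factors,
                      iteration = seq_len(cfg$n_iterations))
  grid$auc <- NA_real_
  models <- lapply(cfg$weight_factors, reweight_indels, model = model,
                   mode = reweight_mode)
  for (g in seq_len(nrow(grid))) {
    # the same child stream across factors: identical downsampled catalogs
    # are scored under each reweighted model, isolating the weight effect
    set.seed(child_seed(cfg$seed, 7L, grid$iteration[g]))
    ds <- t(apply(catalog, 1L, downsample_catalog, n = size, indel_prop = NULL))
    m <- models[[match(grid$factor[g], cfg$weight_factors)]]
    post <- posterior_matrix(ds, m)
    p_hrd <- rowSums(post[, m$hrd_flags, drop = FALSE])
    grid$auc[g] <- auc(p_hrd, truth)
  }
  grid
}

#' Full-phenotype reclassification study
#'
#' Downsamples every sample to each target load and scores, per cluster, the
#' one-vs-rest AUC of that cluster's posterior probability against the true
#' cluster labels; also aggregates the assigned-vs-true misassignment
#' matrix.
#'
#' @param catalog Catalog matrix.
#' @param labels True cluster id per catalog row; every label must exist in
#'   the model.
#' @inheritParams run_downsampling_experiment
#' @return List with `results` (cluster, size, iteration, auc) and
#'   `misassignment` (true cluster x assigned cluster count matrix, summed
#'   over sizes and iterations).
#' @export
run_reclassification_study <- function(catalog, labels, model, cfg) {
  catalog <- as_catalog(catalog)
  labels <- as.character(labels)
  unknown <- setdiff(unique(labels), model$cluster_ids)
  if (length(unknown) > 0L) {
    stop("cluster(s) absent from model: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  clusters <- intersect(model$cluster_ids, unique(labels))
  grid <- expand.grid(cluster = clusters, size = cfg$sizes,
                      iteration = seq_len(cfg$n_iterations),
                      stringsAsFactors = FALSE)
  grid$auc <- NA_real_
  mis <- matrix(0L, nrow = length(model$cluster_ids),
                ncol = length(model$cluster_ids),
                dimnames = list(true = model$cluster_ids,
                                assigned = model$cluster_ids))
  for (s in cfg$sizes) {
    for (it in seq_len(cfg$n_iterations)) {
      set.seed(child_seed(cfg$seed, 11L, match(s, cfg$sizes), it))
      ds <- t(apply(catalog, 1L, downsample_catalog, n = s, indel_prop = NULL))
      post <- posterior_matrix(ds, model)
      assigned <- model$cluster_ids[max.col(post, ties.method = "first")]
      for (i in seq_along(labels)) {
        mis[labels[i], assigned[i]] <- mis[labels[i], assigned[i]] + 1L
      }
      for (cl in clusters) {
        sel <- grid$cluster == cl & grid$size == s & grid$iteration == it
        grid$auc[sel] <- auc(post[, cl], labels == cl)
      }
    }
  }
  list(results = grid, misassignment = mis)
}
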