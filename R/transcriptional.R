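#' Gene-level filters for signature development
#'
#' Applies the pre-selection rules used before consensus gene selection:
#' mitochondrial, ribosomal and sex-chromosome genes are excluded, only
#' protein-coding genes are retained, and genes expressed in fewer than
#' `min_frac` of the cancer cells are dropped. Per-rule removal counts are
#' returned in the `removed` attribute.
#'
#' @param mat Gene x sample (or gene x cell) expression matrix.
#' @param annotations `data.frame` with columns `gene`, `biotype`,
#'   `chromosome`, and logical `mito`, `ribo`.
#' @param cancer_cells Optional column mask of cancer cells used for the
#'   expression-fraction rule; defaults to all columns.
#' @param min_frac Minimum fraction of cancer cells with nonzero expression
#'   (default 0.02).
#' @param strict Error on genes absent from the annotation (default keeps
#'   them with a warning).
#' @return The row-filtered matrix.
#' @export
filter_genes <- function(mat, annotations, cancer_cells = NULL,
                         min_frac = 0.02, strict = FALSE) {
  genes <- rownames(mat)
  if (is.null(cancer_cells)) cancer_cells <- rep(TRUE, ncol(mat))
  idx <- match(genes, annotations$gene)
  unannotated <- is.na(idx)
  if (any(unannotated)) {
    if (strict) {
      stop("genes missing from annotation: ",
           paste(utils::head(genes[unannotated], 5), collapse = ", "),
           call. = FALSE)
    }
    warning(sum(unannotated), " gene(s) missing from annotation retained",
            call. = FALSE)
  }
  ann <- annotations[idx, , drop = FALSE]
  drop_mito <- !unannotated & ann$mito %in% TRUE
  drop_ribo <- !unannotated & ann$ribo %in% TRUE
  drop_sex <- !unannotated & ann$chromosome %in% c("X", "Y", "chrX", "chrY")
  drop_biotype <- !unannotated & !(ann$biotype %in% "protein_coding")
  frac <- Matrix::rowSums(mat[, cancer_cells, drop = FALSE] > 0) /
    sum(cancer_cells)
  drop_lowfrac <- frac < min_frac
  drop <- drop_mito | drop_ribo | drop_sex | drop_biotype | drop_lowfrac
  out <- mat[!drop, , drop = FALSE]
  attr(out, "removed") <- c(
    mitochondrial = sum(drop_mito), ribosomal = sum(drop_ribo),
    sex_chromosome = sum(drop_sex), non_protein_coding = sum(drop_biotype),
    low_expression = sum(drop_lowfrac)
  )
  out
}

#' Quality-control filter and log-normalization for single cells
#'
#' Retains cells with between `min_features` and `max_features` detected
#' genes (inclusive) and mitochondrial content strictly below `max_mito`
#' (genes with an `MT-` prefix), then log-normalizes the surviving counts:
#' per-cell scaling to `scale_total` total counts followed by `log1p`.
#'
#' @param counts Gene x cell raw count matrix (gene names identify
#'   mitochondrial genes).
#' @param min_features,max_features Detected-feature bounds (default 200 and
#'   6000).
#' @param max_mito Mitochondrial count fraction cutoff (default 0.15,
#'   strict `<`).
#' @param scale_total Per-cell total after scaling (default 1e4).
#' @return Log-normalized matrix of the retained cells, with attribute
#'   `n_removed`.
#' @export
filter_cells <- function(counts, min_features = 200L, max_features = 6000L,
                         max_mito = 0.15, scale_total = 1e4) {
  n_feat <- Matrix::colSums(counts > 0)
  mito_genes <- grepl("^MT-", rownames(counts))
  totals <- Matrix::colSums(counts)
  mito_frac <- if (any(mito_genes)) {
    Matrix::colSums(counts[mito_genes, , drop = FALSE]) / pmax(totals, 1)
  } else {
    rep(0, ncol(counts))
  }
  keep <- n_feat >= min_features & n_feat <= max_features & mito_frac < max_mito
  if (!any(keep)) stop("no cells pass quality control", call. = FALSE)
  kept <- counts[, keep, drop = FALSE]
  inv_tot <- scale_total / Matrix::colSums(kept)
  if (methods::is(kept, "Matrix")) {
    norm <- kept %*% Matrix::Diagonal(x = inv_tot)
    out <- methods::as(norm, "CsparseMatrix")
    out@x <- log1p(out@x)             # log1p(0) = 0: sparsity preserved
    dimnames(out) <- dimnames(kept)
  } else {
    out <- log1p(t(t(kept) * inv_tot))
  }
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Selection configuration for the consensus elastic net
#'
#' @param alpha Elastic-net mixing parameter in (0, 1\] (default 0.25, the
#'   configuration retained for the final signature).
#' @param n_iterations Cross-validation repetitions whose selected gene sets
#'   are intersected (the full-scale signature uses 1000; the package
#'   default is a desk-scale 50).
#' @param n_folds CV folds (default 10).
#' @param class_weights `"none"` or `"balanced"` (inverse class frequency,
#'   normalized to mean 1).
#' @param seed Integer seed driving the CV fold streams.
#' @return List of class `selection_config`.
#' @export
selection_config <- function(alpha = 0.25, n_iterations = 50L, n_folds = 10L,
                             class_weights = c("none", "balanced"), seed = 1L) {
  class_weights <- match.arg(class_weights)
  stopifnot(alpha > 0, alpha <= 1, n_folds >= 2, n_iterations >= 1)
  structure(
    list(alpha = alpha, n_iterations = as.integer(n_iterations),
         n_folds = as.integer(n_folds), class_weights = class_weights,
         seed = as.integer(seed)),
    class = "selection_config"
  )
}

#' Consensus gene selection by repeated multinomial elastic net
#'
#' Runs `n_iterations` rounds of k-fold cross-validated multinomial
#' elastic-net regression (\pkg{glmnet}, grouped multinomial penalty, so a
#' gene's class coefficients enter or leave together) with re-randomized
#' folds, records the genes with nonzero coefficients at `lambda.min` in
#' each round, and returns the genes selected in every round. Predictors
#' are standardized internally by glmnet.
#'
#' @param X Samples x genes numeric matrix (column names are gene ids).
#' @param y Class labels (factor or character; the signature uses the four
#'   HRD/BRCA-defect groups).
#' @param cfg `selection_config`.
#' @return List with `genes` (consensus set), `frequency` (named selection
#'   counts over iterations), `n_iterations`.
#' @export
consensus_select <- function(X, y, cfg = selection_config()) {
  X <- as.matrix(X)
  y <- factor(y)
  if (any(table(y) < 2)) {
    stop("every class needs at least 2 samples", call. = FALSE)
  }
  if (any(table(y) < cfg$n_folds)) {
    stop("class smaller than n_folds = ", cfg$n_folds,
         "; reduce the number of folds", call. = FALSE)
  }
  weights <- if (cfg$class_weights == "balanced") {
    w <- 1 / table(y)[y]
    as.numeric(w / mean(w))
  } else {
    rep(1, length(y))
  }
  freq <- integer(ncol(X))
  names(freq) <- colnames(X)
  consensus <- colnames(X)
  for (it in seq_len(cfg$n_iterations)) {
    set.seed(child_seed(cfg$seed, 13L, it))
    folds <- sample(rep_len(seq_len(cfg$n_folds), length(y)))
    # CV error = misclassification rate: the deviance curve is monotone on
    # separable low-dimensional problems, making its lambda.min degenerate
    fit <- glmnet::cv.glmnet(X, y, family = "multinomial",
                             type.multinomial = "grouped",
                             type.measure = "class",
                             alpha = cfg$alpha, foldid = folds,
                             weights = weights, standardize = TRUE)
    co <- glmnet::coef.glmnet(fit$glmnet.fit, s = fit$lambda.min)
    nz <- Reduce(`|`, lapply(co, function(b) as.numeric(b[-1, 1]) != 0))
    selected <- colnames(X)[nz]
    freq[selected] <- freq[selected] + 1L
    consensus <- intersect(consensus, selected)
  }
  list(genes = consensus, frequency = freq, n_iterations = cfg$n_iterations)
}

#' Build nearest-centroid templates
#'
#' One template per group: the mean expression of each signature gene across
#' the group's training samples. Both the four-group (HRD-BRCA1, HRD-BRCA2,
#' HRD-BRCA-positive, HR-proficient) and the two-group (HRD /
#' HR-proficient) variants are simply different `labels` vectors.
#'
#' @param X Genes x samples expression matrix (training scale; record it in
#'   `scale`).
#' @param labels Group label per sample column.
#' @param genes Signature gene ids (subset of rownames, duplicate-free).
#' @param scale Free-text tag recording the expression scale templates were
#'   built on (training and scoring scales must match).
#' @return List of class `centroid_templates`: `group_names`, `genes`,
#'   `means` (groups x genes), `scale`.
#' @export
build_centroids <- function(X, labels, genes, scale = "log2") {
  labels <- as.character(labels)
  if (length(labels) != ncol(X)) {
    stop("one label per sample column required", call. = FALSE)
  }
  if (anyDuplicated(genes)) stop("signature gene list has duplicates", call. = FALSE)
  missing <- setdiff(genes, rownames(X))
  if (length(missing) > 0L) {
    stop("signature gene(s) absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  groups <- sort(unique(labels))
  means <- t(vapply(groups, function(g) {
    cols <- which(labels == g)
    Matrix::rowMeans(X[genes, cols, drop = FALSE])
  }, numeric(length(genes))))
  dimnames(means) <- list(groups, genes)
  structure(
    list(group_names = groups, genes = genes, means = means, scale = scale),
    class = "centroid_templates"
  )
}

#' Score one expression profile against centroid templates
#'
#' Pearson correlation between the sample's profile and each group template
#' over the signature genes. Genes absent from the sample are removed from
#' the signature for that sample and do not contribute. For two-group
#' templates the HRD score is `r(HRD) - r(HR-proficient)`. Samples with
#' fewer than 3 usable genes, or zero variance over them, are flagged
#' (`usable = FALSE`, correlations `NA`), never silently zeroed.
#'
#' @param x Named numeric expression vector (same scale as the templates).
#' @param templates `centroid_templates`.
#' @param hrd_group,proficient_group Group names used to form the HRD score
#'   (defaults `"HRD"` and `"HR_proficient"`; skipped if either is absent).
#' @return List with `correlations` (named per group), `hrd_score`,
#'   `n_genes_used`, `usable`.
#' @export
score_sample <- function(x, templates, hrd_group = "HRD",
                         proficient_group = "HR_proficient") {
  genes <- intersect(templates$genes, names(x))
  na <- list(correlations = stats::setNames(
    rep(NA_real_, length(templates$group_names)), templates$group_names),
    hrd_score = NA_real_, n_genes_used = length(genes), usable = FALSE)
  if (length(genes) < 3L) return(na)
  v <- as.numeric(x[genes])
  if (stats::sd(v) == 0) return(na)
  cors <- vapply(templates$group_names, function(g) {
    tv <- templates$means[g, genes]
    if (stats::sd(tv) == 0) NA_real_ else stats::cor(v, tv)
  }, numeric(1))
  hrd_score <- if (all(c(hrd_group, proficient_group) %in% names(cors))) {
    cors[[hrd_group]] - cors[[proficient_group]]
  } else {
    NA_real_
  }
  list(correlations = cors, hrd_score = hrd_score,
       n_genes_used = length(genes), usable = TRUE)
}

#' Classify samples by maximum template correlation
#'
#' @param X Genes x samples matrix on the template scale.
#' @param templates `centroid_templates`.
#' @return Character vector: the argmax-correlation group per sample (`NA`
#'   for unusable samples).
#' @export
assign_by_centroid <- function(X, templates) {
  vapply(seq_len(ncol(X)), function(j) {
    x <- X[, j]
    names(x) <- rownames(X)
    r <- score_sample(x, templates)
    if (!r$usable) return(NA_character_)
    names(which.max(r$correlations))
  }, character(1))
}

#' Score single cells and summarise per sample
#'
#' Applies [score_sample()] to every cell column (cells are expected to have
#' passed [filter_cells()] and be log-normalized on the template scale). A
#' cell is labeled HRD iff its score is strictly positive. Cells with too
#' few usable signature genes are excluded from the per-sample proportions
#' and counted.
#'
#' @param cells Genes x cells log-normalized matrix.
#' @param templates Two-group `centroid_templates`.
#' @param sample_map Character vector mapping each cell column to its sample.
#' @return List with `cell_scores` (`data.frame`: barcode, sample, hrd_score,
#'   hrd_cell, n_genes_used, usable) and `sample_summary` (`data.frame`:
#'   sample, n_cells, n_usable, prop_hrd, mean_score).
#' @export
score_cells <- function(cells, templates, sample_map) {
  if (length(sample_map) != ncol(cells)) {
    stop("sample_map must name every cell column", call. = FALSE)
  }
  scores <- vapply(seq_len(ncol(cells)), function(j) {
    x <- as.numeric(cells[, j])
    names(x) <- rownames(cells)
    r <- score_sample(x, templates)
    c(score = r$hrd_score, used = r$n_genes_used, usable = as.numeric(r$usable))
  }, numeric(3))
  cell_scores <- data.frame(
    barcode = if (is.null(colnames(cells))) as.character(seq_len(ncol(cells)))
              else colnames(cells),
    sample = as.character(sample_map),
    hrd_score = scores["score", ],
    hrd_cell = scores["usable", ] == 1 & !is.na(scores["score", ]) &
      scores["score", ] > 0,
    n_genes_used = as.integer(scores["used", ]),
    usable = scores["usable", ] == 1,
    stringsAsFactors = FALSE
  )
  summ <- do.call(rbind, lapply(split(cell_scores, cell_scores$sample), function(d) {
    u <- d[d$usable, , drop = FALSE]
    data.frame(
      sample = d$sample[1], n_cells = nrow(d), n_usable = nrow(u),
      prop_hrd = if (nrow(u) > 0) mean(u$hrd_cell) else NA_real_,
      mean_score = if (nrow(u) > 0) mean(u$hrd_score) else NA_real_,
      stringsAsFactors = FALSE
    )
  }))
  rownames(summ) <- NULL
  list(cell_scores = cell_scores, sample_summary = summ)
}

#' Serialize / restore centroid templates
#'
#' TSV bundle: a comment line records the expression scale, then one row per
#' gene with per-group centroid means.
#'
#' @param templates `centroid_templates`.
#' @param path File path.
#' @export
write_centroids <- function(templates, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# scale=", templates$scale), con)
  tab <- data.frame(gene = templates$genes, t(templates$means),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centroids
#' @export
read_centroids <- function(path) {
  first <- readLines(path, n = 1L)
  scale <- sub("^# scale=", "", first)
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  means <- t(as.matrix(tab[, -1, drop = FALSE]))
  colnames(means) <- tab$gene
  structure(
    list(group_names = rownames(means), genes = tab$gene, means = means,
         scale = scale),
    class = "centroid_templates"
  )
}
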