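make_annotation <- function(genes) {
  data.frame(
    gene = genes,
    biotype = "protein_coding",
    chromosome = "1",
    mito = FALSE,
    ribo = FALSE,
    stringsAsFactors = FALSE
  )
}

test_that("filter_genes applies each exclusion rule and logs counts", {
  genes <- c("KEEP1", "KEEP2", "MTGENE", "RIBO1", "CHRY1", "LNC1", "RARE1")
  mat <- matrix(1, nrow = 7, ncol = 100, dimnames = list(genes, NULL))
  mat["RARE1", ] <- c(rep(1, 1), rep(0, 99))   # expressed in 1% of cells
  ann <- make_annotation(genes)
  ann$mito[ann$gene == "MTGENE"] <- TRUE
  ann$ribo[ann$gene == "RIBO1"] <- TRUE
  ann$chromosome[ann$gene == "CHRY1"] <- "Y"
  ann$biotype[ann$gene == "LNC1"] <- "lincRNA"
  out <- filter_genes(mat, ann)
  expect_setequal(rownames(out), c("KEEP1", "KEEP2"))
  removed <- attr(out, "removed")
  expect_equal(unname(removed[c("mitochondrial", "ribosomal", "sex_chromosome",
                                "non_protein_coding", "low_expression")]),
               c(1, 1, 1, 1, 1))
  # all rules passing: identity
  clean <- matrix(1, nrow = 2, ncol = 10,
                  dimnames = list(c("KEEP1", "KEEP2"), NULL))
  expect_equal(dim(filter_genes(clean, make_annotation(c("KEEP1", "KEEP2")))),
               dim(clean))
  # unannotated gene: kept with warning, error under strict
  expect_warning(filter_genes(clean, make_annotation("KEEP1")), "missing")
  expect_error(filter_genes(clean, make_annotation("KEEP1"), strict = TRUE),
               "missing")
})

test_that("filter_cells enforces feature and mitochondrial bounds strictly", {
  genes <- c("MT-CO1", paste0("g", 1:9))
  counts <- matrix(0L, nrow = 10, ncol = 4,
                   dimnames = list(genes, paste0("c", 1:4)))
  counts[2:6, 1] <- 10L                 # 5 features: below 200 -> removed
  counts[2:10, 2] <- 50L                # 9 features, no mito
  counts[, 3] <- 20L                    # 10 features, mito = 20/200 = 10%
  counts[1, 4] <- 30L; counts[2:10, 4] <- 170L / 9  # exactly 15% mito
  counts <- round(counts)
  counts[1, 4] <- 30L; counts[2:10, 4] <- 19L       # 30/201 ~ 14.9%: kept
  out <- filter_cells(counts, min_features = 8)
  expect_false("c1" %in% colnames(out))
  expect_true(all(c("c2", "c3", "c4") %in% colnames(out)))

  # cell at exactly 15% mitochondrial is removed (strict <)
  counts2 <- counts
  counts2[1, 4] <- 30L; counts2[2:10, 4] <- 170L / 9
  counts2 <- matrix(as.integer(round(counts2)), 10, 4, dimnames = dimnames(counts))
  counts2[1, 4] <- 3L; counts2[2:10, 4] <- 0L; counts2[2:9, 4] <- 2L
  counts2[10, 4] <- 1L   # total 20, mito 3 -> 15%
  expect_equal(sum(counts2[, 4]), 20)
  out2 <- filter_cells(counts2, min_features = 2)
  expect_false("c4" %in% colnames(out2))

  # feature-count bounds: 300 features with 1% mito is retained
  big <- matrix(0L, nrow = 400, ncol = 1,
                dimnames = list(c("MT-CO1", paste0("g", 1:399)), "cell"))
  big[2:301, 1] <- 10L
  big[1, 1] <- 30L
  expect_equal(ncol(filter_cells(big)), 1)
  expect_error(filter_cells(big, min_features = 500), "no cells")

  # log-normalization: per-cell totals scaled then log1p
  norm <- filter_cells(counts, min_features = 8, scale_total = 100)
  expect_equal(unname(expm1(norm["g1", "c2"])),
               unname(100 * counts["g1", "c2"] / sum(counts[, "c2"])))
})

test_that("consensus selection recovers planted genes and shrinks with iterations", {
  ge <- generate_expression(n_genes = 60, n_informative = 4,
                            group_sizes = c(30, 30, 30, 30),
                            effect_size = 2.5, seed = 71)
  X <- t(ge$matrix)
  cfg1 <- selection_config(n_iterations = 1, seed = 5)
  one <- consensus_select(X, ge$labels, cfg1)
  expect_setequal(one$genes, names(one$frequency)[one$frequency == 1])

  cfg8 <- selection_config(n_iterations = 8, seed = 5)
  eight <- consensus_select(X, ge$labels, cfg8)
  # nested iteration prefixes: consensus can only shrink
  expect_true(all(eight$genes %in% one$genes))
  expect_true(all(ge$informative %in% eight$genes))

  expect_error(consensus_select(X[1:9, ], ge$labels[1:9],
                                selection_config(n_folds = 10)),
               "folds")
})

test_that("consensus selection stays sparse under a pure-noise design", {
  # with no class signal the CV-selected gene sets are unstable, so the
  # intersection over iterations collapses to a handful of chance genes
  # (the data are fixed across iterations, so genes with spuriously large
  # class differences can persist; the consensus never empties entirely)
  set.seed(99)
  Xn <- matrix(rnorm(200 * 100), 200, 100,
               dimnames = list(NULL, paste0("g", 1:100)))
  sel <- consensus_select(Xn, rep(1:4, each = 50),
                          selection_config(n_iterations = 20, seed = 3))
  expect_lte(length(sel$genes), 10)
})

test_that("centroid templates average group members and score by correlation", {
  X <- matrix(c(2, 1, 0,
                4, 3, 0,
                0, 1, 5,
                0, 3, 7), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  tem <- build_centroids(X, c("HRD", "HRD", "HR_proficient", "HR_proficient"),
                         c("g1", "g2", "g3"))
  expect_equal(unname(tem$means["HRD", ]), c(3, 2, 0))
  expect_equal(unname(tem$means["HR_proficient", ]), c(0, 2, 6))
  # single-sample group equals that sample
  tem1 <- build_centroids(X, c("A", "B", "B", "B"), c("g1", "g2"))
  expect_equal(unname(tem1$means["A", ]), c(2, 1))
  # permutation invariance
  perm <- c(3, 1, 4, 2)
  tem2 <- build_centroids(X[, perm],
                          c("HRD", "HRD", "HR_proficient", "HR_proficient")[perm],
                          c("g1", "g2", "g3"))
  expect_equal(tem2$means, tem$means)
  expect_error(build_centroids(X, c("A", "A", "A", "A"), c("g1", "gX")), "absent")

  # perfect linear relation scores r = 1
  s <- score_sample(c(g1 = 1, g2 = 2, g3 = 3),
                    build_centroids(matrix(c(2, 4, 6), 3,
                                           dimnames = list(c("g1", "g2", "g3"),
                                                           "t")),
                                    "HRD", c("g1", "g2", "g3")),
                    proficient_group = "none")
  expect_equal(unname(s$correlations["HRD"]), 1)
})

test_that("scoring is affine-invariant and handles missing genes by reduction", {
  set.seed(81)
  genes <- paste0("g", 1:20)
  tr <- matrix(rnorm(20 * 8), nrow = 20,
               dimnames = list(genes, paste0("s", 1:8)))
  tem <- build_centroids(tr, rep(c("HRD", "HR_proficient"), each = 4), genes)
  x <- rnorm(20)
  names(x) <- genes
  base <- score_sample(x, tem)
  shifted <- score_sample(3.7 * x + 11, tem)
  expect_equal(shifted$correlations, base$correlations, tolerance = 1e-12)
  expect_equal(shifted$hrd_score, base$hrd_score, tolerance = 1e-12)

  # dropping a gene equals recomputation on the reduced signature
  x2 <- x[-5]
  dropped <- score_sample(x2, tem)
  tem_red <- build_centroids(tr, rep(c("HRD", "HR_proficient"), each = 4),
                             genes[-5])
  recomputed <- score_sample(x2, tem_red)
  expect_equal(dropped$correlations, recomputed$correlations, tolerance = 1e-12)
  expect_equal(dropped$n_genes_used, 19)

  # too few genes or zero variance: flagged, not zeroed
  tiny <- score_sample(x[1:2], tem)
  expect_false(tiny$usable)
  expect_true(is.na(tiny$hrd_score))
  flat <- rep(1, 20); names(flat) <- genes
  expect_false(score_sample(flat, tem)$usable)
})

test_that("held-out class assignment by centroid correlation is accurate", {
  ge <- generate_expression(n_genes = 100, n_informative = 20,
                            group_sizes = c(50, 50, 50, 50),
                            effect_size = 2, seed = 91)
  n <- ncol(ge$matrix)
  set.seed(92)
  train <- sort(sample(n, n / 2))
  test <- setdiff(seq_len(n), train)
  tem <- build_centroids(ge$matrix[, train], ge$labels[train], ge$informative)
  pred <- assign_by_centroid(ge$matrix[, test], tem)
  expect_gte(mean(pred == ge$labels[test]), 0.95)
})

test_that("cell scoring labels by strict positivity and summarises per sample", {
  cc <- generate_cell_cohort(n_samples = 8, cells_per_sample = 120, seed = 101)
  filt <- filter_cells(cc$counts, min_features = 10)
  tem <- build_centroids(
    cbind(HRD = cc$hrd_mean, HR_proficient = cc$prof_mean),
    c("HRD", "HR_proficient"), names(cc$hrd_mean)
  )
  res <- score_cells(filt, tem, cc$sample_map[colnames(filt)])
  expect_equal(nrow(res$cell_scores), ncol(filt))
  expect_equal(res$cell_scores$hrd_cell,
               res$cell_scores$usable & res$cell_scores$hrd_score > 0)
  expect_true(all(res$sample_summary$prop_hrd >= 0 &
                    res$sample_summary$prop_hrd <= 1))
  # balanced two-population sample: proportion near the mixing parameter
  agree <- cor(res$sample_summary$prop_hrd,
               cc$theta[res$sample_summary$sample])
  expect_gt(agree, 0.8)

  # cells identical to the HRD template score positive, proportion 1
  pure <- matrix(rep(cc$hrd_mean, 5), ncol = 5,
                 dimnames = list(names(cc$hrd_mean), paste0("c", 1:5)))
  res_pure <- score_cells(pure, tem, rep("P", 5))
  expect_equal(res_pure$sample_summary$prop_hrd, 1)
})
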