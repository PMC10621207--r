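#' Synthetic cluster-structured catalog generators
#'
#' The generators emulate the data regime the classifier is designed for:
#' cohorts of tumours falling into signature-phenotype clusters, each
#' cluster characterised by a probability distribution over the 179 mutation
#' categories, with per-sample mutation loads in the low-count exome regime
#' and a controllable share of probability mass on the indel channel.
#'
#' @param n_clusters Number of clusters.
#' @param hrd_clusters Integer indices of the HRD-flagged clusters.
#' @param concentration Dirichlet concentration per cluster (scalar or
#'   vector); larger values give flatter, more similar templates.
#' @param indel_mass Total template probability on the 83 indel categories
#'   (scalar or per-cluster vector) in \[0, 1\].
#' @param n_samples Samples per cluster (scalar or vector); also sets the
#'   model priors.
#' @param load_mean,load_dispersion Negative-binomial per-sample mutation
#'   load (mean 50, dispersion 1 by default — the low-count exome regime).
#' @param seed Integer seed; generators are pure functions of spec + seed.
#' @return For `generate_cluster_model`: list with `model`
#'   (`hrd_cluster_model`) and `raw_templates` (pre-flooring).
#' @name synthetic-catalogs
NULL

#' @rdname synthetic-catalogs
#' @param floor Smoothing floor for the returned model.
#' @export
generate_cluster_model <- function(n_clusters, hrd_clusters = integer(0),
                                   concentration = 1, indel_mass = 0.1,
                                   n_samples = 10L, floor = 1e-6, seed = 1L) {
  stopifnot(n_clusters >= 1, all(indel_mass >= 0 & indel_mass <= 1),
            all(concentration > 0), all(n_samples > 0))
  concentration <- rep_len(concentration, n_clusters)
  indel_mass <- rep_len(indel_mass, n_clusters)
  n_samples <- rep_len(as.integer(n_samples), n_clusters)
  set.seed(seed)
  mask <- indel_channel_mask()
  templates <- matrix(0, nrow = n_clusters, ncol = N_CAT,
                      dimnames = list(paste0("C", seq_len(n_clusters)),
                                      catalog_categories()))
  for (k in seq_len(n_clusters)) {
    sbs <- stats::rgamma(N_SBS, shape = concentration[k])
    id <- stats::rgamma(N_ID, shape = concentration[k])
    templates[k, !mask] <- (1 - indel_mass[k]) * sbs / sum(sbs)
    templates[k, mask] <- if (indel_mass[k] > 0) indel_mass[k] * id / sum(id)
                          else 0
  }
  raw <- templates
  if (floor > 0) {
    templates <- pmax(templates, floor)
    templates <- templates / rowSums(templates)
  }
  flags <- seq_len(n_clusters) %in% hrd_clusters
  model <- new_cluster_model(rownames(templates), templates,
                             n_samples / sum(n_samples), flags, floor)
  list(model = model, raw_templates = raw, n_samples = n_samples)
}

#' @rdname synthetic-catalogs
#' @param model_spec Output of [generate_cluster_model()].
#' @param load_constant Fix every sample's load to this value instead of
#'   drawing from the negative binomial.
#' @export
generate_catalogs <- function(model_spec, load_mean = 50, load_dispersion = 1,
                              load_constant = NULL, seed = 1L) {
  model <- model_spec$model
  n_samples <- model_spec$n_samples
  set.seed(seed)
  rows <- list()
  labels <- character(0)
  for (k in seq_along(model$cluster_ids)) {
    for (s in seq_len(n_samples[k])) {
      load <- if (!is.null(load_constant)) load_constant else
        max(1L, stats::rnbinom(1, mu = load_mean, size = load_dispersion))
      rows[[length(rows) + 1L]] <-
        as.integer(stats::rmultinom(1, load, model$templates[k, ]))
      labels <- c(labels, model$cluster_ids[k])
    }
  }
  catalog <- do.call(rbind, rows)
  dimnames(catalog) <- list(paste0("S", seq_len(nrow(catalog))),
                            catalog_categories())
  list(catalog = as_catalog(catalog), labels = labels)
}

#' Synthetic reference genome + variant fixture with known category tallies
#'
#' Assembles a ~10 kb single-contig reference from engineered context blocks
#' (homopolymer runs of length 1-8, tandem repeats with unit sizes 2-5,
#' microhomology-flanked deletion sites, and SNV contexts on both strands),
#' each block carrying one variant whose ID83/SBS96 category is known *by
#' construction* — the truth tally never touches the classifiers, so it can
#' serve as an independent oracle for [build_catalog()]. A couple of
#' non-ACGT (OTHER) records are included to exercise the exclusion path.
#'
#' @param seed Integer seed (controls spacer sequence and block order).
#' @param sample_id Sample name written into the fixture.
#' @param dir Optional directory; when given, writes `ref.fa`, `variants.vcf`
#'   and `truth_tally.tsv` there.
#' @return List with `ref_seq` (named character), `variants` (variant
#'   table), `truth` (named category tally), `n_other`, and (when `dir` is
#'   set) the file `paths`.
#' @export
generate_reference_and_variants <- function(seed = 1L, sample_id = "SYN1",
                                            dir = NULL) {
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  # spacer avoiding accidental runs/repeats around block payloads: random
  # sequence with no two adjacent equal bases
  spacer <- function(n) {
    out <- character(n)
    out[1] <- sample(bases, 1)
    for (i in seq_len(n - 1L)) {
      out[i + 1L] <- sample(setdiff(bases, out[i]), 1)
    }
    paste(out, collapse = "")
  }

  blocks <- list()   # each: list(payload=, make_variant(offset)=..., label=)
  add <- function(payload, label, vpos, ref, alt) {
    blocks[[length(blocks) + 1L]] <<-
      list(payload = payload, label = label, vpos = vpos, ref = ref, alt = alt)
  }

  # --- SBS blocks: one per substitution type, pyrimidine and purine strand
  sbs_specs <- list(
    list(ctx = "ACA", alt = "T", label = "A[C>T]A"),
    list(ctx = "TGT", alt = "A", label = "A[C>T]A"),   # purine strand
    list(ctx = "GCG", alt = "A", label = "G[C>A]G"),
    list(ctx = "ATC", alt = "G", label = "A[T>G]C"),
    list(ctx = "CAT", alt = "C", label = "A[T>G]G"),   # A>C == T>G revcomp
    list(ctx = "TTA", alt = "C", label = "T[T>C]A"),
    list(ctx = "CCC", alt = "G", label = "C[C>G]C"),
    list(ctx = "GTG", alt = "A", label = "G[T>A]G")
  )
  for (s in sbs_specs) {
    add(s$ctx, s$label, vpos = 2L, ref = substr(s$ctx, 2, 2), alt = s$alt)
  }

  # trailing guard: two unequal bases, the first avoiding a given base so
  # the 3' flank can never extend an engineered run / repeat / homology
  guard2 <- function(avoid) {
    g1 <- setdiff(bases, avoid)[1]
    g2 <- setdiff(bases, c(g1, avoid))[1]
    paste0(g1, g2)
  }

  # --- 1bp deletions in homopolymers of length 1..8 (alternating C/T/A/G)
  hp_bases <- c("C", "T", "A", "G", "C", "T", "A", "G")
  for (len in 1:8) {
    b <- hp_bases[len]
    anchor <- setdiff(bases, b)[1]
    payload <- paste0(anchor, strrep(b, len), guard2(b))
    chan <- if (b %in% c("A", "G")) chartr("AG", "TC", b) else b
    add(payload, paste0("1:Del:", chan, ":", min(len, 6L)),
        vpos = 1L, ref = paste0(anchor, b), alt = anchor)
  }

  # --- 1bp insertions adjacent to runs of length 0..6
  for (len in 0:6) {
    b <- if (len %% 2 == 0) "C" else "T"
    payload <- paste0("G", strrep(b, len), guard2(b))
    add(payload, paste0("1:Ins:", b, ":", min(len, 5L)),
        vpos = 1L, ref = "G", alt = paste0("G", b))
  }

  # --- tandem-repeat deletions: unit lengths 2..5, copies 2..7
  units <- c("AC", "AGT", "ACGT", "ACGTC")
  for (u in units) {
    for (copies in c(2L, 3L, 6L, 7L)) {
      anchor <- "T"
      payload <- paste0(anchor, strrep(u, copies), guard2(substr(u, 1L, 1L)))
      lbin <- min(nchar(u), 5L)
      add(payload, paste0(lbin, ":Del:R:", min(copies, 6L)),
          vpos = 1L, ref = paste0(anchor, u), alt = anchor)
    }
  }

  # --- repeat insertions: unit lengths 2..5, pre-existing copies 0..6
  for (u in units) {
    for (copies in c(0L, 1L, 5L, 6L)) {
      anchor <- "T"
      payload <- paste0(anchor, strrep(u, copies), guard2(substr(u, 1L, 1L)))
      lbin <- min(nchar(u), 5L)
      add(payload, paste0(lbin, ":Ins:R:", min(copies, 5L)),
          vpos = 1L, ref = anchor, alt = paste0(anchor, u))
    }
  }

  # --- microhomology deletions: deleted sequence shares a prefix with the
  # 3' flank (no tandem repeat); anchor avoids the deleted sequence's last
  # base so no suffix homology arises on the 5' side
  mh_specs <- list(
    list(del = "CA", mh = "C", lab = "2:Del:M:1"),
    list(del = "CAT", mh = "C", lab = "3:Del:M:1"),
    list(del = "CAT", mh = "CA", lab = "3:Del:M:2"),
    list(del = "CATG", mh = "CAT", lab = "4:Del:M:3"),
    list(del = "CATGA", mh = "CATG", lab = "5:Del:M:4"),
    list(del = "CATGAC", mh = "CATGA", lab = "5:Del:M:5")
  )
  for (m in mh_specs) {
    last <- substr(m$del, nchar(m$del), nchar(m$del))
    next_after_mh <- substr(m$del, nchar(m$mh) + 1L, nchar(m$mh) + 1L)
    anchor <- setdiff(bases, last)[1]
    payload <- paste0(anchor, m$del, m$mh, guard2(next_after_mh))
    add(payload, m$lab, vpos = 1L, ref = paste0(anchor, m$del), alt = anchor)
  }

  # --- no-context deletion (neither repeat nor microhomology)
  add(paste0("TACG", guard2("A")), "3:Del:R:1", vpos = 1L,
      ref = "TACG", alt = "T")

  # --- OTHER records: MNV and a non-ACGT allele
  other <- list(
    list(payload = "ATG", ref = "TG", alt = "CA", vpos = 2L),
    list(payload = "ACA", ref = "C", alt = "N", vpos = 2L)
  )

  ord <- sample(seq_along(blocks))
  seq_parts <- character(0)
  vrows <- list()
  pos <- 0L
  emit <- function(part) {
    seq_parts <<- c(seq_parts, part)
    pos <<- pos + nchar(part)
  }
  emit(spacer(150L))
  truth <- stats::setNames(rep(0L, N_CAT), catalog_categories())
  for (b in blocks[ord]) {
    start <- pos
    emit(b$payload)
    vrows[[length(vrows) + 1L]] <- data.frame(
      chrom = "synth1", pos = start + b$vpos, ref = b$ref, alt = b$alt,
      stringsAsFactors = FALSE
    )
    truth[b$label] <- truth[b$label] + 1L
    emit(spacer(sample(120L:200L, 1)))
  }
  for (o in other) {
    start <- pos
    emit(o$payload)
    vrows[[length(vrows) + 1L]] <- data.frame(
      chrom = "synth1", pos = start + o$vpos, ref = o$ref, alt = o$alt,
      stringsAsFactors = FALSE
    )
    emit(spacer(sample(120L:200L, 1)))
  }
  emit(spacer(150L))

  contig <- paste(seq_parts, collapse = "")
  vtab <- do.call(rbind, vrows)
  variants <- data.frame(
    sample_id = sample_id, chrom = vtab$chrom, pos = vtab$pos,
    ref = vtab$ref, alt = vtab$alt,
    variant_class = classify_variant_type(vtab$ref, vtab$alt),
    stringsAsFactors = FALSE
  )
  ref_seq <- c(synth1 = contig)
  out <- list(ref_seq = ref_seq, variants = variants, truth = truth,
              n_other = length(other))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fa <- file.path(dir, "ref.fa")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(ref_seq), fa)
    vcf <- file.path(dir, "variants.vcf")
    write_fixture_vcf(variants, nchar(contig), vcf)
    tsv <- file.path(dir, "truth_tally.tsv")
    utils::write.table(
      data.frame(category = names(truth), count = as.integer(truth)),
      tsv, sep = "\t", quote = FALSE, row.names = FALSE
    )
    out$paths <- c(fasta = fa, vcf = vcf, truth = tsv)
  }
  out
}

# minimal VCF 4.2 writer for the synthetic fixture (reading uses vcfR)
write_fixture_vcf <- function(variants, contig_len, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=synth1,length=", contig_len, ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", variants$sample_id[1], sep = "\t")
  )
  ord <- order(variants$pos)
  body <- paste(variants$chrom[ord], variants$pos[ord], ".", variants$ref[ord],
                variants$alt[ord], ".", "PASS", ".", "GT", "0/1", sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Synthetic class-structured expression data
#'
#' Bulk mode: Gaussian log-scale expression, `n_informative` planted genes
#' receiving class-specific mean shifts of `effect_size * noise_sd` (class k
#' shifts a distinct third of the planted genes up, mimicking group-specific
#' programmes). Single-cell mode: per-cell negative-binomial depth, counts
#' multinomially allocated over an expression-derived proportion vector with
#' dropout, integer and sparse, meant to flow through [filter_cells()].
#'
#' @param n_genes Total genes.
#' @param n_informative Planted informative genes.
#' @param group_sizes Named or unnamed vector of samples per class.
#' @param effect_size Class-mean shift in `noise_sd` units.
#' @param noise_sd Residual SD on the log scale.
#' @param seed Integer seed.
#' @return List with `matrix` (genes x samples), `labels`, `informative`
#'   (planted gene ids).
#' @export
generate_expression <- function(n_genes = 100L, n_informative = 5L,
                                group_sizes = c(50L, 50L, 50L, 50L),
                                effect_size = 2, noise_sd = 1, seed = 1L) {
  stopifnot(n_informative <= n_genes, all(group_sizes > 0))
  set.seed(seed)
  n_classes <- length(group_sizes)
  classes <- if (!is.null(names(group_sizes))) names(group_sizes) else
    paste0("G", seq_len(n_classes))
  labels <- rep(classes, group_sizes)
  n <- sum(group_sizes)
  genes <- paste0("gene", seq_len(n_genes))
  base_mean <- stats::runif(n_genes, 2, 8)
  mat <- matrix(stats::rnorm(n_genes * n, mean = base_mean, sd = noise_sd),
                nrow = n_genes, ncol = n, dimnames = list(genes, paste0("B", seq_len(n))))
  informative <- genes[seq_len(n_informative)]
  # each class up-shifts a distinct (cyclic) subset of the planted genes
  for (k in seq_len(n_classes)) {
    idx <- which(((seq_len(n_informative) - 1L) %% n_classes) + 1L == k)
    if (length(idx) == 0L) next
    cols <- labels == classes[k]
    mat[informative[idx], cols] <- mat[informative[idx], cols] +
      effect_size * noise_sd
  }
  list(matrix = mat, labels = labels, informative = informative)
}

#' Synthetic single-cell cohort with sample-level HRD mixing
#'
#' Each sample carries an HRD-fraction parameter theta in \[0, 1\]; its
#' cells are drawn from an HRD-like or HR-proficient-like mean programme
#' with probability theta, converted to counts via per-cell
#' negative-binomial depth, multinomial allocation and Bernoulli dropout.
#' The per-sample mean cell score recovered downstream should track theta —
#' the desk-scale analogue of bulk-vs-single-cell score concordance.
#'
#' @param n_samples Number of samples.
#' @param cells_per_sample Cells per sample.
#' @param n_genes Total genes (the first `n_signature` are the separating
#'   programme).
#' @param n_signature Genes differing between the two programmes.
#' @param effect Log-scale programme separation.
#' @param depth_mean,depth_dispersion Negative-binomial per-cell depth.
#' @param dropout Per-entry zeroing probability.
#' @param seed Integer seed.
#' @return List with `counts` (genes x cells, sparse), `sample_map`,
#'   `cell_truth` (logical HRD per cell), `theta` (per-sample HRD fraction),
#'   `hrd_mean`, `prof_mean` (programme mean vectors).
#' @export
generate_cell_cohort <- function(n_samples = 10L, cells_per_sample = 200L,
                                 n_genes = 60L, n_signature = 20L,
                                 effect = 2, depth_mean = 2000,
                                 depth_dispersion = 5, dropout = 0.2,
                                 seed = 1L) {
  stopifnot(n_signature <= n_genes)
  set.seed(seed)
  genes <- paste0("gene", seq_len(n_genes))
  base <- stats::runif(n_genes, 1, 5)
  hrd_mean <- prof_mean <- base
  up <- seq_len(n_signature %/% 2)
  down <- seq(n_signature %/% 2 + 1L, n_signature)
  hrd_mean[up] <- hrd_mean[up] + effect
  prof_mean[down] <- prof_mean[down] + effect
  theta <- stats::runif(n_samples, 0.05, 0.95)
  n_cells <- n_samples * cells_per_sample
  counts <- matrix(0L, nrow = n_genes, ncol = n_cells,
                   dimnames = list(genes, paste0("cell", seq_len(n_cells))))
  sample_map <- character(n_cells)
  cell_truth <- logical(n_cells)
  j <- 0L
  for (s in seq_len(n_samples)) {
    for (cc in seq_len(cells_per_sample)) {
      j <- j + 1L
      sample_map[j] <- paste0("P", s)
      is_hrd <- stats::runif(1) < theta[s]
      cell_truth[j] <- is_hrd
      mu <- if (is_hrd) hrd_mean else prof_mean
      p <- exp(mu) / sum(exp(mu))
      depth <- max(50L, stats::rnbinom(1, mu = depth_mean,
                                       size = depth_dispersion))
      x <- as.integer(stats::rmultinom(1, depth, p))
      keep <- stats::runif(n_genes) >= dropout
      counts[, j] <- x * keep
    }
  }
  names(sample_map) <- colnames(counts)
  list(counts = Matrix::Matrix(counts, sparse = TRUE),
       sample_map = sample_map, cell_truth = cell_truth,
       theta = stats::setNames(theta, paste0("P", seq_len(n_samples))),
       hrd_mean = stats::setNames(hrd_mean, genes),
       prof_mean = stats::setNames(prof_mean, genes))
}
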