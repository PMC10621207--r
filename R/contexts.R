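#' Classify an SNV into its SBS96 category
#'
#' Substitutions are reported on the pyrimidine strand: when the reference
#' base is a purine (A/G), the substitution and both flanking bases are
#' reverse-complemented before labeling, so a variant and its exact
#' reverse-complement counterpart land in the same category.
#'
#' @param v A one-row variant table (or list) with fields `chrom`, `pos`,
#'   `ref`, `alt`, `variant_class == "SNV"`.
#' @param ref_seq Named character vector of contig sequences.
#' @return An SBS96 category label, e.g. `"A[C>T]A"`.
#' @export
classify_sbs <- function(v, ref_seq) {
  if (v$variant_class != "SNV") stop("not an SNV record", call. = FALSE)
  ctx <- ref_slice(ref_seq, v$chrom, v$pos - 1L, v$pos + 1L)
  mid <- substr(ctx, 2L, 2L)
  if (mid != v$ref) {
    stop("reference mismatch at ", v$chrom, ":", v$pos, " (expected ", v$ref,
         ", reference has ", mid, ")", call. = FALSE)
  }
  base_ref <- v$ref
  base_alt <- v$alt
  if (base_ref %in% c("A", "G")) {
    ctx <- revcomp(ctx)
    base_ref <- complement_base(base_ref)
    base_alt <- complement_base(base_alt)
  }
  paste0(substr(ctx, 1L, 1L), "[", base_ref, ">", base_alt, "]",
         substr(ctx, 3L, 3L))
}

#' Classify an indel into its ID83 category
#'
#' Implements the COSMIC-style decision cascade on VCF-anchored alleles:
#'
#' * 1 bp deletions/insertions are labeled by the event base (A/G collapsed
#'   to T/C by complementation) and the homopolymer context, counted on the
#'   3' side of the (left-aligned) event.
#' * Longer deletions are first tested for a tandem-repeat context (>= 2
#'   copies of the deleted unit, counting the deleted copy plus 3'-adjacent
#'   copies); failing that, for flanking microhomology (longest shared
#'   prefix of the deleted sequence with the 3' flank, or shared suffix with
#'   the 5' flank, whichever is longer); failing both, they fall into the
#'   repeat-count-1 bin.
#' * Longer insertions are binned by the number of pre-existing copies of
#'   the inserted unit in the 3' flank (0 when none).
#'
#' Lengths and counts are capped at the scheme's terminal bins (see
#' [id83_labels()]).
#'
#' @inheritParams classify_sbs
#' @return An ID83 category label, e.g. `"1:Del:T:5"` or `"3:Del:M:2"`.
#' @export
classify_indel <- function(v, ref_seq) {
  if (!v$variant_class %in% c("INS", "DEL")) {
    stop("not an indel record", call. = FALSE)
  }
  if (substr(v$ref, 1L, 1L) != substr(v$alt, 1L, 1L)) {
    stop("indel alleles must be anchored (ref[1] == alt[1])", call. = FALSE)
  }
  if (v$variant_class == "DEL") {
    obs <- ref_slice(ref_seq, v$chrom, v$pos, v$pos + nchar(v$ref) - 1L)
    if (obs != v$ref) {
      stop("reference mismatch at ", v$chrom, ":", v$pos, " (expected ",
           v$ref, ", reference has ", obs, ")", call. = FALSE)
    }
    classify_deletion(v, ref_seq)
  } else {
    classify_insertion(v, ref_seq)
  }
}

# count copies of `unit` in `ref_seq` starting at `start` (1-based), 3'-wards
count_unit_copies <- function(ref_seq, chrom, start, unit) {
  k <- nchar(unit)
  n_contig <- nchar(ref_seq[[chrom]])
  copies <- 0L
  while (start + k - 1L <= n_contig &&
         ref_slice(ref_seq, chrom, start, start + k - 1L) == unit) {
    copies <- copies + 1L
    start <- start + k
  }
  copies
}

classify_deletion <- function(v, ref_seq) {
  del <- substr(v$ref, 2L, nchar(v$ref))
  len <- nchar(del)
  after <- v$pos + nchar(v$ref)      # first reference base 3' of the deletion

  if (len == 1L) {
    run <- 1L + count_unit_copies(ref_seq, v$chrom, after, del)
    base <- if (del %in% c("A", "G")) complement_base(del) else del
    return(paste0("1:Del:", base, ":", min(run, 6L)))
  }

  lbin <- min(len, 5L)
  copies <- 1L + count_unit_copies(ref_seq, v$chrom, after, del)
  if (copies >= 2L) {
    return(paste0(lbin, ":Del:R:", min(copies, 6L)))
  }

  mh <- microhomology_length(v, ref_seq, del)
  if (mh >= 1L) {
    cap <- c(1L, 2L, 3L, 5L)[lbin - 1L]
    return(paste0(lbin, ":Del:M:", min(mh, cap)))
  }
  paste0(lbin, ":Del:R:1")
}

# longest homology between the deleted sequence and its flanks: shared
# prefix with the 3' flank or shared suffix with the 5' flank, max of both,
# bounded below the deletion length
microhomology_length <- function(v, ref_seq, del) {
  len <- nchar(del)
  n_contig <- nchar(ref_seq[[v$chrom]])
  after <- v$pos + nchar(v$ref)

  prefix <- 0L
  while (prefix < len - 1L && after + prefix <= n_contig &&
         ref_slice(ref_seq, v$chrom, after + prefix, after + prefix) ==
           substr(del, prefix + 1L, prefix + 1L)) {
    prefix <- prefix + 1L
  }
  suffix <- 0L
  while (suffix < len - 1L && v$pos - suffix >= 1L &&
         ref_slice(ref_seq, v$chrom, v$pos - suffix, v$pos - suffix) ==
           substr(del, len - suffix, len - suffix)) {
    suffix <- suffix + 1L
  }
  max(prefix, suffix)
}

classify_insertion <- function(v, ref_seq) {
  ins <- substr(v$alt, 2L, nchar(v$alt))
  len <- nchar(ins)
  after <- v$pos + 1L                # first reference base 3' of the insertion

  if (len == 1L) {
    run <- count_unit_copies(ref_seq, v$chrom, after, ins)
    base <- if (ins %in% c("A", "G")) complement_base(ins) else ins
    return(paste0("1:Ins:", base, ":", min(run, 5L)))
  }
  lbin <- min(len, 5L)
  copies <- count_unit_copies(ref_seq, v$chrom, after, ins)
  paste0(lbin, ":Ins:R:", min(copies, 5L))
}

#' Build a per-sample mutation catalog from variants
#'
#' Classifies every SNV and indel record and tallies counts per sample over
#' the 179 canonical categories. `OTHER`-class variants are excluded and
#' counted in the `n_other` attribute; classification failures are collected
#' in the `errors` attribute (or raised immediately with `strict = TRUE`).
#' Row sums therefore equal each sample's number of classifiable variants.
#'
#' @param variants Variant table (see [variant_table()]).
#' @param ref_seq Named character vector of contig sequences.
#' @param samples Optional character vector declaring the catalog rows
#'   (useful to keep mutation-free samples in the output).
#' @param strict Fail on the first classification error instead of
#'   collecting.
#' @return Catalog matrix as from [as_catalog()], with attributes `n_other`
#'   and `errors`.
#' @export
build_catalog <- function(variants, ref_seq, samples = NULL, strict = FALSE) {
  if (is.null(samples)) samples <- unique(variants$sample_id)
  canon <- catalog_categories()
  counts <- matrix(0L, nrow = length(samples), ncol = length(canon),
                   dimnames = list(samples, canon))
  errors <- character(0)
  n_other <- 0L
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    if (!v$sample_id %in% samples) next
    if (v$variant_class == "OTHER") {
      n_other <- n_other + 1L
      next
    }
    lab <- tryCatch(
      if (v$variant_class == "SNV") classify_sbs(v, ref_seq)
      else classify_indel(v, ref_seq),
      error = function(e) {
        if (strict) stop(e)
        errors <<- c(errors, paste0(v$chrom, ":", v$pos, " ", v$ref, ">",
                                    v$alt, ": ", conditionMessage(e)))
        NA_character_
      }
    )
    if (!is.na(lab)) counts[v$sample_id, lab] <- counts[v$sample_id, lab] + 1L
  }
  out <- as_catalog(counts)
  attr(out, "n_other") <- n_other
  attr(out, "errors") <- errors
  out
}
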