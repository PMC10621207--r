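#' Canonical SBS96 trinucleotide-context category labels
#'
#' The 96 single-base-substitution categories follow the COSMIC convention:
#' substitutions are reported on the pyrimidine strand (C or T reference
#' base), giving six substitution types (C>A, C>G, C>T, T>A, T>C, T>G), each
#' combined with the 16 possible 5'/3' flanking-base contexts. Labels take
#' the form `"A[C>T]G"`.
#'
#' Ordering is fixed: substitution types in the order above (outer), then 5'
#' flank A,C,G,T, then 3' flank A,C,G,T (inner).
#'
#' @return Character vector of 96 labels.
#' @export
#' @examples
#' head(sbs96_labels())
sbs96_labels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in subs) {
    for (p5 in bases) {
      for (p3 in bases) {
        out <- c(out, paste0(p5, "[", s, "]", p3))
      }
    }
  }
  out
}

#' Canonical ID83 indel category labels
#'
#' The 83 small insertion/deletion categories follow the COSMIC-style scheme:
#'
#' * 1 bp deletions of C or T (purine events are complemented onto the
#'   pyrimidine channel), binned by the homopolymer tract length containing
#'   the deleted base: 1..5, 6+ (encoded `1:Del:C:1` .. `1:Del:C:6`).
#' * 1 bp insertions of C or T, binned by the length of the adjacent
#'   identical-base run: 0..4, 5+ (`1:Ins:T:0` .. `1:Ins:T:5`).
#' * Deletions of length 2, 3, 4, 5+ at tandem repeats, binned by the number
#'   of copies of the deleted unit present in the reference (including the
#'   deleted copy): 1..5, 6+ (`2:Del:R:1` .. `5:Del:R:6`). The `:1` bin holds
#'   deletions with neither repeat nor microhomology context.
#' * Insertions of length 2, 3, 4, 5+ at repeats, binned by pre-existing unit
#'   copies: 0..4, 5+ (`2:Ins:R:0` .. `5:Ins:R:5`).
#' * Deletions of length 2, 3, 4, 5+ with flanking microhomology, binned by
#'   microhomology length: `2:Del:M:1`, `3:Del:M:1`..`2`, `4:Del:M:1`..`3`,
#'   `5:Del:M:1`..`5`.
#'
#' This totals 12 + 12 + 24 + 24 + 11 = 83 categories.
#'
#' @return Character vector of 83 labels.
#' @export
id83_labels <- function() {
  out <- character(0)
  for (b in c("C", "T")) out <- c(out, paste0("1:Del:", b, ":", 1:6))
  for (b in c("C", "T")) out <- c(out, paste0("1:Ins:", b, ":", 0:5))
  for (l in 2:5) out <- c(out, paste0(l, ":Del:R:", 1:6))
  for (l in 2:5) out <- c(out, paste0(l, ":Ins:R:", 0:5))
  mh_max <- c(`2` = 1, `3` = 2, `4` = 3, `5` = 5)
  for (l in 2:5) out <- c(out, paste0(l, ":Del:M:", seq_len(mh_max[[as.character(l)]])))
  out
}

#' Full canonical catalog category enumeration
#'
#' The 179 mutation categories used throughout the package: the 96 SBS
#' categories first, then the 83 indel categories. Per-sample mutation
#' catalogs, cluster templates and normalization-factor vectors are all
#' ordered this way.
#'
#' @return Character vector of 179 labels.
#' @export
catalog_categories <- function() {
  c(sbs96_labels(), id83_labels())
}

#' Index masks for the two catalog channels
#'
#' @return Logical vector of length 179; `TRUE` marks indel (ID83) positions.
#' @export
indel_channel_mask <- function() {
  c(rep(FALSE, 96), rep(TRUE, 83))
}

# shared constants
N_SBS <- 96L
N_ID <- 83L
N_CAT <- 179L
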