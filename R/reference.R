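#' Load a reference sequence from FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] returning the
#' in-memory representation used by the context classifiers: a named
#' character vector of uppercase contig sequences.
#'
#' @param path Path to a (plain-text) FASTA file.
#' @return Named character vector, one element per contig.
#' @export
read_reference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  # FASTA headers may carry descriptions; contig name is the first token
  names(out) <- vapply(strsplit(names(seqs), "\\s+"), `[[`, character(1), 1)
  out
}

#' Extract reference bases with bounds checking
#'
#' Out-of-contig lookups are errors, never silently empty: context
#' classification at a contig edge must fail loudly.
#'
#' @param ref Named character vector of contig sequences (see
#'   [read_reference()]).
#' @param chrom Contig name.
#' @param start,end 1-based inclusive coordinates.
#' @return The reference substring, uppercase.
#' @export
ref_slice <- function(ref, chrom, start, end) {
  if (!chrom %in% names(ref)) {
    stop("contig '", chrom, "' not present in reference", call. = FALSE)
  }
  n <- nchar(ref[[chrom]])
  if (start < 1 || end > n || start > end) {
    stop(
      "coordinates [", start, ", ", end, "] outside contig '", chrom,
      "' (length ", n, ")",
      call. = FALSE
    )
  }
  substr(ref[[chrom]], start, end)
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(
    strsplit(x, NULL),
    function(ch) paste(rev(ch), collapse = ""),
    character(1)
  ))
}

complement_base <- function(x) chartr("ACGT", "TGCA", x)
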