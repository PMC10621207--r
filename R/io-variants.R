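#' Construct a variant table
#'
#' The package represents somatic variants as a plain data frame with columns
#' `sample_id`, `chrom`, `pos` (1-based, as in VCF), `ref`, `alt` and
#' `variant_class`. Indel alleles are VCF-style anchored (first base of `ref`
#' and `alt` identical). `variant_class` is derived from the alleles:
#' `SNV` (1 bp substitution), `INS`, `DEL`, or `OTHER` (multi-nucleotide
#' substitutions or non-ACGT alleles).
#'
#' @param sample_id,chrom,pos,ref,alt Parallel vectors describing variants.
#' @return A `data.frame` with a `variant_class` column.
#' @export
variant_table <- function(sample_id, chrom, pos, ref, alt) {
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (any(ref == alt)) {
    stop("ref and alt alleles must differ", call. = FALSE)
  }
  data.frame(
    sample_id = as.character(sample_id),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = ref,
    alt = alt,
    variant_class = classify_variant_type(ref, alt),
    stringsAsFactors = FALSE
  )
}

classify_variant_type <- function(ref, alt) {
  acgt <- function(x) grepl("^[ACGT]+$", x)
  cls <- rep("OTHER", length(ref))
  ok <- acgt(ref) & acgt(alt)
  snv <- ok & nchar(ref) == 1L & nchar(alt) == 1L
  ins <- ok & nchar(alt) > nchar(ref) & substr(alt, 1L, 1L) == substr(ref, 1L, 1L) &
    nchar(ref) == 1L
  del <- ok & nchar(ref) > nchar(alt) & substr(alt, 1L, 1L) == substr(ref, 1L, 1L) &
    nchar(alt) == 1L
  cls[snv] <- "SNV"
  cls[ins] <- "INS"
  cls[del] <- "DEL"
  cls
}

#' Read somatic variants from VCF or MAF
#'
#' VCF 4.x files are parsed with \pkg{vcfR}; multi-allelic rows are split
#' into one record per alternate allele. MAF files (GDC dialect) must carry
#' the columns `Chromosome`, `Start_Position`, `Reference_Allele`,
#' `Tumor_Seq_Allele2` and `Tumor_Sample_Barcode`; MAF-style `"-"` indel
#' alleles are re-anchored to VCF-style alleles, which requires `ref_seq`.
#' Records with non-ACGT alleles are retained with class `OTHER` and counted
#' in the `n_other` attribute. Exact duplicate records (same sample and
#' coordinates and alleles) are dropped, with the count in `n_duplicates`.
#'
#' @param path File path.
#' @param format `"vcf"` or `"maf"`.
#' @param sample_id Sample name to assign to VCF records; defaults to the
#'   first genotype column, or the file basename for site-only VCFs.
#' @param ref_seq Named character vector of contig sequences (see
#'   [read_reference()]); required only for MAF files containing `"-"`
#'   alleles.
#' @return Variant table as from [variant_table()], with attributes
#'   `n_other` and `n_duplicates`.
#' @export
read_variants <- function(path, format = c("vcf", "maf"), sample_id = NULL,
                          ref_seq = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  v <- if (format == "vcf") {
    read_variants_vcf(path, sample_id)
  } else {
    read_variants_maf(path, ref_seq)
  }
  if (nrow(v) == 0L) {
    warning("no variant records in ", path, call. = FALSE)
    attr(v, "n_other") <- 0L
    attr(v, "n_duplicates") <- 0L
    return(v)
  }
  key <- do.call(paste, c(v[c("sample_id", "chrom", "pos", "ref", "alt")],
                          sep = "\r"))
  dup <- duplicated(key)
  out <- v[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_other") <- sum(out$variant_class == "OTHER")
  attr(out, "n_duplicates") <- sum(dup)
  if (any(out$variant_class == "OTHER")) {
    warning(sum(out$variant_class == "OTHER"),
            " record(s) with non-SNV/indel alleles kept as OTHER",
            call. = FALSE)
  }
  out
}

read_variants_vcf <- function(path, sample_id) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) {
    return(variant_table(character(0), character(0), integer(0),
                         character(0), character(0))[0, ])
  }
  if (is.null(sample_id)) {
    gt_samples <- colnames(vcf@gt)
    gt_samples <- setdiff(gt_samples, "FORMAT")
    sample_id <- if (length(gt_samples) >= 1L) gt_samples[[1]] else
      sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  alts <- strsplit(as.character(fix[, "ALT"]), ",", fixed = TRUE)
  n_alt <- lengths(alts)
  variant_table(
    sample_id = sample_id,
    chrom = rep(as.character(fix[, "CHROM"]), n_alt),
    pos = rep(as.integer(fix[, "POS"]), n_alt),
    ref = rep(as.character(fix[, "REF"]), n_alt),
    alt = unlist(alts)
  )
}

read_variants_maf <- function(path, ref_seq) {
  maf <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  required <- c("Chromosome", "Start_Position", "Reference_Allele",
                "Tumor_Seq_Allele2", "Tumor_Sample_Barcode")
  missing <- setdiff(required, colnames(maf))
  if (length(missing) > 0L) {
    stop("MAF is missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(maf) == 0L) {
    return(variant_table(character(0), character(0), integer(0),
                         character(0), character(0))[0, ])
  }
  chrom <- as.character(maf$Chromosome)
  pos <- as.integer(maf$Start_Position)
  ref <- toupper(as.character(maf$Reference_Allele))
  alt <- toupper(as.character(maf$Tumor_Seq_Allele2))
  sample <- as.character(maf$Tumor_Sample_Barcode)

  is_del <- alt == "-"
  is_ins <- ref == "-"
  if (any(is_del | is_ins) && is.null(ref_seq)) {
    stop("MAF contains '-' indel alleles; supply ref_seq to re-anchor them",
         call. = FALSE)
  }
  for (i in which(is_del)) {
    # MAF deletion: Start_Position is the first deleted base; anchor on the
    # preceding reference base to recover VCF-style alleles
    anchor <- ref_slice(ref_seq, chrom[i], pos[i] - 1L, pos[i] - 1L)
    ref[i] <- paste0(anchor, ref[i])
    alt[i] <- anchor
    pos[i] <- pos[i] - 1L
  }
  for (i in which(is_ins)) {
    # MAF insertion: Start_Position is the base preceding the inserted bases
    anchor <- ref_slice(ref_seq, chrom[i], pos[i], pos[i])
    alt[i] <- paste0(anchor, alt[i])
    ref[i] <- anchor
  }
  variant_table(sample, chrom, pos, ref, alt)
}
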