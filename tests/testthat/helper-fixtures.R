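# Shared in-code fixtures for the test suite (no binary data on disk).

# two-cluster toy model on the full 179 categories: cluster 1 (HRD-like)
# places extra mass on the indel channel
toy_model <- function(indel_mass = c(0.3, 0.05), floor = 1e-6, seed = 3) {
  generate_cluster_model(
    n_clusters = 2, hrd_clusters = 1, concentration = 0.5,
    indel_mass = indel_mass, n_samples = c(15L, 15L),
    floor = floor, seed = seed
  )
}

# small variant helper: a single-record variant table
one_variant <- function(chrom, pos, ref, alt, sample_id = "S1") {
  variant_table(sample_id, chrom, pos, ref, alt)
}

# total-variation distance between probability vectors
tv_dist <- function(p, q) 0.5 * sum(abs(p - q))

# write a tiny VCF for reader tests
write_test_vcf <- function(lines, path = tempfile(fileext = ".vcf")) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t")
  )
  writeLines(c(header, lines), path)
  path
}
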