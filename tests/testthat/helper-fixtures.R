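# In-code pipeline fixtures: everything is generated programmatically at
# test time from the synthetic-data module; nothing is stored on disk.

# A self-consistent file set for the CLI: proteome FASTA, variants drawn
# from the proteome, pseudo-affinities covering every peptide the profile
# stage can look up, and an allele frequency table.
make_pipeline_fixture <- function(dir, n_variants = 5, seed = 1,
                                  alleles = c("HLA-A*02:01",
                                              "HLA-B*07:02")) {
  pro <- generate_proteome(12, c(60, 90), seed = seed)
  df <- proteome_as_df(pro)
  fasta <- file.path(dir, "proteome.fasta")
  Biostrings::writeXStringSet(pro, fasta)

  set.seed(seed + 1000)
  rows <- lapply(seq_len(n_variants), function(i) {
    pi <- sample(nrow(df), 1)
    pos <- sample(15:45, 1)
    ref <- substr(df$sequence[pi], pos, pos)
    alt <- sample(setdiff(aa_standard(), ref), 1)
    data.frame(gene = df$gene_id[pi], protein_id = df$protein_id[pi],
               protein_position = pos, ref_aa = ref, alt_aa = alt,
               stringsAsFactors = FALSE)
  })
  variants <- file.path(dir, "variants.tsv")
  write_tsv_file(do.call(rbind, rows), variants)

  pairs <- cli_enumerate(variants, file.path(dir, "pairs.tsv"),
                         proteome = fasta, lengths = 9)
  peps <- unique(c(pairs$tumor_peptide, pairs$normal_peptide,
                   build_peptide_db(df, 9)$windows))
  aff <- expand.grid(peptide = peps, allele = alleles,
                     stringsAsFactors = FALSE)
  aff$affinity_nm <- pseudo_affinity(aff$peptide, aff$allele)
  affinities <- file.path(dir, "affinities.tsv")
  write_tsv_file(aff, affinities)

  freqs <- data.frame(
    allele = c(sprintf("HLA-A*%02d:01", 1:4),
               sprintf("HLA-B*%02d:02", 1:4),
               sprintf("HLA-C*%02d:03", 1:4)),
    gene = rep(c("HLA-A", "HLA-B", "HLA-C"), each = 4),
    frequency = rep(0.25, 12))
  allele_freqs <- file.path(dir, "allele_freqs.tsv")
  write_tsv_file(freqs, allele_freqs)

  list(dir = dir, proteome = fasta, proteome_df = df,
       variants = variants, pairs_tsv = file.path(dir, "pairs.tsv"),
       pairs = pairs, affinities = affinities, affinity_table = aff,
       allele_freqs = allele_freqs, alleles = alleles)
}
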