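# Fixture builders shared across the suite.  Everything is generated in
# code under fixed seeds; no data files.

random_genome <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Named character vector of random genomes
random_genomes <- function(lengths, prefix = "genome") {
  out <- vapply(lengths, random_genome, character(1))
  names(out) <- paste0(prefix, seq_along(lengths))
  out
}

write_fasta_fixture <- function(seqs, path = tempfile(fileext = ".fasta")) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  path
}

# FASTQ lines for given sequences and integer phred qualities
fastq_lines <- function(seqs, quals) {
  unlist(lapply(seq_along(seqs), function(i)
    c(paste0("@fixture_", i), seqs[i], "+",
      intToUtf8(quals[[i]] + 33L))))
}

# A profile whose error probabilities sit exactly on integer phred scores,
# so quality encoding in simulated FASTQ is lossless.
phred_exact_profile <- function(name = "qexact", reads_per_run = 1000,
                                length_mean = 100, length_sd = 10,
                                max_length = 150,
                                q_cycle = c(30L, 25L, 20L, 35L)) {
  q <- rep_len(q_cycle, max_length)
  sequencing_profile(name, reads_per_run, length_mean, length_sd,
                     max_length, 10^(-q / 10))
}

# Reconstruct the genomic template addressed by a key record and report
# where it disagrees with the (uppercased) read.
template_for_key <- function(key_row, genomes) {
  g <- genomes[[key_row$genome_id]]
  tmpl <- substr(g, key_row$start + 1L, key_row$end)
  if (key_row$strand == "-") {
    comp <- chartr("ACGTN", "TGCAN", tmpl)
    tmpl <- paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }
  tmpl
}
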