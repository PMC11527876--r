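# Shared fixture builders.

# Convert simulate_gametolog_alignments() output into gametolog_set objects
# without a round trip through FASTA files.
sets_from_sim <- function(aln) {
  lapply(stats::setNames(names(aln$alignments), names(aln$alignments)),
         function(og) {
    seqs <- aln$alignments[[og]]
    parts <- do.call(rbind, strsplit(names(seqs), "|", fixed = TRUE))
    gametolog_set(og, stats::setNames(seqs, paste(parts[, 2], parts[, 3], sep = "|")),
                  gene_id = parts[1, 1])
  })
}

# Minimal per-sex depth table for hand-built metric tests.
depth_rows <- function(scaffold_id, male_depth, female_depth,
                       male_cov = 0.99, female_cov = 0.99) {
  data.frame(scaffold_id = scaffold_id,
             sex = c("male", "female"),
             mean_depth = c(male_depth, female_depth),
             horiz_cov = c(male_cov, female_cov),
             stringsAsFactors = FALSE)
}

kmer_row <- function(scaffold_id, n_kmers = 100L, unmatched = 0L,
                     length_bp = 1e5) {
  data.frame(scaffold_id = scaffold_id, length_bp = length_bp,
             n_kmers = n_kmers, n_kmers_unmatched = unmatched,
             stringsAsFactors = FALSE)
}

fixture_fasta <- function() {
  system.file("extdata", "synthetic_ndufa12_like.fasta",
              package = "neosexscan")
}
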