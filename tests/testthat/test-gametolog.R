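test_that("longest-transcript selection uses ungapped length with id tiebreak", {
  tr <- c(t1 = strrep("A", 300), t2 = strrep("C", 450), t3 = strrep("G", 450))
  expect_equal(names(select_longest_transcript(tr)), "t2")
  expect_equal(names(select_longest_transcript(tr["t1"])), "t1")
  expect_equal(names(select_longest_transcript(
    c(a = strrep("A", 99), b = strrep("T", 300)))), "b")
  # gaps do not count toward length
  expect_equal(names(select_longest_transcript(
    c(a = paste0(strrep("A", 100), strrep("-", 300)), b = strrep("T", 150)))), "b")
  expect_error(select_longest_transcript(character(0)), "empty")
})

test_that("autosomal-to-Z reassignment follows the asymmetric rule", {
  s <- strrep("ACG", 10)
  # A + W, no Z -> A becomes Z
  set1 <- gametolog_set("og1", c("coastal|A" = s, "coastal|W" = s))
  out1 <- reassign_autosomal_gametologs(set1)
  expect_setequal(names(out1$seqs), c("coastal|Z", "coastal|W"))
  expect_equal(out1$reassigned, "coastal|Z")
  # A + Z, no W -> unchanged (missing W treated as not sequenced)
  set2 <- gametolog_set("og2", c("coastal|A" = s, "coastal|Z" = s))
  out2 <- reassign_autosomal_gametologs(set2)
  expect_identical(out2$seqs, set2$seqs)
  expect_length(out2$reassigned, 0)
  # A alone -> unchanged
  set3 <- gametolog_set("og3", c("coastal|A" = s))
  expect_identical(reassign_autosomal_gametologs(set3)$seqs, set3$seqs)
})

test_that("reassignment is idempotent and lineage-local", {
  s <- strrep("ACG", 10)
  set <- gametolog_set("og", c("coastal|A" = s, "coastal|W" = s,
                               "inland|A" = s, "inland|Z" = s,
                               "outgroup|A" = s))
  once <- reassign_autosomal_gametologs(set)
  twice <- reassign_autosomal_gametologs(once)
  expect_identical(once$seqs, twice$seqs)
  expect_true("coastal|Z" %in% names(once$seqs))
  expect_true("inland|A" %in% names(once$seqs)) # inland untouched
})

test_that("function labels default to non-N-mt with conflict detection", {
  genes <- data.frame(gene_id = c("NDUFA12", "OTHER"), stringsAsFactors = FALSE)
  tab <- data.frame(gene_id = "NDUFA12", is_nmt = 1L)
  expect_warning(out <- label_function(genes, tab), "absent")
  expect_identical(out$is_nmt, c(TRUE, FALSE))

  empty <- data.frame(gene_id = character(0), is_nmt = integer(0))
  expect_warning(all_false <- label_function(genes, empty), "absent")
  expect_false(any(all_false$is_nmt))

  dup_ok <- data.frame(gene_id = c("NDUFA12", "NDUFA12", "OTHER"), is_nmt = c(1L, 1L, 0L))
  expect_silent(label_function(genes, dup_ok))
  dup_bad <- data.frame(gene_id = c("NDUFA12", "NDUFA12"), is_nmt = c(1L, 0L))
  expect_error(label_function(genes, dup_bad), "conflicting")
})

test_that("site-level gap deletion removes columns gapped in either sequence", {
  expect_equal(delete_gap_sites("AC-G", "A-TG"), c("AG", "AG"))
  expect_equal(delete_gap_sites("ACGT", "ACGT"), c("ACGT", "ACGT"))
  expect_equal(delete_gap_sites("----", "ACGT"), c("", ""))
  expect_equal(delete_gap_sites("ANGT", "ACGT"), c("AGT", "AGT")) # N as gap
  expect_error(delete_gap_sites("ACG", "ACGT"), "lengths differ")
})

test_that("codon trimming drops codons gapped in any focal gametolog only", {
  base <- strrep("ATGGCC", 5) # 10 codons
  gapped <- paste0(substr(base, 1, 12), "---", substr(base, 16, 30))
  set <- gametolog_set("og", c("coastal|Z" = base, "coastal|W" = gapped,
                               "inland|Z" = base, "outgroup|A" = base))
  out <- trim_codon_gaps(set)
  lens <- nchar(out$seqs)
  expect_true(all(lens == 27))
  expect_equal(out$seqs[["coastal|Z"]],
               paste0(substr(base, 1, 12), substr(base, 16, 30)))

  # outgroup-only gaps do not trigger trimming
  set2 <- gametolog_set("og2", c("coastal|Z" = base,
                                 "outgroup|A" = gapped))
  expect_identical(trim_codon_gaps(set2)$seqs, set2$seqs)

  # identity with no gaps
  expect_identical(trim_codon_gaps(set)$seqs, trim_codon_gaps(trim_codon_gaps(set))$seqs)

  bad <- gametolog_set("og3", c("coastal|Z" = "ACGT", "coastal|W" = "ACGT"))
  expect_error(trim_codon_gaps(bad), "multiple of 3")
})

test_that("gap operations never alter retained characters", {
  set.seed(4)
  for (i in 1:20) {
    a <- random_dna(60)
    b <- random_dna(60)
    idx <- sample(60, 8)
    av <- unlist(strsplit(a, "")); av[idx[1:4]] <- "-"
    bv <- unlist(strsplit(b, "")); bv[idx[5:8]] <- "-"
    pair <- delete_gap_sites(paste(av, collapse = ""), paste(bv, collapse = ""))
    # retained characters are a subsequence of the originals
    expect_true(grepl(paste(unlist(strsplit(pair[1], "")), collapse = ".*"), a))
    expect_true(grepl(paste(unlist(strsplit(pair[2], "")), collapse = ".*"), b))
  }
})

test_that("trimming recovers exactly the simulated deletion span", {
  del <- data.frame(gene_id = "g0001", lineage = "inland", linkage = "W",
                    start_codon = 21, length_codons = 10)
  cfg <- sim_config(seed = 12, n_genes = 1, gene_length_codons = 60,
                    deletion_spec = del)
  aln <- simulate_gametolog_alignments(cfg)
  set <- sets_from_sim(aln)[[1]]
  out <- trim_codon_gaps(set)
  expect_true(all(nchar(out$seqs) == (60 - 10) * 3))
  # untouched sequences lose exactly the deleted codon block
  full <- set$seqs[["coastal|Z"]]
  expect_equal(out$seqs[["coastal|Z"]],
               paste0(substr(full, 1, 60), substr(full, 91, 180)))
})
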