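test_that("K80 distance matches direct counting and the closed form", {
  expect_equal(k80_distance("ACGT", "ACGT")$dxy, 0)

  # n = 100 with 2 transitions and 1 transversion
  a <- strrep("ACGT", 25)
  av <- unlist(strsplit(a, ""))
  bv <- av
  bv[1] <- "G"  # A->G transition
  bv[2] <- "T"  # C->T transition
  bv[3] <- "C"  # G->C transversion
  d <- k80_distance(a, paste(bv, collapse = ""))
  expect_equal(d$P, 0.02)
  expect_equal(d$Q, 0.01)
  expect_equal(d$dxy, -0.5 * log(0.95) - 0.25 * log(0.98))

  # symmetry
  set.seed(1)
  x <- random_dna(300)
  xv <- unlist(strsplit(x, ""))
  idx <- sample(300, 30)
  xv[idx] <- sample(c("A", "C", "G", "T"), 30, replace = TRUE)
  y <- paste(xv, collapse = "")
  expect_equal(k80_distance(x, y)$dxy, k80_distance(y, x)$dxy)
})

test_that("K80 agrees with an independent oracle and with ape on random pairs", {
  skip_if_not_installed("ape")
  set.seed(2)
  for (i in 1:50) {
    a <- random_dna(240)
    av <- unlist(strsplit(a, ""))
    bv <- av
    nmut <- sample(1:30, 1)
    idx <- sample(240, nmut)
    bv[idx] <- sample(c("A", "C", "G", "T"), nmut, replace = TRUE)
    b <- paste(bv, collapse = "")
    mine <- k80_distance(a, b)$dxy
    expect_equal(mine, oracle_k80(a, b), tolerance = 1e-12)
    mat <- rbind(strsplit(tolower(a), "")[[1]], strsplit(tolower(b), "")[[1]])
    ref <- as.numeric(ape::dist.dna(ape::as.DNAbin(mat), model = "K80"))
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("K80 estimates are consistent under simulation at known distance", {
  # pairs diverged by d = 0.05 built from exact K80 substitution
  # probabilities (alpha*t = 0.03 transitions, beta*t = 0.01 per
  # transversion target): P and Q from the K80 transition functions
  at <- 0.03; bt <- 0.01
  Pexp <- 0.25 - 0.5 * exp(-2 * (at + bt)) + 0.25 * exp(-4 * bt)
  Qexp <- 0.5 - 0.5 * exp(-4 * bt)
  set.seed(11)
  ds <- replicate(20, {
    n <- 100000
    av <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    bv <- av
    u <- runif(n)
    ts_idx <- u < Pexp
    tv_idx <- u >= Pexp & u < Pexp + Qexp
    trs <- c(A = "G", G = "A", C = "T", T = "C")
    tvs <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))
    bv[ts_idx] <- trs[av[ts_idx]]
    bv[tv_idx] <- vapply(av[tv_idx], function(x) sample(tvs[[x]], 1), "")
    k80_distance(paste(av, collapse = ""), paste(bv, collapse = ""))$dxy
  })
  se <- sd(ds) / sqrt(length(ds))
  expect_lt(abs(mean(ds) - 0.05), 3 * se)
})

test_that("saturated or empty alignments give undefined distances with warnings", {
  expect_warning(d <- k80_distance("", ""), "no overlapping")
  expect_true(is.na(d$dxy))
  a <- strrep("A", 40)
  b <- strrep("C", 40) # all transversions, Q = 1
  expect_warning(d2 <- k80_distance(a, b), "saturation")
  expect_true(is.na(d2$dxy))
})

test_that("Dxy table applies the availability rule and is order invariant", {
  s <- strrep("ATGGCC", 20)
  set1 <- gametolog_set("og1", c("coastal|W" = s, "inland|W" = s,
                                 "coastal|Z" = s))
  set2 <- gametolog_set("og2", c("coastal|Z" = s, "inland|Z" = s,
                                 "coastal|W" = s, "inland|W" = s))
  tab <- dxy_table(list(set1, set2))
  expect_equal(tab$linkage[tab$og_id == "og1"], "W")
  expect_setequal(tab$linkage[tab$og_id == "og2"], c("Z", "W"))
  tab2 <- dxy_table(list(set2, set1))
  key <- function(t) t[order(t$og_id, t$linkage), c("og_id", "linkage", "dxy")]
  expect_equal(key(tab), key(tab2), ignore_attr = TRUE)
})

test_that("boosted W divergence of N-mt genes exceeds non-N-mt W divergence", {
  cfg <- sim_config(seed = 61, n_genes = 200, gene_length_codons = 150,
                    nmt_fraction = 0.5, w_nmt_boost = 4)
  aln <- simulate_gametolog_alignments(cfg)
  dx <- dxy_table(sets_from_sim(aln))
  nmt <- aln$truth$gene_function[dx$gene_id]
  w <- dx$linkage == "W" & !is.na(dx$dxy)
  test <- wilcox.test(dx$dxy[w & nmt], dx$dxy[w & !nmt], alternative = "greater")
  expect_lt(test$p.value, 0.01)
})

test_that("delta-Dxy outliers are flagged against the pooled distribution", {
  mk <- function(og, dz, dw) {
    rbind(data.frame(og_id = og, gene_id = og, linkage = "Z", dxy = dz,
                     n_sites = 300L, P = 0, Q = 0),
          data.frame(og_id = og, gene_id = og, linkage = "W", dxy = dw,
                     n_sites = 300L, P = 0, Q = 0))
  }
  # degenerate: all deltas equal
  same <- do.call(rbind, lapply(1:5, function(i) mk(paste0("og", i), 0.001, 0.003)))
  expect_error(delta_dxy_outliers(same), "equal")

  # one extreme among 100
  set.seed(5)
  base <- do.call(rbind, lapply(1:99, function(i)
    mk(sprintf("og%03d", i), 0.001, 0.001 + rnorm(1, 0.002, 5e-4))))
  hot <- mk("og100", 0.001, 0.02)
  out <- delta_dxy_outliers(rbind(base, hot))
  expect_true(out$is_outlier[out$og_id == "og100"])

  # 4 boosted genes among 68: exactly the boosted four flagged
  set.seed(6)
  quiet <- do.call(rbind, lapply(1:64, function(i)
    mk(sprintf("q%02d", i), 0.001, 0.001 + rnorm(1, 0.002, 4e-4))))
  boosted <- do.call(rbind, lapply(1:4, function(i)
    mk(sprintf("b%02d", i), 0.001, 0.018 + rnorm(1, 0, 1e-3))))
  out2 <- delta_dxy_outliers(rbind(quiet, boosted))
  expect_setequal(out2$og_id[out2$is_outlier], sprintf("b%02d", 1:4))
})

test_that("NG86 counts match enumeration on elementary codon pairs", {
  # identical sequences
  e0 <- ng86_dnds("TTTGGG", "TTTGGG")
  expect_equal(e0$dn, 0)
  expect_equal(e0$ds, 0)
  expect_true(is.na(e0$dnds))
  # TTT -> TTA: Phe -> Leu, one nonsynonymous difference
  e1 <- ng86_dnds("TTT", "TTA")
  expect_equal(e1$n_diff, 1)
  expect_equal(e1$s_diff, 0)
  # internal stop is reported with its codon index
  expect_error(ng86_dnds("TTTTAAGGG", "TTTTTAGGG"), "stop codon TAA at codon 2")
})

test_that("NG86 agrees with the exhaustive pathway oracle on random codon pairs", {
  tabs <- getFromNamespace("codon_tables", "neosexscan")()
  set.seed(9)
  for (i in 1:200) {
    c1 <- sample(tabs$codons, 1)
    c2 <- sample(tabs$codons, 1)
    # only the counts are under test; the JC correction is legitimately
    # undefined for many single-codon pairs
    est <- suppressWarnings(ng86_dnds(c1, c2))
    od <- oracle_ng86_diffs(c1, c2)
    s1 <- oracle_ng86_sites(c1); s2 <- oracle_ng86_sites(c2)
    expect_equal(est$s_diff, unname(od["sd"]), tolerance = 1e-12)
    expect_equal(est$n_diff, unname(od["nd"]), tolerance = 1e-12)
    expect_equal(est$s_sites, unname((s1["s"] + s2["s"]) / 2), tolerance = 1e-12)
    expect_equal(est$n_sites, unname((s1["n"] + s2["n"]) / 2), tolerance = 1e-12)
  }
})

test_that("dN/dS contrast applies the sign convention and the ceiling rule", {
  mk <- function(og, lineage, dnds) {
    data.frame(og_id = og, gene_id = og, lineage = lineage, linkage = "W",
               outgroup_id = "outgroup|A", dn = dnds * 0.1, ds = 0.1,
               dnds = dnds, n_codons = 100L, s_sites = 70, n_sites = 200,
               s_diff = 1, n_diff = 1, stringsAsFactors = FALSE)
  }
  set.seed(8)
  vals_c <- c(2, runif(199, 0.1, 0.3))
  vals_i <- c(0.2, runif(199, 0.1, 0.3))
  tab <- do.call(rbind, c(
    lapply(1:200, function(i) mk(sprintf("og%03d", i), "coastal", vals_c[i])),
    lapply(1:200, function(i) mk(sprintf("og%03d", i), "inland", vals_i[i]))))
  out <- dnds_contrast(tab)
  expect_equal(nrow(out), 200)
  expect_equal(sum(out$is_outlier), 2) # ceiling(0.01 * 200)
  expect_true(out$is_outlier[out$og_id == "og001"])
  expect_gt(out$dnds_ci[out$og_id == "og001"], 0) # coastal-elevated -> positive

  # equal estimates give zero contrasts that are never flagged
  eq <- rbind(mk("ogx", "coastal", 0.5), mk("ogx", "inland", 0.5))
  oeq <- dnds_contrast(eq)
  expect_equal(oeq$dnds_ci, 0)
  expect_false(any(oeq$is_outlier))
})

test_that("bootstrap screen is deterministic and undefined for identical pairs", {
  set.seed(10)
  root <- random_codon_sequence(200)
  desc <- evolve_codon_sequence(root, 0.3, kappa = 2, omega = 3)
  a <- bootstrap_selection_screen(desc, root, n_boot = 200, seed = 42)
  b <- bootstrap_selection_screen(desc, root, n_boot = 200, seed = 42)
  expect_identical(a, b)
  expect_true(a$p_value >= 0 && a$p_value <= 1)

  same <- bootstrap_selection_screen(root, root, n_boot = 200, seed = 1)
  expect_true(is.na(same$p_value))
  expect_error(bootstrap_selection_screen(desc, root, n_boot = 50), "n_boot")
})

test_that("bootstrap screen has power against strong positive selection", {
  set.seed(12)
  ps <- replicate(20, {
    root <- random_codon_sequence(500)
    desc <- evolve_codon_sequence(root, 0.3, kappa = 1, omega = 5)
    bootstrap_selection_screen(desc, root, n_boot = 200, seed = 1)$p_value
  })
  expect_gt(mean(ps < 0.05), 0.5)
})

test_that("gap spans report maximal runs with alignment fractions", {
  aln <- c("seq1" = strrep("ATG", 20),
           "seq2" = paste0(strrep("ATG", 5), strrep("-", 9),
                           strrep("ATG", 10), strrep("-", 6)))
  spans <- detect_gap_spans(aln, min_len_codons = 1)
  s2 <- spans[spans$sequence_id == "seq2", ]
  expect_equal(nrow(s2), 2)
  expect_equal(s2$start_codon, c(5L, 18L))
  expect_equal(s2$length_codons, c(3L, 2L))
  expect_equal(s2$fraction_of_alignment, c(9, 6) / 60)
  expect_equal(nrow(detect_gap_spans(aln, min_len_codons = 4)), 0)
  expect_equal(nrow(detect_gap_spans(c(a = "ATGATG"))), 0)
  expect_error(detect_gap_spans(c(a = "ATGA")), "multiple of 3")
})

test_that("local exon alignment finds exact substrings on both strands", {
  set.seed(14)
  scaffold <- random_dna(2000)
  exon <- substr(scaffold, 101, 373) # 0-based [100, 373)
  hit <- local_align_exon(exon, scaffold, query_id = "exon4")
  expect_equal(hit$target_start, 100)
  expect_equal(hit$target_end, 373)
  expect_equal(hit$identity, 1.0)
  expect_equal(hit$strand, "+")

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(exon)))
  hit_rc <- local_align_exon(rc, scaffold, query_id = "exon4rc")
  expect_equal(hit_rc$target_start, 100)
  expect_equal(hit_rc$target_end, 373)
  expect_equal(hit_rc$strand, "-")

  expect_null(local_align_exon(exon, ""))
  expect_error(local_align_exon("ACGT", scaffold), "at least 20")
})

test_that("random queries rarely reach the reporting threshold", {
  set.seed(15)
  hits <- 0L
  for (i in 1:100) {
    q <- random_dna(60)
    s <- random_dna(10000)
    if (!is.null(local_align_exon(q, s))) hits <- hits + 1L
  }
  expect_lte(hits, 5L)
})
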