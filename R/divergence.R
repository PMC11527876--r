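# Between-lineage divergence statistics: K80 pairwise distances (Dxy),
# delta-Dxy outlier screening, Nei-Gojobori (1986) dN/dS with between-lineage
# contrasts, a codon-bootstrap positive-selection screen, and exon-loss
# forensics (gap-span detection and local re-alignment of missing exons).

#' Kimura two-parameter (K80) distance
#'
#' Counts transition (P) and transversion (Q) proportions over the aligned
#' sites and evaluates the K80 closed form
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`. No correction for
#' among-site rate variation is applied. The distance is undefined
#' (returned as `NA` with a warning) when `1 - 2P - Q <= 0`, `1 - 2Q <= 0`,
#' or no sites overlap.
#'
#' @param a,b Equal-length, gap-free nucleotide sequences (see
#'   [delete_gap_sites()]).
#' @return One-row data frame with `dxy`, `n_sites`, `P`, `Q`.
#' @export
k80_distance <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  if (length(ca) != length(cb))
    stop("sequences differ in length: ", length(ca), " vs ", length(cb))
  ok <- ca %in% .NTS & cb %in% .NTS
  ca <- ca[ok]; cb <- cb[ok]
  n <- length(ca)
  if (n == 0) {
    warning("K80 distance undefined: no overlapping ungapped sites")
    return(data.frame(dxy = NA_real_, n_sites = 0L, P = NA_real_, Q = NA_real_))
  }
  diff <- ca != cb
  ts <- diff & .TS_PARTNER[ca] == cb
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    warning("K80 distance undefined: saturation (1-2P-Q or 1-2Q <= 0)")
    return(data.frame(dxy = NA_real_, n_sites = n, P = P, Q = Q))
  }
  data.frame(dxy = -0.5 * log(w1) - 0.25 * log(w2), n_sites = n, P = P, Q = Q)
}

#' Between-lineage Dxy per gametolog
#'
#' For each orthogroup and each sex linkage (Z, W) represented in both the
#' coastal and inland lineage, deletes gapped sites pairwise and computes the
#' K80 distance between the two lineages' gametologs. W is never compared
#' with Z directly.
#'
#' @param sets List of [gametolog_set()]s (after
#'   [reassign_autosomal_gametologs()]).
#' @return Data frame with `og_id`, `gene_id`, `linkage`, `dxy`, `n_sites`,
#'   `P`, `Q`. Orthogroup/linkage combinations missing one lineage are
#'   skipped.
#' @export
dxy_table <- function(sets) {
  rows <- list()
  for (set in sets) {
    for (lk in c("Z", "W")) {
      ca <- paste("coastal", lk, sep = "|")
      ia <- paste("inland", lk, sep = "|")
      if (!(ca %in% names(set$seqs)) || !(ia %in% names(set$seqs))) next
      pair <- delete_gap_sites(set$seqs[[ca]], set$seqs[[ia]])
      if (nchar(pair[1]) == 0) {
        warning("orthogroup ", set$og_id, " ", lk,
                ": no ungapped sites; Dxy undefined")
        next
      }
      d <- k80_distance(pair[1], pair[2])
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(og_id = set$og_id, gene_id = set$gene_id, linkage = lk,
                   stringsAsFactors = FALSE), d)
    }
  }
  if (!length(rows)) {
    return(data.frame(og_id = character(), gene_id = character(),
                      linkage = character(), dxy = numeric(),
                      n_sites = integer(), P = numeric(), Q = numeric()))
  }
  do.call(rbind, rows)
}

#' Delta-Dxy outliers between W and Z gametologs
#'
#' For every orthogroup with defined Dxy for both the W and Z gametolog,
#' computes `delta_dxy = dxy_W - dxy_Z`, standardizes against the pooled
#' delta-Dxy distribution, and flags Z-score outliers.
#'
#' @param dxy Data frame from [dxy_table()] (an optional `is_nmt` column is
#'   carried through).
#' @param zscore_cut Outlier threshold on |Z-score| (default 1.96).
#' @return Data frame with `og_id`, `gene_id`, `delta_dxy`, `zscore`,
#'   `is_outlier` (and `is_nmt` when available).
#' @export
delta_dxy_outliers <- function(dxy, zscore_cut = 1.96) {
  w <- dxy[dxy$linkage == "W" & !is.na(dxy$dxy), ]
  z <- dxy[dxy$linkage == "Z" & !is.na(dxy$dxy), ]
  common <- intersect(w$og_id, z$og_id)
  if (length(common) < 3)
    stop("need >= 3 orthogroups with both W and Z Dxy (have ",
         length(common), ")")
  w <- w[match(common, w$og_id), ]
  z <- z[match(common, z$og_id), ]
  delta <- w$dxy - z$dxy
  s <- stats::sd(delta)
  if (s == 0) stop("all delta-Dxy values equal: Z-scores undefined")
  zsc <- (delta - mean(delta)) / s
  out <- data.frame(og_id = common, gene_id = w$gene_id, delta_dxy = delta,
                    zscore = zsc, is_outlier = abs(zsc) > zscore_cut,
                    stringsAsFactors = FALSE)
  if ("is_nmt" %in% names(w)) out$is_nmt <- w$is_nmt
  out
}

# Remove codon columns where either sequence has a gap or ambiguity, keeping
# the reading frame.
.delete_gap_codons <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("aligned lengths differ: ", nchar(a), " vs ", nchar(b))
  if (nchar(a) %% 3 != 0)
    stop("aligned length ", nchar(a), " is not a multiple of 3")
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  bad <- !(ca %in% .NTS) | !(cb %in% .NTS)
  drop <- colSums(matrix(bad, nrow = 3)) > 0
  keep <- rep(!drop, each = 3)
  c(paste(ca[keep], collapse = ""), paste(cb[keep], collapse = ""))
}

# Per-codon NG86 components between two codon index vectors: synonymous /
# nonsynonymous site counts (averaged over the two sequences) and
# pathway-averaged difference counts.
.ng86_components <- function(xa, xb) {
  tab <- codon_tables()
  cbind(
    s_sites = (tab$syn_sites[xa] + tab$syn_sites[xb]) / 2,
    n_sites = (tab$nonsyn_sites[xa] + tab$nonsyn_sites[xb]) / 2,
    s_diff = tab$SD[cbind(xa, xb)],
    n_diff = tab$ND[cbind(xa, xb)]
  )
}

.jc_correct <- function(p) {
  ifelse(p >= 0.75, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

.codon_indices_checked <- function(seq, what) {
  tab <- codon_tables()
  x <- .codon_indices(seq)
  if (anyNA(x)) {
    nc <- nchar(seq)
    cods <- substring(toupper(seq), seq(1, nc, 3), seq(3, nc, 3))
    bad <- which(is.na(x))[1]
    if (cods[bad] %in% tab$stops)
      stop(what, ": internal stop codon ", cods[bad], " at codon ", bad)
    stop(what, ": non-ACGT codon '", cods[bad], "' at codon ", bad)
  }
  x
}

#' Nei-Gojobori (1986) dN/dS
#'
#' Pathway-counting estimate of synonymous and nonsynonymous substitution
#' rates between a focal sequence and an outgroup. Synonymous and
#' nonsynonymous site counts are averaged over the three positions of each
#' codon (and over the two sequences); differences between codon pairs are
#' averaged over all orderings of the position changes with equal weight,
#' excluding pathways through stop codons. Changes to stop codons count
#' toward neither site class. Proportions are distance-corrected with the
#' Jukes-Cantor formula `d = -3/4 log(1 - 4p/3)`.
#'
#' @param seq,outgroup_seq Gap-free, in-frame, equal-length coding sequences
#'   without internal stop codons.
#' @return One-row data frame with `dn`, `ds`, `dnds` (`NA` when `ds` is 0 or
#'   a correction is undefined), `n_codons`, `s_sites`, `n_sites`, `s_diff`,
#'   `n_diff`.
#' @export
ng86_dnds <- function(seq, outgroup_seq) {
  if (nchar(seq) != nchar(outgroup_seq))
    stop("sequences differ in length: ", nchar(seq), " vs ", nchar(outgroup_seq))
  xa <- .codon_indices_checked(seq, "seq")
  xb <- .codon_indices_checked(outgroup_seq, "outgroup_seq")
  comp <- .ng86_components(xa, xb)
  tot <- colSums(comp)
  S <- tot[["s_sites"]]; N <- tot[["n_sites"]]
  Sd <- tot[["s_diff"]]; Nd <- tot[["n_diff"]]
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  ds <- .jc_correct(pS)
  dn <- .jc_correct(pN)
  if ((!is.na(pS) && pS >= 0.75) || (!is.na(pN) && pN >= 0.75))
    warning("NG86 estimate undefined: proportion of differences >= 3/4")
  dnds <- if (!is.na(ds) && !is.na(dn) && ds > 0) dn / ds else NA_real_
  data.frame(dn = dn, ds = ds, dnds = dnds, n_codons = length(xa),
             s_sites = S, n_sites = N, s_diff = Sd, n_diff = Nd)
}

#' Per-gametolog dN/dS against the outgroup
#'
#' For each orthogroup, trims codon columns gapped in any focal-lineage
#' gametolog ([trim_codon_gaps()]), then estimates NG86 dN/dS for each
#' available Z/W gametolog of each lineage relative to the orthogroup's
#' outgroup sequence (codon columns gapped in the outgroup are dropped
#' pairwise).
#'
#' @param sets List of [gametolog_set()]s (after
#'   [reassign_autosomal_gametologs()]).
#' @return Data frame with `og_id`, `gene_id`, `lineage`, `linkage`,
#'   `outgroup_id`, and the [ng86_dnds()] columns.
#' @export
dnds_table <- function(sets) {
  rows <- list()
  for (set in sets) {
    og_slot <- grep("^outgroup\\|", names(set$seqs), value = TRUE)
    if (!length(og_slot)) {
      warning("orthogroup ", set$og_id, ": no outgroup sequence; skipped")
      next
    }
    og_slot <- og_slot[1]
    trimmed <- trim_codon_gaps(set)
    for (lin in c("coastal", "inland")) {
      for (lk in c("Z", "W")) {
        slot <- paste(lin, lk, sep = "|")
        if (!(slot %in% names(trimmed$seqs))) next
        pair <- .delete_gap_codons(trimmed$seqs[[slot]], trimmed$seqs[[og_slot]])
        if (nchar(pair[1]) == 0) {
          warning("orthogroup ", set$og_id, " ", slot,
                  ": no ungapped codons against outgroup; skipped")
          next
        }
        est <- ng86_dnds(pair[1], pair[2])
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(og_id = set$og_id, gene_id = set$gene_id, lineage = lin,
                     linkage = lk, outgroup_id = og_slot,
                     stringsAsFactors = FALSE), est)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(og_id = character(), gene_id = character(),
                      lineage = character(), linkage = character(),
                      outgroup_id = character(), dn = numeric(),
                      ds = numeric(), dnds = numeric(), n_codons = integer(),
                      s_sites = numeric(), n_sites = numeric(),
                      s_diff = numeric(), n_diff = numeric()))
  }
  do.call(rbind, rows)
}

#' Between-lineage dN/dS contrast with extreme-value flags
#'
#' Computes, per orthogroup and linkage, the coastal-minus-inland difference
#' in dN/dS (positive values mean faster protein evolution in the coastal
#' lineage) and flags the most extreme fraction by absolute value
#' (`ceiling(outlier_quantile * n)`, at least 1 when any pair exists).
#'
#' @param dnds Data frame from [dnds_table()].
#' @param outlier_quantile Fraction flagged (default 0.01).
#' @return Data frame with `og_id`, `gene_id`, `linkage`, `dnds_coastal`,
#'   `dnds_inland`, `dnds_ci`, `is_outlier`. Pairs with an undefined estimate
#'   on either side are skipped.
#' @export
dnds_contrast <- function(dnds, outlier_quantile = 0.01) {
  co <- dnds[dnds$lineage == "coastal" & !is.na(dnds$dnds), ]
  inl <- dnds[dnds$lineage == "inland" & !is.na(dnds$dnds), ]
  key_c <- paste(co$og_id, co$linkage)
  key_i <- paste(inl$og_id, inl$linkage)
  common <- intersect(key_c, key_i)
  if (!length(common)) {
    return(data.frame(og_id = character(), gene_id = character(),
                      linkage = character(), dnds_coastal = numeric(),
                      dnds_inland = numeric(), dnds_ci = numeric(),
                      is_outlier = logical()))
  }
  co <- co[match(common, key_c), ]
  inl <- inl[match(common, key_i), ]
  val <- co$dnds - inl$dnds
  n <- length(val)
  k <- max(1L, ceiling(outlier_quantile * n))
  flagged <- rep(FALSE, n)
  # a zero contrast is never an outlier, even under the minimum-one rule
  cand <- order(-abs(val))[seq_len(k)]
  flagged[cand[abs(val[cand]) > 0]] <- TRUE
  data.frame(og_id = co$og_id, gene_id = co$gene_id, linkage = co$linkage,
             dnds_coastal = co$dnds, dnds_inland = inl$dnds, dnds_ci = val,
             is_outlier = flagged, stringsAsFactors = FALSE)
}

#' Codon-bootstrap screen for dN > dS
#'
#' Resamples codon columns with replacement `n_boot` times and recomputes the
#' NG86 dN and dS on each replicate; the one-sided p-value is the fraction of
#' replicates with `dN <= dS`. Small p-values indicate consistent excess of
#' nonsynonymous over synonymous divergence. Replicates whose Jukes-Cantor
#' correction is undefined are dropped; if more than half are undefined, or
#' the observed pair has no differences at all, the p-value is `NA`.
#'
#' @param seq,outgroup_seq As in [ng86_dnds()].
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed Integer seed making the resampling deterministic.
#' @return One-row data frame with `p_value`, `n_boot`, `n_defined`, `dn`,
#'   `ds` (point estimates).
#' @export
bootstrap_selection_screen <- function(seq, outgroup_seq, n_boot = 1000L,
                                       seed = 1L) {
  if (n_boot < 100) stop("n_boot must be >= 100")
  xa <- .codon_indices_checked(seq, "seq")
  xb <- .codon_indices_checked(outgroup_seq, "outgroup_seq")
  comp <- .ng86_components(xa, xb)
  est <- ng86_dnds(seq, outgroup_seq)
  nc <- length(xa)
  if (sum(comp[, "s_diff"]) + sum(comp[, "n_diff"]) == 0) {
    return(data.frame(p_value = NA_real_, n_boot = as.integer(n_boot),
                      n_defined = 0L, dn = est$dn, ds = est$ds))
  }
  set.seed(as.integer(seed))
  idx <- matrix(sample.int(nc, nc * n_boot, replace = TRUE), nrow = nc)
  S <- colSums(matrix(comp[idx, "s_sites"], nrow = nc))
  N <- colSums(matrix(comp[idx, "n_sites"], nrow = nc))
  Sd <- colSums(matrix(comp[idx, "s_diff"], nrow = nc))
  Nd <- colSums(matrix(comp[idx, "n_diff"], nrow = nc))
  ds <- .jc_correct(ifelse(S > 0, Sd / S, NA_real_))
  dn <- .jc_correct(ifelse(N > 0, Nd / N, NA_real_))
  defined <- !is.na(ds) & !is.na(dn)
  if (mean(!defined) > 0.5) {
    warning("dS or dN undefined in > 50% of bootstrap replicates; p undefined")
    return(data.frame(p_value = NA_real_, n_boot = as.integer(n_boot),
                      n_defined = sum(defined), dn = est$dn, ds = est$ds))
  }
  data.frame(p_value = mean(dn[defined] <= ds[defined]),
             n_boot = as.integer(n_boot), n_defined = sum(defined),
             dn = est$dn, ds = est$ds)
}

#' Detect codon-level gap spans
#'
#' Finds, per sequence of an aligned orthogroup, maximal runs of all-gap
#' codons of at least `min_len_codons`, reporting the 0-based start codon,
#' the run length in codons, and the fraction of the aligned length the run
#' covers. Used as exon-loss forensics: a large gap span confined to one
#' gametolog indicates loss of the corresponding exon.
#'
#' @param seqs Named character vector of aligned sequences (or a
#'   [gametolog_set()]), aligned length divisible by 3.
#' @param min_len_codons Minimum span length reported (default 1).
#' @param og_id Orthogroup label for the report (default `""`).
#' @return Data frame with `og_id`, `sequence_id`, `start_codon`,
#'   `length_codons`, `fraction_of_alignment`.
#' @export
detect_gap_spans <- function(seqs, min_len_codons = 1L, og_id = "") {
  if (inherits(seqs, "gametolog_set")) {
    og_id <- seqs$og_id
    seqs <- seqs$seqs
  }
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1)
    stop("aligned lengths differ: ", paste(unique(lens), collapse = ", "))
  alen <- lens[1]
  if (alen %% 3 != 0)
    stop("aligned length ", alen, " is not a multiple of 3")
  rows <- list()
  for (id in names(seqs)) {
    ch <- strsplit(seqs[[id]], "")[[1]]
    gap_codon <- colSums(matrix(ch == "-", nrow = 3)) == 3
    r <- rle(gap_codon)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_len_codons)) {
      rows[[length(rows) + 1L]] <- data.frame(
        og_id = og_id, sequence_id = id,
        start_codon = starts[k] - 1L, length_codons = r$lengths[k],
        fraction_of_alignment = 3 * r$lengths[k] / alen,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(og_id = character(), sequence_id = character(),
                      start_codon = integer(), length_codons = integer(),
                      fraction_of_alignment = numeric()))
  }
  do.call(rbind, rows)
}

#' Local alignment of an exon against a scaffold
#'
#' Smith-Waterman local alignment with affine gaps (via
#' `Biostrings::pairwiseAlignment`), searching both the forward strand and
#' the reverse complement of the query. Coordinates are reported 0-based,
#' half-open, on the forward strand of the scaffold.
#'
#' @param query_exon Query sequence (>= 20 nt).
#' @param scaffold_seq Target scaffold sequence.
#' @param match,mismatch,gap_open,gap_extend Scoring scheme (defaults
#'   +2/-3/-5/-2).
#' @param score_min Minimum score to report a hit (default 50).
#' @param query_id Label carried into the result.
#' @return One-row data frame with `query_id`, `target_start`, `target_end`,
#'   `strand`, `score`, `identity`, or `NULL` when no alignment reaches
#'   `score_min` (or the scaffold is empty).
#' @export
local_align_exon <- function(query_exon, scaffold_seq,
                             match = 2, mismatch = -3,
                             gap_open = 5, gap_extend = 2,
                             score_min = 50, query_id = "query") {
  if (nchar(query_exon) < 20) stop("query must be at least 20 nt")
  if (nchar(scaffold_seq) == 0) return(NULL)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch)
  q_fwd <- Biostrings::DNAString(query_exon)
  q_rev <- Biostrings::reverseComplement(q_fwd)
  subj <- Biostrings::DNAString(scaffold_seq)
  best <- NULL
  for (strand in c("+", "-")) {
    q <- if (strand == "+") q_fwd else q_rev
    pa <- Biostrings::pairwiseAlignment(q, subj, type = "local",
                                        substitutionMatrix = sm,
                                        gapOpening = gap_open,
                                        gapExtension = gap_extend)
    if (is.null(best) || Biostrings::score(pa) > best$score) {
      s <- Biostrings::start(Biostrings::subject(pa))
      w <- Biostrings::width(Biostrings::subject(pa))
      best <- list(score = Biostrings::score(pa), strand = strand,
                   start0 = s - 1L, end0 = s - 1L + w,
                   identity = Biostrings::pid(pa) / 100)
    }
  }
  if (best$score < score_min) return(NULL)
  data.frame(query_id = query_id, target_start = best$start0,
             target_end = best$end0, strand = best$strand,
             score = best$score, identity = best$identity,
             stringsAsFactors = FALSE)
}
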