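# Codon-level machinery shared by the sequence simulator and the NG86
# estimator: sense-codon tables, single-nucleotide neighbourhoods,
# synonymous/nonsynonymous site counts and pathway-averaged difference
# counts between all sense codon pairs.

.codon_cache <- new.env(parent = emptyenv())

.NTS <- c("A", "C", "G", "T")
# transitions: A<->G, C<->T
.TS_PARTNER <- c(A = "G", C = "T", G = "A", T = "C")

#' Sense-codon tables for the standard nuclear genetic code
#'
#' Builds (and caches) the lookup tables used throughout the package: the 61
#' sense codons of the standard genetic code, their amino-acid translations,
#' the 9 single-nucleotide neighbours of each codon with transition and
#' synonymy flags, per-codon synonymous/nonsynonymous site counts, and the
#' pathway-averaged synonymous/nonsynonymous difference counts for every
#' ordered pair of sense codons.
#'
#' Changes to and through stop codons are excluded: a mutation creating a stop
#' codon contributes to neither the synonymous nor the nonsynonymous site
#' count, and substitution pathways between two codons that would pass through
#' a stop codon are dropped (remaining pathways are reweighted equally). For
#' the rare pair with no stop-free pathway, all pathways are used and steps
#' involving a stop codon are counted as nonsynonymous.
#'
#' @return A list with elements `codons` (61 sense codons), `aa` (translations),
#'   `stops`, `nb_codon` (61 x 9 matrix of neighbour codons), `nb_idx`
#'   (neighbour index among sense codons, `NA` for stops), `nb_is_ts`,
#'   `nb_is_syn`, `syn_sites`, `nonsyn_sites` (per-codon site counts), and
#'   `SD`/`ND` (61 x 61 pathway-averaged difference count matrices).
#' @keywords internal
codon_tables <- function() {
  if (!is.null(.codon_cache$tab)) return(.codon_cache$tab)

  gc_std <- Biostrings::GENETIC_CODE
  all_codons <- names(gc_std)
  stops <- all_codons[gc_std == "*"]
  codons <- all_codons[gc_std != "*"]
  aa <- gc_std[codons]
  n <- length(codons) # 61

  idx_of <- stats::setNames(seq_len(n), codons)

  nb_codon <- matrix("", n, 9L)
  nb_is_ts <- matrix(FALSE, n, 9L)
  for (i in seq_len(n)) {
    chars <- strsplit(codons[i], "")[[1]]
    k <- 0L
    for (pos in 1:3) {
      for (nt in .NTS) {
        if (nt == chars[pos]) next
        k <- k + 1L
        mut <- chars
        mut[pos] <- nt
        nb_codon[i, k] <- paste(mut, collapse = "")
        nb_is_ts[i, k] <- (.TS_PARTNER[[chars[pos]]] == nt)
      }
    }
  }
  nb_idx <- matrix(idx_of[nb_codon], n, 9L) # NA where neighbour is a stop
  nb_is_stop <- is.na(nb_idx)
  nb_is_syn <- matrix(NA, n, 9L)
  for (i in seq_len(n)) {
    ok <- !nb_is_stop[i, ]
    nb_is_syn[i, ok] <- gc_std[nb_codon[i, ok]] == aa[i]
  }

  # Site counts: each of the 3 positions offers 3 changes; a change counts
  # 1/3 of a site toward the class (syn / nonsyn) it belongs to, stop-creating
  # changes toward neither.
  syn_sites <- rowSums(nb_is_syn & !nb_is_stop, na.rm = TRUE) / 3
  nonsyn_sites <- rowSums(!nb_is_syn & !nb_is_stop, na.rm = TRUE) / 3

  pw <- .pairwise_path_counts(codons, gc_std, stops)

  .codon_cache$tab <- list(
    codons = codons, aa = aa, stops = stops, idx_of = idx_of,
    nb_codon = nb_codon, nb_idx = nb_idx, nb_is_ts = nb_is_ts,
    nb_is_syn = nb_is_syn, nb_is_stop = nb_is_stop,
    syn_sites = syn_sites, nonsyn_sites = nonsyn_sites,
    SD = pw$SD, ND = pw$ND
  )
  .codon_cache$tab
}

# Pathway-averaged synonymous / nonsynonymous difference counts for each
# ordered sense-codon pair. For a pair differing at k positions, the k!
# orderings of the position changes are enumerated; orderings passing through
# a stop codon are discarded and the rest weighted equally.
.pairwise_path_counts <- function(codons, gc_std, stops) {
  n <- length(codons)
  SD <- matrix(0, n, n)
  ND <- matrix(0, n, n)
  perms <- list(
    `1` = list(1L),
    `2` = list(c(1L, 2L), c(2L, 1L)),
    `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
               c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )
  split_codons <- strsplit(codons, "")
  for (i in seq_len(n)) {
    ci <- split_codons[[i]]
    for (j in seq_len(n)) {
      if (i == j) next
      cj <- split_codons[[j]]
      diff_pos <- which(ci != cj)
      k <- length(diff_pos)
      paths_s <- numeric(0)
      paths_n <- numeric(0)
      paths_s_all <- numeric(0)
      paths_n_all <- numeric(0)
      for (ord in perms[[as.character(k)]]) {
        cur <- ci
        s <- 0; nn <- 0
        valid <- TRUE
        for (pos in diff_pos[ord]) {
          nxt <- cur
          nxt[pos] <- cj[pos]
          from <- paste(cur, collapse = "")
          to <- paste(nxt, collapse = "")
          if (to %in% stops) valid <- FALSE # endpoints are sense, so any stop is an intermediate
          if (from %in% stops || to %in% stops) {
            nn <- nn + 1 # stop-involving step counted as nonsynonymous
          } else if (gc_std[[from]] == gc_std[[to]]) {
            s <- s + 1
          } else {
            nn <- nn + 1
          }
          cur <- nxt
        }
        paths_s_all <- c(paths_s_all, s)
        paths_n_all <- c(paths_n_all, nn)
        if (valid) {
          paths_s <- c(paths_s, s)
          paths_n <- c(paths_n, nn)
        }
      }
      if (length(paths_s) > 0) {
        SD[i, j] <- mean(paths_s)
        ND[i, j] <- mean(paths_n)
      } else {
        SD[i, j] <- mean(paths_s_all)
        ND[i, j] <- mean(paths_n_all)
      }
    }
  }
  list(SD = SD, ND = ND)
}

# Per-omega substitution-rate tables for the Gillespie simulator.
# rate(c -> neighbour) = kappa^[transition] * omega^[nonsynonymous],
# 0 for changes to stop codons; total rates are normalized by the mean total
# rate over a uniform codon distribution so that branch lengths are expected
# substitutions per codon site.
.codon_rates <- function(kappa, omega) {
  tab <- codon_tables()
  rate <- matrix(0, nrow(tab$nb_idx), 9L)
  ok <- !tab$nb_is_stop
  rate[ok] <- ifelse(tab$nb_is_ts[ok], kappa, 1) *
    ifelse(tab$nb_is_syn[ok], 1, omega)
  total <- rowSums(rate)
  rbar <- mean(total)
  cp <- rate / total
  cp <- t(apply(cp, 1, cumsum))
  list(total = total / rbar, cp = cp, nb_idx = tab$nb_idx)
}

# Split a gap-free in-frame nucleotide string into codon indices (1..61).
# Codons containing characters outside ACGT, or stop codons, are returned
# as NA.
.codon_indices <- function(seq) {
  tab <- codon_tables()
  seq <- toupper(seq)
  nc <- nchar(seq)
  if (nc %% 3 != 0) {
    stop("sequence length ", nc, " is not a multiple of 3")
  }
  cods <- substring(seq, seq(1, nc, by = 3), seq(3, nc, by = 3))
  unname(tab$idx_of[cods])
}
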