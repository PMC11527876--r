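# Independent oracles: brute-force K80 recount and exhaustive NG86
# codon-pair enumeration, coded separately from the package internals.

oracle_k80 <- function(a, b) {
  va <- toupper(unlist(strsplit(a, "")))
  vb <- toupper(unlist(strsplit(b, "")))
  n <- length(va)
  purine <- c("A", "G")
  ts <- 0L
  tv <- 0L
  for (i in seq_len(n)) {
    if (va[i] == vb[i]) next
    same_class <- (va[i] %in% purine) == (vb[i] %in% purine)
    if (same_class) ts <- ts + 1L else tv <- tv + 1L
  }
  P <- ts / n
  Q <- tv / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) return(NA_real_)
  -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
}

.oracle_gc <- Biostrings::GENETIC_CODE
.oracle_stops <- names(.oracle_gc)[.oracle_gc == "*"]
.oracle_sense <- names(.oracle_gc)[.oracle_gc != "*"]

# Synonymous / nonsynonymous (sense) site counts of one codon: each of the
# nine possible single-nucleotide changes contributes 1/3 of a site to the
# class it belongs to; changes creating a stop codon count toward neither.
oracle_ng86_sites <- function(codon) {
  ch <- unlist(strsplit(codon, ""))
  s <- 0
  n <- 0
  for (pos in 1:3) {
    for (nt in c("A", "C", "G", "T")) {
      if (nt == ch[pos]) next
      mut <- ch
      mut[pos] <- nt
      mc <- paste(mut, collapse = "")
      if (mc %in% .oracle_stops) next
      if (.oracle_gc[[mc]] == .oracle_gc[[codon]]) s <- s + 1 / 3 else n <- n + 1 / 3
    }
  }
  c(s = s, n = n)
}

.oracle_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in .oracle_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# Pathway-averaged synonymous / nonsynonymous differences between two sense
# codons: enumerate all orderings of the position changes, drop orderings
# passing through a stop codon (if all do, keep them all, counting
# stop-involving steps as nonsynonymous), and average with equal weights.
oracle_ng86_diffs <- function(c1, c2) {
  ch1 <- unlist(strsplit(c1, ""))
  ch2 <- unlist(strsplit(c2, ""))
  pos <- which(ch1 != ch2)
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  res_valid <- NULL
  res_all <- NULL
  for (ord in .oracle_perms(pos)) {
    cur <- ch1
    s <- 0
    n <- 0
    valid <- TRUE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- ch2[p]
      from <- paste(cur, collapse = "")
      to <- paste(nxt, collapse = "")
      if (to %in% .oracle_stops) valid <- FALSE
      if (from %in% .oracle_stops || to %in% .oracle_stops) {
        n <- n + 1
      } else if (.oracle_gc[[from]] == .oracle_gc[[to]]) {
        s <- s + 1
      } else {
        n <- n + 1
      }
      cur <- nxt
    }
    res_all <- rbind(res_all, c(s, n))
    if (valid) res_valid <- rbind(res_valid, c(s, n))
  }
  use <- if (!is.null(res_valid)) res_valid else res_all
  c(sd = mean(use[, 1]), nd = mean(use[, 2]))
}

# Random ungapped DNA string
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
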