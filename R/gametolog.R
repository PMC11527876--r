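# Gametolog resolution within orthogroups: longest-transcript selection,
# the asymmetric autosomal-to-Z reassignment rule, N-mt function labels,
# and the two gap-handling operations used before distance estimation.

#' Construct a gametolog set
#'
#' A gametolog set holds the aligned coding sequences of one orthogroup,
#' keyed by `"<lineage>|<linkage>"` (lineages `coastal`, `inland`,
#' `outgroup`; linkages `A`, `Z`, `W`). All sequences must share the aligned
#' length and at most one sequence may occupy each slot.
#'
#' @param og_id Orthogroup identifier.
#' @param seqs Named character vector of aligned sequences; names
#'   `"<lineage>|<linkage>"`.
#' @param gene_id Optional gene identifier (defaults to `og_id`).
#' @return A list of class `gametolog_set`.
#' @export
gametolog_set <- function(og_id, seqs, gene_id = og_id) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("seqs must be named '<lineage>|<linkage>'")
  if (anyDuplicated(names(seqs)))
    stop("duplicate (lineage, linkage) slot in orthogroup ", og_id)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1)
    stop("orthogroup ", og_id, ": aligned lengths differ (",
         paste(unique(lens), collapse = ", "), ")")
  structure(list(og_id = og_id, gene_id = gene_id, seqs = seqs,
                 reassigned = character(0)),
            class = "gametolog_set")
}

#' @export
print.gametolog_set <- function(x, ...) {
  cat("gametolog set", x$og_id, "(gene", paste0(x$gene_id, "):"),
      length(x$seqs), "sequences,", nchar(x$seqs[1]), "nt aligned\n")
  cat(" slots:", paste(names(x$seqs), collapse = ", "), "\n")
  if (length(x$reassigned))
    cat(" reassigned:", paste(x$reassigned, collapse = ", "), "\n")
  invisible(x)
}

#' Select the longest transcript per gene
#'
#' Picks, for each gene, the transcript with the greatest ungapped nucleotide
#' length; ties are broken by the lexicographically smallest transcript id.
#'
#' @param transcripts Named character vector of transcript sequences for one
#'   gene (names are transcript ids; gaps `-` are ignored for length).
#' @return The selected sequence, named by its transcript id.
#' @export
select_longest_transcript <- function(transcripts) {
  if (length(transcripts) == 0) stop("empty transcript set")
  if (is.null(names(transcripts))) stop("transcripts must be named")
  ungapped <- nchar(gsub("-", "", transcripts, fixed = TRUE))
  best <- which(ungapped == max(ungapped))
  best <- best[order(names(transcripts)[best])][1]
  transcripts[best]
}

#' Apply the asymmetric autosomal-to-Z gametolog reassignment rule
#'
#' Long, weakly differentiated neo-Z scaffolds are prone to being called
#' autosomal, so within each focal (non-outgroup) lineage: if the orthogroup
#' has an autosomal and a W-linked sequence but no Z-linked one, the autosomal
#' sequence is reassigned as the Z gametolog. The mirror case (autosomal + Z,
#' no W) is left unchanged: a missing W gametolog is treated as not sequenced,
#' because W scaffolds are easier to distinguish from autosomes, accumulate
#' sex-linked signal faster, and are shorter, making misassignment unlikely.
#'
#' @param set A [gametolog_set()].
#' @return The set with reassignments applied; reassigned slots are recorded
#'   in `$reassigned`. Idempotent.
#' @export
reassign_autosomal_gametologs <- function(set) {
  stopifnot(inherits(set, "gametolog_set"))
  for (lin in c("coastal", "inland")) {
    a <- paste(lin, "A", sep = "|")
    z <- paste(lin, "Z", sep = "|")
    w <- paste(lin, "W", sep = "|")
    has <- names(set$seqs)
    if (a %in% has && w %in% has && !(z %in% has)) {
      set$seqs[[z]] <- set$seqs[[a]]
      set$seqs <- set$seqs[names(set$seqs) != a]
      set$reassigned <- union(set$reassigned, z)
    }
  }
  set
}

#' Label genes with mitochondrial function
#'
#' Joins a gene table against a two-column function table (`gene_id`,
#' `is_nmt` in 0/1). Genes absent from the table default to non-N-mt, with a
#' warning reporting how many defaulted.
#'
#' @param genes Data frame with a `gene_id` column.
#' @param function_table Data frame with columns `gene_id` and `is_nmt`.
#' @return `genes` with a logical `is_nmt` column set.
#' @export
label_function <- function(genes, function_table) {
  if (anyDuplicated(function_table$gene_id)) {
    dup <- function_table[function_table$gene_id %in%
                            function_table$gene_id[duplicated(function_table$gene_id)], ]
    agg <- tapply(dup$is_nmt, dup$gene_id, function(v) length(unique(v)))
    if (any(agg > 1))
      stop("conflicting is_nmt entries for gene(s): ",
           paste(names(agg)[agg > 1], collapse = ", "))
    function_table <- function_table[!duplicated(function_table$gene_id), ]
  }
  idx <- match(genes$gene_id, function_table$gene_id)
  n_missing <- sum(is.na(idx))
  if (n_missing > 0)
    warning(n_missing, " gene(s) absent from function table; labelled non-N-mt")
  genes$is_nmt <- !is.na(idx) & function_table$is_nmt[idx] == 1
  genes
}

#' Remove gapped alignment columns from a sequence pair
#'
#' Deletes every alignment column in which either sequence carries a gap
#' (`-`) or an ambiguous base (`N`); retained characters keep their order.
#'
#' @param a,b Aligned sequences of equal length.
#' @return Character vector of length 2: the gap-free pair.
#' @export
delete_gap_sites <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("aligned lengths differ: ", nchar(a), " vs ", nchar(b))
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  keep <- !(ca %in% c("-", "N") | cb %in% c("-", "N"))
  c(paste(ca[keep], collapse = ""), paste(cb[keep], collapse = ""))
}

#' Trim codon columns gapped in any focal-lineage gametolog
#'
#' Removes from every sequence of an orthogroup the codon columns (nucleotide
#' triplets) in which any non-outgroup sequence carries a gap (`-`) or an
#' ambiguous base (`N`). Gaps confined to the outgroup do not trigger
#' removal.
#'
#' @param set A [gametolog_set()] with aligned length divisible by 3.
#' @return The trimmed set; all sequences keep a common length divisible by 3.
#' @export
trim_codon_gaps <- function(set) {
  stopifnot(inherits(set, "gametolog_set"))
  len <- nchar(set$seqs[1])
  if (len %% 3 != 0)
    stop("orthogroup ", set$og_id, ": aligned length ", len,
         " is not a multiple of 3")
  n_codons <- len / 3
  focal <- set$seqs[!startsWith(names(set$seqs), "outgroup")]
  drop <- rep(FALSE, n_codons)
  for (s in focal) {
    ch <- strsplit(toupper(s), "")[[1]]
    bad <- ch == "-" | ch == "N"
    drop <- drop | colSums(matrix(bad, nrow = 3)) > 0
  }
  if (any(drop)) {
    keep_nt <- rep(!drop, each = 3)
    set$seqs <- vapply(set$seqs, function(s) {
      paste(strsplit(s, "")[[1]][keep_nt], collapse = "")
    }, "")
  }
  set
}
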