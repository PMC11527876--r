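# Readers and writers for the pipeline's file formats: TSV tables with a
# provenance footer, per-orthogroup FASTA alignments, and the reference
# chromosome naming table.

#' Write a TSV table with a provenance footer
#'
#' Tab-separated UTF-8 with a header row; provenance (config hash, seed, tool
#' version) is appended as `#`-prefixed comment lines that [read_tsv()]
#' ignores.
#'
#' @param x Data frame.
#' @param path Output path.
#' @param provenance Optional named character vector appended as comments.
#' @export
write_tsv <- function(x, path, provenance = NULL) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  if (!is.null(provenance)) {
    con <- file(path, open = "a", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste0("# ", names(provenance), "=", provenance), con)
  }
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, quote = "",
                    fileEncoding = "UTF-8")
}

#' Write per-orthogroup FASTA alignments
#'
#' One FASTA file per orthogroup, named `<og_id>.fasta`; sequence ids follow
#' `<gene>|<lineage>|<linkage>`.
#'
#' @param alignments Named list (og_id -> named character vector of aligned
#'   sequences), as produced by [simulate_gametolog_alignments()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_og_fasta <- function(alignments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (og in names(alignments)) {
    x <- Biostrings::DNAStringSet(alignments[[og]])
    Biostrings::writeXStringSet(x, file.path(dir, paste0(og, ".fasta")))
  }
  invisible(dir)
}

#' Read per-orthogroup FASTA alignments into gametolog sets
#'
#' Reads every `*.fasta`/`*.fa` file in a directory; the orthogroup id is the
#' file name stem and sequence ids must be `<gene>|<lineage>|<linkage>`.
#' Files are processed in sorted order so results do not depend on directory
#' listing order.
#'
#' @param dir Directory of FASTA files.
#' @return Named list of [gametolog_set()]s keyed by og_id.
#' @export
read_og_fasta_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.(fasta|fa)$", full.names = TRUE))
  sets <- list()
  for (f in files) {
    og <- sub("\\.(fasta|fa)$", "", basename(f))
    x <- Biostrings::readDNAStringSet(f)
    seqs <- stats::setNames(as.character(x), names(x))
    parts <- strsplit(names(seqs), "|", fixed = TRUE)
    bad <- vapply(parts, length, 0L) != 3L
    if (any(bad))
      stop(f, ": sequence id not '<gene>|<lineage>|<linkage>': ",
           names(seqs)[bad][1])
    gene <- vapply(parts, `[[`, "", 1)
    slot <- paste(vapply(parts, `[[`, "", 2), vapply(parts, `[[`, "", 3),
                  sep = "|")
    sets[[og]] <- gametolog_set(og, stats::setNames(seqs, slot),
                                gene_id = gene[1])
  }
  sets
}

#' Read a reference chromosome naming table
#'
#' Two tab-separated columns, `chrom` and `class`, where `class` is one of
#' `autosome`, `Z`, `W`, `mito`. Needed because reference assemblies differ
#' in chromosome naming dialects.
#'
#' @param path Path to the TSV.
#' @return Named character vector chrom -> class.
#' @export
read_chrom_classes <- function(path) {
  tab <- read_tsv(path)
  if (!all(c("chrom", "class") %in% names(tab)))
    stop("chromosome naming table needs columns 'chrom' and 'class'")
  bad <- setdiff(unique(tab$class), c("autosome", "Z", "W", "mito"))
  if (length(bad))
    stop("unknown chromosome class(es): ", paste(bad, collapse = ", "))
  stats::setNames(tab$class, tab$chrom)
}
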