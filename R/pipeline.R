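# End-to-end orchestration: configuration loading/validation and the two
# analysis stages (H1 scaffold classification; H2/H3 gametolog divergence),
# each a pure function of its inputs and configuration, writing TSV tables
# with provenance footers plus a machine-readable JSON summary.

#' Load and validate a pipeline configuration
#'
#' Configuration is a YAML file (or an equivalent list) with input paths
#' (`depth_table`, `kmer_table`, `paf`, `chrom_classes`, `og_fasta_dir`,
#' `function_table`), thresholds (`mapq_min`, `zscore_cut`,
#' `outlier_quantile`, `n_boot`), a `seed` and an `outdir`. Referenced input
#' paths must exist; thresholds outside their valid ranges are rejected.
#'
#' @param x Path to a YAML file, or a list.
#' @return Validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  defaults <- list(mapq_min = 40L, zscore_cut = 1.96, outlier_quantile = 0.01,
                   n_boot = 1000L, seed = 1L, outdir = ".")
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (cfg$mapq_min < 0 || cfg$zscore_cut <= 0 ||
      cfg$outlier_quantile <= 0 || cfg$outlier_quantile > 1 ||
      cfg$n_boot < 100)
    stop("pipeline threshold out of valid range")
  for (key in c("depth_table", "kmer_table", "paf", "chrom_classes",
                "og_fasta_dir", "function_table")) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]]))
      stop("configured input does not exist: ", key, " = ", cfg[[key]])
  }
  class(cfg) <- "pipeline_config"
  cfg
}

.provenance <- function(cfg) {
  plain <- unclass(cfg)
  plain$outdir <- NULL # hash covers inputs, thresholds and seed only
  hash <- substr(.digest_list(plain), 1, 12)
  c(config_hash = hash, seed = as.character(cfg$seed),
    tool = paste0("neosexscan ", as.character(utils::packageVersion("neosexscan"))))
}

# md5 of the deparsed configuration (written to a temp file: tools::md5sum
# works on files)
.digest_list <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(x), collapse = ""), f)
  unname(tools::md5sum(f))
}

#' Run the scaffold sex-linkage stage (H1)
#'
#' Computes the three per-scaffold metrics, classifies scaffolds (PCA +
#' clustering), validates with LOOCV LDA, assigns reference top hits from the
#' PAF and flags neo-sex scaffolds. Writes `linkage_calls.tsv`,
#' `neo_sex_hits.tsv` and `h1_summary.json` into `cfg$outdir`.
#'
#' @param cfg A [pipeline_config()] with `depth_table`, `kmer_table`, `paf`
#'   and `chrom_classes` set.
#' @return Invisibly, a list with `calls`, `hits`, `variance_explained`,
#'   `loocv_accuracy`, `summary`.
#' @export
run_h1 <- function(cfg) {
  cfg <- pipeline_config(cfg)
  for (key in c("depth_table", "kmer_table", "paf", "chrom_classes"))
    if (is.null(cfg[[key]])) stop("run_h1 requires config entry: ", key)
  t0 <- proc.time()[["elapsed"]]
  warn <- character(0)
  wh <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warn <<- c(warn, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  depth <- read_tsv(cfg$depth_table)
  kmer <- read_tsv(cfg$kmer_table)
  chrom_classes <- read_chrom_classes(cfg$chrom_classes)
  paf <- read_paf(cfg$paf)

  metrics <- compute_metrics(depth, kmer)
  cls <- classify_scaffolds(metrics)
  acc <- wh(lda_cross_validate(metrics, cls$calls))
  hits <- do.call(rbind, lapply(unique(paf$query), function(q)
    assign_reference_target(paf, q, mapq_min = cfg$mapq_min)))
  flags <- if (is.null(hits)) NULL else wh(flag_neo_sex(cls$calls, hits, chrom_classes))

  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  prov <- .provenance(cfg)
  calls_out <- merge(cls$calls, metrics, by = "scaffold_id", sort = TRUE)
  write_tsv(calls_out, file.path(cfg$outdir, "linkage_calls.tsv"), prov)
  if (!is.null(flags))
    write_tsv(flags, file.path(cfg$outdir, "neo_sex_hits.tsv"), prov)

  class_counts <- table(factor(cls$calls$call, levels = c("A", "Z", "W")))
  if (class_counts[["W"]] == 0) {
    warn <- c(warn, "no scaffolds called W")
    warning("no scaffolds called W")
  }
  neo_len <- list()
  if (!is.null(flags)) {
    neo <- flags[flags$is_neo_sex, ]
    lens <- metrics$length_bp[match(neo$scaffold_id, metrics$scaffold_id)]
    neo_len <- as.list(tapply(lens, factor(neo$call, levels = c("Z", "W")),
                              function(v) sum(v, na.rm = TRUE)))
    neo_len[vapply(neo_len, is.na, TRUE)] <- 0
  }
  summary <- list(
    n_scaffolds = nrow(metrics),
    class_counts = as.list(class_counts),
    variance_explained = cls$variance_explained,
    loocv_accuracy = acc,
    n_neo_sex = if (is.null(flags)) 0L else sum(flags$is_neo_sex),
    neo_sex_length_bp = neo_len,
    warnings = warn,
    provenance = as.list(prov)
  )
  jsonlite::write_json(summary, file.path(cfg$outdir, "h1_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("[h1] done in %.1fs (%d scaffolds)",
                  proc.time()[["elapsed"]] - t0, nrow(metrics)))
  invisible(list(calls = cls$calls, hits = flags,
                 variance_explained = cls$variance_explained,
                 loocv_accuracy = acc, summary = summary))
}

#' Run the gametolog divergence stage (H2/H3)
#'
#' Reads per-orthogroup alignments and the function table, applies the
#' autosomal-to-Z reassignment rule, and computes: between-lineage K80 Dxy per
#' gametolog, delta-Dxy Z-score outliers, NG86 dN/dS per gametolog with the
#' coastal-inland contrast and its extreme-value flags, codon-bootstrap
#' positive-selection p-values, gap-span (exon loss) reports, and
#' random-intercept LMM fits for both responses. Writes TSV tables and
#' `h2h3_summary.json` into `cfg$outdir`.
#'
#' @param cfg A [pipeline_config()] with `og_fasta_dir` and `function_table`
#'   set.
#' @return Invisibly, a list with the component tables and fits.
#' @export
run_h2_h3 <- function(cfg) {
  cfg <- pipeline_config(cfg)
  for (key in c("og_fasta_dir", "function_table"))
    if (is.null(cfg[[key]])) stop("run_h2_h3 requires config entry: ", key)
  t0 <- proc.time()[["elapsed"]]
  warn <- character(0)
  wh <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warn <<- c(warn, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  sets <- read_og_fasta_dir(cfg$og_fasta_dir)
  fun_tab <- read_tsv(cfg$function_table)
  ok_len <- vapply(sets, function(s) nchar(s$seqs[1]) %% 3 == 0, TRUE)
  if (any(!ok_len)) {
    warn <- c(warn, paste("skipped orthogroup(s) with frame violation:",
                          paste(names(sets)[!ok_len], collapse = ", ")))
    sets <- sets[ok_len]
  }
  sets <- lapply(sets, reassign_autosomal_gametologs)

  dxy <- wh(dxy_table(sets))
  genes <- data.frame(gene_id = vapply(sets, `[[`, "", "gene_id"),
                      stringsAsFactors = FALSE)
  genes <- wh(label_function(genes, fun_tab))
  dxy$is_nmt <- genes$is_nmt[match(dxy$gene_id, genes$gene_id)]
  delta <- tryCatch(wh(delta_dxy_outliers(dxy, zscore_cut = cfg$zscore_cut)),
                    error = function(e) {
                      warn <<- c(warn, conditionMessage(e))
                      NULL
                    })
  dnds <- wh(dnds_table(sets))
  dnds$is_nmt <- genes$is_nmt[match(dnds$gene_id, genes$gene_id)]
  contrast <- wh(dnds_contrast(dnds, outlier_quantile = cfg$outlier_quantile))

  boot <- do.call(rbind, lapply(seq_along(sets), function(i) {
    set <- sets[[i]]
    og_slot <- grep("^outgroup\\|", names(set$seqs), value = TRUE)
    if (!length(og_slot)) return(NULL)
    trimmed <- trim_codon_gaps(set)
    rows <- list()
    for (slot in intersect(c("coastal|Z", "coastal|W", "inland|Z", "inland|W"),
                           names(trimmed$seqs))) {
      pair <- .delete_gap_codons(trimmed$seqs[[slot]],
                                 trimmed$seqs[[og_slot[1]]])
      if (nchar(pair[1]) == 0) next
      res <- wh(bootstrap_selection_screen(pair[1], pair[2],
                                           n_boot = cfg$n_boot,
                                           seed = .sub_seed(cfg$seed, i)))
      rows[[slot]] <- cbind(data.frame(og_id = set$og_id, slot = slot,
                                       stringsAsFactors = FALSE), res)
    }
    if (length(rows)) do.call(rbind, rows) else NULL
  }))

  gaps <- do.call(rbind, lapply(sets, function(s) detect_gap_spans(s)))

  lmm_dxy <- NULL
  if (!is.null(dxy) && nrow(dxy) > 0 && length(unique(dxy$linkage)) == 2 &&
      length(unique(dxy$is_nmt)) == 2) {
    lmm_dxy <- wh(interaction_and_contrasts(
      dxy[!is.na(dxy$dxy), ], response = "dxy"))
  }
  lmm_ci <- NULL
  if (!is.null(contrast) && nrow(contrast) > 0) {
    cdat <- contrast
    cdat$is_nmt <- genes$is_nmt[match(cdat$gene_id, genes$gene_id)]
    if (length(unique(cdat$linkage)) == 2 && length(unique(cdat$is_nmt)) == 2) {
      lmm_ci <- wh(fit_random_intercept_lmm(cdat, "dnds_ci",
                                            c("is_nmt", "linkage"),
                                            interaction = FALSE))
    }
  }

  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  prov <- .provenance(cfg)
  write_tsv(dxy, file.path(cfg$outdir, "dxy.tsv"), prov)
  if (!is.null(delta)) write_tsv(delta, file.path(cfg$outdir, "delta_dxy.tsv"), prov)
  write_tsv(dnds, file.path(cfg$outdir, "dnds.tsv"), prov)
  write_tsv(contrast, file.path(cfg$outdir, "dnds_contrast.tsv"), prov)
  if (!is.null(boot)) write_tsv(boot, file.path(cfg$outdir, "selection_screen.tsv"), prov)
  if (!is.null(gaps) && nrow(gaps) > 0)
    write_tsv(gaps, file.path(cfg$outdir, "gap_spans.tsv"), prov)

  summary <- list(
    n_orthogroups = length(sets),
    n_dxy = nrow(dxy),
    n_delta_outliers = if (is.null(delta)) 0L else sum(delta$is_outlier),
    n_dnds = nrow(dnds),
    n_contrast_outliers = if (is.null(contrast)) 0L else sum(contrast$is_outlier),
    lmm_dxy_interaction_p = if (is.null(lmm_dxy)) NA else lmm_dxy$interaction_p,
    lmm_dxy_w_effect_ratio = if (is.null(lmm_dxy)) NA else lmm_dxy$w_effect_ratio,
    n_gap_spans = if (is.null(gaps)) 0L else nrow(gaps),
    warnings = warn,
    provenance = as.list(prov)
  )
  jsonlite::write_json(summary, file.path(cfg$outdir, "h2h3_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("[h2h3] done in %.1fs (%d orthogroups)",
                  proc.time()[["elapsed"]] - t0, length(sets)))
  invisible(list(dxy = dxy, delta_dxy = delta, dnds = dnds,
                 contrast = contrast, bootstrap = boot, gap_spans = gaps,
                 lmm_dxy = lmm_dxy, lmm_dnds_ci = lmm_ci, summary = summary))
}

#' Generate a full synthetic input bundle on disk
#'
#' Runs both synthetic-data generators and writes their outputs in the
#' pipeline's input formats: depth/kmer TSVs, per-orthogroup FASTA, OG and
#' function tables, a PAF of reference alignments (sex-linked scaffolds map
#' to the neo-sex source autosome `chr1A`, autosomal scaffolds to `chr2`),
#' a reference chromosome naming table, and the truth labels as JSON.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory.
#' @return Invisibly, a named list of written paths.
#' @export
run_simulate <- function(config, outdir) {
  validate_sim_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  scaf <- simulate_scaffold_tables(config)
  aln <- simulate_gametolog_alignments(config)
  paths <- list(
    depth_table = file.path(outdir, "depth_table.tsv"),
    kmer_table = file.path(outdir, "kmer_table.tsv"),
    paf = file.path(outdir, "reference_hits.paf"),
    chrom_classes = file.path(outdir, "chrom_classes.tsv"),
    og_fasta_dir = file.path(outdir, "og_fasta"),
    og_table = file.path(outdir, "og_table.tsv"),
    function_table = file.path(outdir, "function_table.tsv"),
    truth = file.path(outdir, "truth.json")
  )
  write_tsv(scaf$depth_table, paths$depth_table)
  write_tsv(scaf$kmer_table, paths$kmer_table)
  linkage <- scaf$truth$scaffold_linkage
  target <- ifelse(linkage == "A", "chr2", "chr1A")
  qlen <- scaf$kmer_table$length_bp[match(names(linkage),
                                          scaf$kmer_table$scaffold_id)]
  blk <- pmax(1000L, as.integer(round(qlen * 0.9)))
  writeLines(paste(names(linkage), qlen, 0L, blk, "+", target, 150000000L,
                   1000L, 1000L + blk, as.integer(round(blk * 0.95)), blk,
                   60L, sep = "\t"),
             paths$paf)
  write_tsv(data.frame(chrom = c("chr1A", "chr2", "chrZ", "chrW", "chrM"),
                       class = c("autosome", "autosome", "Z", "W", "mito")),
            paths$chrom_classes)
  write_og_fasta(aln$alignments, paths$og_fasta_dir)
  write_tsv(aln$og_table, paths$og_table)
  write_tsv(aln$function_table, paths$function_table)
  jsonlite::write_json(list(scaffold_linkage = as.list(scaf$truth$scaffold_linkage),
                            gene_function = as.list(aln$truth$gene_function)),
                       paths$truth, auto_unbox = TRUE)
  invisible(paths)
}
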