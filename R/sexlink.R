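# Scaffold sex-linkage: the three per-scaffold metrics (unmatched single-copy
# kmer proportion, male:female mean-depth ratio, male:female horizontal
# coverage ratio), PCA + 1-D clustering into Z/W/autosomal, LOOCV LDA
# validation, and neo-sex flagging from reference-genome top hits.

#' Compute per-scaffold sex-linkage metrics
#'
#' From a per-sex depth/coverage table and a female-pool kmer summary,
#' computes for every scaffold the male:female mean-depth ratio, the
#' male:female horizontal-coverage ratio (both with a pseudocount `eps` in
#' numerator and denominator), and the proportion of female-pool single-copy
#' kmers unmatched in the male pool.
#'
#' @param depth_table Data frame with columns `scaffold_id`, `sex`
#'   (male/female), `mean_depth`, `horiz_cov`; exactly one male and one female
#'   row per scaffold.
#' @param kmer_table Data frame with columns `scaffold_id`, `n_kmers`,
#'   `n_kmers_unmatched` (female-pool kmers checked against the male pool);
#'   an optional `length_bp` column is carried through.
#' @param eps Pseudocount added to both sides of each ratio (default 0.5).
#' @return Data frame with columns `scaffold_id`, `unmatched_kmer_prop`,
#'   `depth_ratio_mf`, `cov_ratio_mf`, `length_bp`.
#' @export
compute_metrics <- function(depth_table, kmer_table, eps = 0.5) {
  need <- c("scaffold_id", "sex", "mean_depth", "horiz_cov")
  if (!all(need %in% names(depth_table)))
    stop("depth_table must have columns ", paste(need, collapse = ", "))
  m <- depth_table[depth_table$sex == "male", ]
  f <- depth_table[depth_table$sex == "female", ]
  ids <- sort(unique(depth_table$scaffold_id))
  miss_m <- setdiff(ids, m$scaffold_id)
  miss_f <- setdiff(ids, f$scaffold_id)
  if (length(miss_m) || length(miss_f)) {
    stop("scaffold(s) present for only one sex: ",
         paste(unique(c(miss_m, miss_f)), collapse = ", "))
  }
  m <- m[match(ids, m$scaffold_id), ]
  f <- f[match(ids, f$scaffold_id), ]
  k <- kmer_table[match(ids, kmer_table$scaffold_id), ]
  if (anyNA(k$n_kmers)) {
    stop("kmer_table is missing scaffold(s): ",
         paste(ids[is.na(k$n_kmers)], collapse = ", "))
  }
  data.frame(
    scaffold_id = ids,
    unmatched_kmer_prop = ifelse(k$n_kmers == 0, 0,
                                 k$n_kmers_unmatched / k$n_kmers),
    depth_ratio_mf = (m$mean_depth + eps) / (f$mean_depth + eps),
    cov_ratio_mf = (m$horiz_cov + eps) / (f$horiz_cov + eps),
    length_bp = if ("length_bp" %in% names(k)) k$length_bp else NA_integer_,
    stringsAsFactors = FALSE
  )
}

# Deterministic 1-D k-means (k = 3) seeded from PC1 quantiles; no RNG so the
# result is invariant to input order.
.kmeans3_1d <- function(x) {
  centers <- stats::quantile(x, c(0.1, 0.5, 0.9), names = FALSE, type = 7)
  if (length(unique(centers)) < 3) {
    centers <- sort(unique(x))[1:3] # distinctness checked by caller
  }
  stats::kmeans(x, centers = matrix(centers, ncol = 1), iter.max = 100L)
}

#' Classify scaffolds as Z, W or autosomal
#'
#' Z-standardizes the three metric columns, runs PCA, clusters the PC1 scores
#' with 1-D k-means (k = 3), and anchors the cluster labels biologically by
#' the cluster medians of the raw male:female depth ratio: highest median is
#' Z (males carry two Z copies), lowest is W (absent in males), the remaining
#' cluster is autosomal.
#'
#' @param metrics Output of [compute_metrics()]; at least 3 scaffolds with
#'   at least 3 distinct metric profiles.
#' @return A list with `calls` (data frame `scaffold_id`, `pc1`, `pc2`,
#'   `call`, `dist_to_center`) and `variance_explained` (per-PC fractions
#'   summing to 1).
#' @export
classify_scaffolds <- function(metrics) {
  X <- as.matrix(metrics[, c("unmatched_kmer_prop", "depth_ratio_mf", "cov_ratio_mf")])
  if (nrow(X) < 3) stop("need at least 3 scaffolds to classify")
  sds <- apply(X, 2, stats::sd)
  if (all(sds == 0)) stop("degenerate input: all metrics constant")
  keep <- sds > 0
  Xs <- scale(X[, keep, drop = FALSE])
  pca <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  # canonical sign: largest-magnitude loading of each PC is positive, so
  # calls do not depend on LAPACK sign conventions or row order
  for (j in seq_len(ncol(pca$rotation))) {
    pivot <- which.max(abs(pca$rotation[, j]))
    if (pca$rotation[pivot, j] < 0) {
      pca$rotation[, j] <- -pca$rotation[, j]
      pca$x[, j] <- -pca$x[, j]
    }
  }
  ve <- pca$sdev^2 / sum(pca$sdev^2)
  pc1 <- pca$x[, 1]
  if (length(unique(pc1)) < 3)
    stop("cannot form 3 clusters: fewer than 3 distinct PC1 values")
  km <- .kmeans3_1d(pc1)
  med_ratio <- vapply(1:3, function(cl)
    stats::median(metrics$depth_ratio_mf[km$cluster == cl]), 0)
  # anchor clusters to the ploidy-expected male:female depth ratios
  # (W ~ 0: absent in males; A ~ 1; Z ~ 2: males ZZ, females ZW). Nearest
  # expectation wins, so a cohort genuinely missing a class (e.g. no W
  # scaffolds) does not have one invented for it.
  expected <- c(W = 0, A = 1, Z = 2)
  lab <- vapply(med_ratio, function(m)
    names(expected)[which.min(abs(m - expected))], "")
  calls <- data.frame(
    scaffold_id = metrics$scaffold_id,
    pc1 = pc1,
    pc2 = if (ncol(pca$x) >= 2) pca$x[, 2] else 0,
    call = lab[km$cluster],
    dist_to_center = abs(pc1 - km$centers[km$cluster, 1]),
    stringsAsFactors = FALSE
  )
  list(calls = calls, variance_explained = ve)
}

#' Leave-one-out cross-validated LDA accuracy of the sex-linkage metrics
#'
#' Fits a linear discriminant analysis of the three raw metrics against the
#' PCA-derived linkage calls with leave-one-out cross-validation and returns
#' the cross-validated accuracy. Classes with a single member cannot be
#' cross-validated and are excluded with a warning.
#'
#' @param metrics Output of [compute_metrics()].
#' @param calls The `calls` data frame from [classify_scaffolds()].
#' @return Accuracy in \[0, 1\].
#' @export
lda_cross_validate <- function(metrics, calls) {
  stopifnot(identical(metrics$scaffold_id, calls$scaffold_id))
  cls <- calls$call
  tabn <- table(cls)
  single <- names(tabn)[tabn < 2]
  keep <- !(cls %in% single)
  if (length(single)) {
    warning("excluding ", sum(!keep), " scaffold(s) in single-member class(es): ",
            paste(single, collapse = ", "))
  }
  if (length(unique(cls[keep])) < 2)
    stop("need at least 2 classes with >= 2 members for LOOCV LDA")
  X <- metrics[keep, c("unmatched_kmer_prop", "depth_ratio_mf", "cov_ratio_mf")]
  fit <- MASS::lda(X, grouping = factor(cls[keep]), CV = TRUE)
  mean(as.character(fit$class) == cls[keep])
}

#' Parse a PAF alignment file
#'
#' Reads the 12 mandatory columns of minimap2's pairwise alignment format.
#'
#' @param path Path to a PAF file.
#' @return Data frame with columns `query`, `query_len`, `query_start`,
#'   `query_end`, `strand`, `target`, `target_len`, `target_start`,
#'   `target_end`, `n_match`, `block_len`, `mapq`.
#' @export
read_paf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(query = character(), query_len = integer(),
                      query_start = integer(), query_end = integer(),
                      strand = character(), target = character(),
                      target_len = integer(), target_start = integer(),
                      target_end = integer(), n_match = integer(),
                      block_len = integer(), mapq = integer(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 0L) < 12L)
  if (length(bad)) stop("malformed PAF line ", bad[1], ": fewer than 12 columns")
  num_cols <- c(2, 3, 4, 8, 9, 10, 11, 12)
  out <- data.frame(
    query = vapply(fields, `[[`, "", 1),
    query_len = NA_integer_, query_start = NA_integer_, query_end = NA_integer_,
    strand = vapply(fields, `[[`, "", 5),
    target = vapply(fields, `[[`, "", 6),
    target_len = NA_integer_, target_start = NA_integer_,
    target_end = NA_integer_, n_match = NA_integer_,
    block_len = NA_integer_, mapq = NA_integer_,
    stringsAsFactors = FALSE
  )
  names_num <- c("query_len", "query_start", "query_end", "target_len",
                 "target_start", "target_end", "n_match", "block_len", "mapq")
  cols <- c(2, 3, 4, 7, 8, 9, 10, 11, 12)
  for (k in seq_along(cols)) {
    v <- suppressWarnings(as.integer(vapply(fields, `[[`, "", cols[k])))
    if (anyNA(v)) stop("malformed PAF line ", which(is.na(v))[1],
                       ": non-integer in column ", cols[k])
    out[[names_num[k]]] <- v
  }
  out
}

#' Best reference target for one scaffold
#'
#' Applies the top-hit rule: keep alignment blocks with mapping quality at
#' least `mapq_min`, sort by descending mapq then descending block length
#' (ties broken by ascending target name), and return the top record.
#'
#' @param paf_records Data frame as from [read_paf()].
#' @param scaffold_id Query scaffold name.
#' @param mapq_min Minimum mapping quality retained (default 40).
#' @return One-row data frame `scaffold_id`, `target_chrom`, `mapq`,
#'   `block_len`, or `NULL` if no record survives the filter.
#' @export
assign_reference_target <- function(paf_records, scaffold_id, mapq_min = 40L) {
  rec <- paf_records[paf_records$query == scaffold_id &
                       paf_records$mapq >= mapq_min, , drop = FALSE]
  if (nrow(rec) == 0) return(NULL)
  ord <- order(-rec$mapq, -rec$block_len, rec$target)
  top <- rec[ord[1], ]
  data.frame(scaffold_id = scaffold_id, target_chrom = top$target,
             mapq = top$mapq, block_len = top$block_len,
             stringsAsFactors = FALSE)
}

#' Flag neo-sex scaffolds
#'
#' A scaffold is flagged neo-sex when its linkage call is Z or W but its best
#' reference target is an autosome: sex-linked sequence whose homolog sits on
#' an ancestral autosome betrays a recent autosome-to-sex-chromosome
#' transition.
#'
#' @param calls The `calls` data frame from [classify_scaffolds()].
#' @param hits Data frame of best hits (rows as returned by
#'   [assign_reference_target()]).
#' @param chrom_classes Named character vector mapping reference chromosome
#'   names to `"autosome"`, `"Z"`, `"W"` or `"mito"`.
#' @return `hits` with columns `call` and `is_neo_sex` added; hits without a
#'   linkage call are dropped with a warning.
#' @export
flag_neo_sex <- function(calls, hits, chrom_classes) {
  idx <- match(hits$scaffold_id, calls$scaffold_id)
  if (anyNA(idx)) {
    warning("dropping ", sum(is.na(idx)), " hit(s) without a linkage call: ",
            paste(hits$scaffold_id[is.na(idx)], collapse = ", "))
    hits <- hits[!is.na(idx), , drop = FALSE]
    idx <- idx[!is.na(idx)]
  }
  tclass <- chrom_classes[hits$target_chrom]
  if (anyNA(tclass)) {
    stop("reference chromosome(s) missing from naming table: ",
         paste(unique(hits$target_chrom[is.na(tclass)]), collapse = ", "))
  }
  hits$call <- calls$call[idx]
  hits$is_neo_sex <- hits$call %in% c("Z", "W") & tclass == "autosome"
  hits
}
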