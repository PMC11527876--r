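# Synthetic-data generators: per-scaffold sex-pooled mapping summaries with
# known Z/W/autosomal structure, and codon alignments of gametolog sets
# evolved under a continuous-time codon substitution process, with truth
# labels for parameter-recovery testing.

#' Simulation configuration
#'
#' Assembles and validates the configuration driving both synthetic-data
#' generators. Defaults emulate a two-lineage (coastal/inland) passerine
#' neo-sex chromosome system: autosomal scaffolds with equal male and female
#' read depth, Z scaffolds with a 2:1 male:female depth ratio (males ZZ,
#' females hemizygous Z), W scaffolds present only in females apart from a
#' small mismapping floor, and W-linked gametologs of nuclear genes with
#' mitochondrial function (N-mt genes) diverging faster between lineages.
#'
#' @param seed Integer seed; all randomness in the generators derives from it.
#' @param n_autosomal,n_z,n_w Scaffold counts per linkage class.
#' @param depth_mean Expected per-site read depth in the female pool.
#' @param depth_dispersion Overdispersion factor for depth counts
#'   (variance = dispersion * mean); 1 gives Poisson counts.
#' @param n_genes Number of orthogroups to simulate.
#' @param gene_length_codons Codons per simulated gene.
#' @param nmt_fraction Fraction of genes labelled as N-mt.
#' @param kappa Transition/transversion rate ratio of the codon process.
#' @param omega_map Named numeric vector of dN/dS values per branch class:
#'   `outgroup`, `autosomal`, `z_coastal`, `z_inland`, `w_coastal`,
#'   `w_inland`; all strictly positive.
#' @param branch_lengths Named numeric vector of expected substitutions per
#'   codon site per branch: `outgroup`, `lineage_stem`, `autosomal`,
#'   `sex_stem`, `z`, `w`; all finite and non-negative.
#' @param w_nmt_boost Multiplier (>= 1) applied to the W tip branch length of
#'   N-mt genes, encoding accelerated between-lineage divergence of W-linked
#'   N-mt gametologs.
#' @param deletion_spec Optional data frame with columns `gene_id`, `lineage`,
#'   `linkage`, `start_codon` (1-based), `length_codons`: codon spans replaced
#'   by alignment gaps in the emitted sequence.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_autosomal = 100L, n_z = 100L, n_w = 100L,
                       depth_mean = 30, depth_dispersion = 1.5,
                       n_genes = 100L, gene_length_codons = 300L,
                       nmt_fraction = 0.1,
                       kappa = 4,
                       omega_map = c(outgroup = 0.2, autosomal = 0.2,
                                     z_coastal = 0.2, z_inland = 0.2,
                                     w_coastal = 0.5, w_inland = 0.5),
                       branch_lengths = c(outgroup = 0.10,
                                          lineage_stem = 5e-4,
                                          autosomal = 1e-3,
                                          sex_stem = 5e-4,
                                          z = 5e-4, w = 2e-3),
                       w_nmt_boost = 4,
                       deletion_spec = NULL) {
  cfg <- list(seed = as.integer(seed),
              n_autosomal = as.integer(n_autosomal),
              n_z = as.integer(n_z), n_w = as.integer(n_w),
              depth_mean = depth_mean,
              depth_dispersion = depth_dispersion,
              n_genes = as.integer(n_genes),
              gene_length_codons = as.integer(gene_length_codons),
              nmt_fraction = nmt_fraction, kappa = kappa,
              omega_map = omega_map, branch_lengths = branch_lengths,
              w_nmt_boost = w_nmt_boost, deletion_spec = deletion_spec)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @param cfg A `sim_config` candidate list.
#' @export
validate_sim_config <- function(cfg) {
  stopf <- function(...) stop("invalid sim_config: ", sprintf(...), call. = FALSE)
  cnts <- c(cfg$n_autosomal, cfg$n_z, cfg$n_w, cfg$n_genes,
            cfg$gene_length_codons)
  if (any(!is.finite(cnts)) || any(cnts < 0)) stopf("counts must be finite and >= 0")
  if (!is.finite(cfg$depth_mean) || cfg$depth_mean < 0) stopf("depth_mean must be finite and >= 0")
  if (!is.finite(cfg$depth_dispersion) || cfg$depth_dispersion < 1) stopf("depth_dispersion must be >= 1")
  if (!is.finite(cfg$nmt_fraction) || cfg$nmt_fraction < 0 || cfg$nmt_fraction > 1)
    stopf("nmt_fraction must be in [0, 1]")
  if (!is.finite(cfg$kappa) || cfg$kappa <= 0) stopf("kappa must be > 0")
  need_om <- c("outgroup", "autosomal", "z_coastal", "z_inland", "w_coastal", "w_inland")
  if (!all(need_om %in% names(cfg$omega_map))) stopf("omega_map must name %s", paste(need_om, collapse = ", "))
  if (any(!is.finite(cfg$omega_map)) || any(cfg$omega_map <= 0)) stopf("omega values must be finite and > 0")
  need_bl <- c("outgroup", "lineage_stem", "autosomal", "sex_stem", "z", "w")
  if (!all(need_bl %in% names(cfg$branch_lengths))) stopf("branch_lengths must name %s", paste(need_bl, collapse = ", "))
  if (any(!is.finite(cfg$branch_lengths)) || any(cfg$branch_lengths < 0))
    stopf("branch lengths must be finite and >= 0")
  if (!is.finite(cfg$w_nmt_boost) || cfg$w_nmt_boost < 1) stopf("w_nmt_boost must be >= 1")
  if (!is.null(cfg$deletion_spec)) {
    ds <- cfg$deletion_spec
    need <- c("gene_id", "lineage", "linkage", "start_codon", "length_codons")
    if (!is.data.frame(ds) || !all(need %in% names(ds)))
      stopf("deletion_spec needs columns %s", paste(need, collapse = ", "))
    if (any(ds$start_codon < 1 | ds$length_codons < 1))
      stopf("deletion spans must have start_codon >= 1 and length_codons >= 1")
    if (any(ds$start_codon + ds$length_codons - 1 > cfg$gene_length_codons))
      stopf("deletion span exceeds gene length")
  }
  invisible(cfg)
}

# Deterministic per-unit sub-seed below 2^31, so outputs do not depend on the
# order units are simulated in.
.sub_seed <- function(seed, idx) {
  as.integer((as.double(seed) * 7919 + as.double(idx) * 104729) %% 2147483629 + 1)
}

# Overdispersed depth counts: negative binomial with variance = disp * mean;
# disp = 1 degenerates to Poisson.
.rdepth <- function(n, mu, disp) {
  if (mu <= 0) return(integer(n))
  if (disp <= 1) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = mu / (disp - 1))
}

# A scaffold's mean mapped depth: the scaffold is covered by many positions,
# so the mean concentrates around its expectation. Modelled as an
# overdispersed count total over .N_DEPTH_WINDOWS equal windows divided by
# the window count; expectation mu, variance disp * mu / .N_DEPTH_WINDOWS.
.N_DEPTH_WINDOWS <- 100L
.rmean_depth <- function(n, mu, disp) {
  .rdepth(n, mu * .N_DEPTH_WINDOWS, disp) / .N_DEPTH_WINDOWS
}

.rbeta_mean <- function(n, mean, conc = 300) {
  stats::rbeta(n, mean * conc, (1 - mean) * conc)
}

# Fraction of the present-sex depth expectation that the absent sex still
# receives through mismapped reads.
.MISMAP_FLOOR <- 0.02

#' Simulate per-scaffold sex-pooled mapping summaries
#'
#' Draws, for each scaffold, per-sex mean mapped read depth (overdispersed
#' counts), horizontal mapping coverage, and single-copy kmer match counts,
#' with class-specific expectations: autosomal scaffolds 1:1 male:female
#' depth, Z scaffolds 2:1, W scaffolds 0:1 apart from a 2% mismapping floor.
#' Female-pool single-copy kmers of W scaffolds are mostly unmatched in the
#' male pool; on A and Z scaffolds nearly all match.
#'
#' @param config A [sim_config()].
#' @return A list with `depth_table` (columns `scaffold_id`, `sex`,
#'   `mean_depth`, `horiz_cov`, `n_kmers`, `n_kmers_unmatched`; two rows per
#'   scaffold), `kmer_table` (female-pool kmer summary: `scaffold_id`,
#'   `length_bp`, `n_kmers`, `n_kmers_unmatched`), and `truth` with
#'   `scaffold_linkage` (named vector over {A, Z, W}).
#' @export
simulate_scaffold_tables <- function(config) {
  validate_sim_config(config)
  classes <- rep(c("A", "Z", "W"), c(config$n_autosomal, config$n_z, config$n_w))
  n <- length(classes)
  ids <- sprintf("scaf%05d", seq_len(n))

  mu_f <- config$depth_mean
  mu_m <- c(A = mu_f, Z = 2 * mu_f, W = .MISMAP_FLOOR * mu_f)[classes]
  cov_m_mean <- c(A = 0.99, Z = 0.99, W = 0.04)[classes]
  cov_f_mean <- rep(0.99, n)
  p_unmatched <- c(A = 0.01, Z = 0.02, W = 0.92)[classes]

  length_bp <- integer(n)
  md_m <- md_f <- numeric(n)
  cov_m <- cov_f <- numeric(n)
  nk_f <- nk_unm_f <- integer(n)
  nk_m <- nk_unm_m <- integer(n)
  for (i in seq_len(n)) {
    set.seed(.sub_seed(config$seed, i))
    length_bp[i] <- max(1000L, as.integer(round(stats::rlnorm(1, log(5e5), 0.5))))
    md_m[i] <- .rmean_depth(1, mu_m[i], config$depth_dispersion)
    md_f[i] <- .rmean_depth(1, mu_f, config$depth_dispersion)
    cov_m[i] <- .rbeta_mean(1, cov_m_mean[i])
    cov_f[i] <- .rbeta_mean(1, cov_f_mean[i])
    lam <- length_bp[i] / 500
    nk_f[i] <- stats::rpois(1, lam)
    nk_unm_f[i] <- stats::rbinom(1, nk_f[i], p_unmatched[i])
    # male-pool kmers: W scaffolds are essentially absent from the male pool
    nk_m[i] <- stats::rpois(1, if (classes[i] == "W") lam * 0.03 else lam)
    nk_unm_m[i] <- stats::rbinom(1, nk_m[i], if (classes[i] == "W") 0.5 else 0.01)
  }

  depth_table <- data.frame(
    scaffold_id = rep(ids, each = 2L),
    sex = rep(c("male", "female"), n),
    mean_depth = as.vector(rbind(md_m, md_f)),
    horiz_cov = as.vector(rbind(cov_m, cov_f)),
    n_kmers = as.vector(rbind(nk_m, nk_f)),
    n_kmers_unmatched = as.vector(rbind(nk_unm_m, nk_unm_f)),
    stringsAsFactors = FALSE
  )
  kmer_table <- data.frame(
    scaffold_id = ids, length_bp = length_bp,
    n_kmers = nk_f, n_kmers_unmatched = nk_unm_f,
    stringsAsFactors = FALSE
  )
  list(depth_table = depth_table, kmer_table = kmer_table,
       truth = list(scaffold_linkage = stats::setNames(classes, ids)))
}

#' Random sense-codon sequence
#'
#' Draws codons uniformly over the 61 sense codons of the standard genetic
#' code. Uses the current RNG state.
#'
#' @param n_codons Number of codons.
#' @return A nucleotide string of length `3 * n_codons`.
#' @export
random_codon_sequence <- function(n_codons) {
  tab <- codon_tables()
  paste(tab$codons[sample.int(61L, n_codons, replace = TRUE)], collapse = "")
}

#' Evolve a coding sequence under a codon substitution process
#'
#' Simulates single-nucleotide codon changes by exponential waiting times
#' (Gillespie algorithm), independently per codon site. Change rates are
#' proportional to `kappa` for transitions and 1 for transversions, multiplied
#' by `omega` for nonsynonymous changes; changes to stop codons are forbidden.
#' Rates are normalized so that `t` is the expected number of substitutions
#' per codon site for a uniform sense-codon sequence. Uses the current RNG
#' state.
#'
#' @param seq In-frame, gap-free nucleotide string over sense codons.
#' @param t Branch length (expected substitutions per codon site), >= 0.
#' @param kappa Transition/transversion rate ratio.
#' @param omega dN/dS of the branch.
#' @return The evolved nucleotide string.
#' @export
evolve_codon_sequence <- function(seq, t, kappa = 1, omega = 1) {
  x <- .codon_indices(seq)
  if (anyNA(x)) stop("sequence contains stop codons or non-ACGT characters")
  rt <- .codon_rates(kappa, omega)
  tab <- codon_tables()
  paste(tab$codons[.evolve_codons(x, t, rt)], collapse = "")
}

.evolve_codons <- function(x, t, rt) {
  if (t <= 0 || length(x) == 0) return(x)
  remaining <- rep(t, length(x))
  active <- seq_along(x)
  while (length(active)) {
    w <- stats::rexp(length(active), rt$total[x[active]])
    remaining[active] <- remaining[active] - w
    active <- active[remaining[active] > 0]
    if (!length(active)) break
    u <- stats::runif(length(active))
    j <- rowSums(rt$cp[x[active], , drop = FALSE] < u) + 1L
    x[active] <- rt$nb_idx[cbind(x[active], j)]
  }
  x
}

#' Simulate codon alignments of two-lineage gametolog sets
#'
#' For each orthogroup, draws a root coding sequence (uniform over sense
#' codons), then evolves it along the fixed topology
#' `(Outgroup, (Autosomal, (W, Z)))`, independently for the coastal and inland
#' lineages which share the outgroup. W tip branches of N-mt genes are
#' multiplied by `w_nmt_boost`. Since homology is exact by construction, the
#' emitted per-orthogroup sequence sets are aligned; deletions requested in
#' `deletion_spec` are written as `-` gap columns and recorded in the truth
#' labels.
#'
#' @param config A [sim_config()].
#' @return A list with `alignments` (named list: og_id -> named character
#'   vector of aligned sequences with ids `<gene>|<lineage>|<linkage>`),
#'   `og_table` (`og_id`, `gene_id`, `lineage`, `linkage`), `function_table`
#'   (`gene_id`, `is_nmt`), and `truth` (`gene_function`, `branch_omega`,
#'   `deletion_spans`).
#' @export
simulate_gametolog_alignments <- function(config) {
  validate_sim_config(config)
  tab <- codon_tables()
  ng <- config$n_genes
  genes <- sprintf("g%04d", seq_len(ng))
  ogs <- sprintf("OG%04d", seq_len(ng))
  bl <- config$branch_lengths
  om <- config$omega_map

  set.seed(.sub_seed(config$seed, 0L))
  n_nmt <- round(config$nmt_fraction * ng)
  is_nmt <- stats::setNames(rep(FALSE, ng), genes)
  if (n_nmt > 0) is_nmt[sample.int(ng, n_nmt)] <- TRUE

  rt <- list(
    outgroup = .codon_rates(config$kappa, om[["outgroup"]]),
    autosomal = .codon_rates(config$kappa, om[["autosomal"]]),
    z_coastal = .codon_rates(config$kappa, om[["z_coastal"]]),
    z_inland = .codon_rates(config$kappa, om[["z_inland"]]),
    w_coastal = .codon_rates(config$kappa, om[["w_coastal"]]),
    w_inland = .codon_rates(config$kappa, om[["w_inland"]])
  )

  alignments <- vector("list", ng)
  names(alignments) <- ogs
  branch_omega <- list()
  L <- config$gene_length_codons

  for (gi in seq_len(ng)) {
    set.seed(.sub_seed(config$seed, gi))
    g <- genes[gi]
    root <- sample.int(61L, L, replace = TRUE)
    seqs <- list()
    seqs[[paste(g, "outgroup", "A", sep = "|")]] <-
      .evolve_codons(root, bl[["outgroup"]], rt$outgroup)
    for (lin in c("coastal", "inland")) {
      anc <- .evolve_codons(root, bl[["lineage_stem"]], rt$autosomal)
      seqs[[paste(g, lin, "A", sep = "|")]] <-
        .evolve_codons(anc, bl[["autosomal"]], rt$autosomal)
      sexanc <- .evolve_codons(anc, bl[["sex_stem"]], rt$autosomal)
      seqs[[paste(g, lin, "Z", sep = "|")]] <-
        .evolve_codons(sexanc, bl[["z"]], rt[[paste0("z_", lin)]])
      t_w <- bl[["w"]] * if (is_nmt[[g]]) config$w_nmt_boost else 1
      seqs[[paste(g, lin, "W", sep = "|")]] <-
        .evolve_codons(sexanc, t_w, rt[[paste0("w_", lin)]])
      branch_omega[[paste(g, lin, "Z", sep = "|")]] <- om[[paste0("z_", lin)]]
      branch_omega[[paste(g, lin, "W", sep = "|")]] <- om[[paste0("w_", lin)]]
    }
    branch_omega[[paste(g, "outgroup", "A", sep = "|")]] <- om[["outgroup"]]
    aln <- vapply(seqs, function(x) paste(tab$codons[x], collapse = ""), "")
    alignments[[ogs[gi]]] <- aln
  }

  del_spans <- NULL
  if (!is.null(config$deletion_spec)) {
    ds <- config$deletion_spec
    for (r in seq_len(nrow(ds))) {
      og <- ogs[match(ds$gene_id[r], genes)]
      if (is.na(og)) stop("deletion_spec names unknown gene: ", ds$gene_id[r])
      sid <- paste(ds$gene_id[r], ds$lineage[r], ds$linkage[r], sep = "|")
      aln <- alignments[[og]]
      if (!sid %in% names(aln)) stop("deletion_spec names unknown sequence: ", sid)
      nt_start <- (ds$start_codon[r] - 1L) * 3L + 1L
      nt_len <- ds$length_codons[r] * 3L
      s <- aln[[sid]]
      substr(s, nt_start, nt_start + nt_len - 1L) <-
        strrep("-", nt_len)
      aln[[sid]] <- s
      alignments[[og]] <- aln
    }
    del_spans <- ds
  }

  og_table <- do.call(rbind, lapply(seq_len(ng), function(gi) {
    ids <- names(alignments[[ogs[gi]]])
    parts <- do.call(rbind, strsplit(ids, "|", fixed = TRUE))
    data.frame(og_id = ogs[gi], gene_id = parts[, 1], lineage = parts[, 2],
               linkage = parts[, 3], stringsAsFactors = FALSE)
  }))
  function_table <- data.frame(gene_id = genes, is_nmt = as.integer(is_nmt),
                               stringsAsFactors = FALSE)
  list(alignments = alignments, og_table = og_table,
       function_table = function_table,
       truth = list(gene_function = is_nmt, branch_omega = branch_omega,
                    deletion_spans = del_spans))
}
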