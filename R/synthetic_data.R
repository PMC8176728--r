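# Synthetic cohorts with planted ground truth: log-normal baseline
# abundances, tissue-level jitter calibrated so the uniformly-expressed CV
# mode sits near 65, fold-enriched tissues pushing the tissue-enriched CV
# mode past 200, host genes generated at planted log-scale correlations,
# and categorical annotations drawn from an odds-ratio design.

odds_p <- function(p, or) {
  o <- or * p / (1 - p)
  o / (1 + o)
}

#' Simulation parameters for a synthetic snoRNA cohort
#'
#' Defaults emulate the structure of the published seven-tissue cohort:
#' 7 tissues x 3 replicates, 390 uniformly-expressed and 85 tissue-enriched
#' snoRNAs, a log-normal TPM baseline, tissue jitter placing the UE CV mode
#' near 65, enrichment folds of 5-50x placing the TE CV mode past 200, a
#' host-correlation design of 60% rho = 0.7 / 25% rho = 0 / 15% rho = -0.6
#' (correlation planted on the log2 abundance scale), and class-dependent
#' categorical flags specified as (probability in UE, odds ratio in TE).
#'
#' @param n_ue,n_te Number of uniformly-expressed / tissue-enriched genes.
#' @param tissues Tissue names; the first two form the default joint pair.
#' @param replicates_per_tissue Replicates per tissue.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline of true mean
#'   abundance (natural-log scale, TPM units).
#' @param tissue_jitter_sdlog Log-scale sd of the per-tissue multiplier for
#'   every gene (0.59 puts the UE CV mode near 65).
#' @param te_fold_range Uniform range of the enrichment multiplier.
#' @param replicate_noise_cv Coefficient of variation of replicate noise.
#' @param joint_pair,joint_pair_fraction Joint-enrichment tissue pair and
#'   the fraction of TE genes enriched in both.
#' @param intergenic_fraction Fraction of snoRNAs without a host gene.
#' @param correlation_design Tibble with columns `fraction`, `rho`
#'   (fractions sum to 1).
#' @param host_meanlog,host_baseline_sdlog,host_sdlog Host-gene baseline
#'   location/spread and within-host log-scale variation.
#' @param flag_design Tibble with columns `flag`, `p_ue`, `or_te` for the
#'   binary annotations box_cd, target_orphan, host_noncoding,
#'   nmd_substrate, promoter_di.
#' @param cons_mean_ue,cons_mean_te,cons_concentration Beta-distributed
#'   conservation score means per class and shared concentration.
#' @param seed Integer master seed; every draw derives from it.
#' @param null_associations If `TRUE`, all flag odds ratios are set to 1,
#'   every planted correlation to 0 and the conservation means equalized —
#'   the null configuration used for calibration checks.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_ue = 390, n_te = 85,
                       tissues = c("breast", "ovary", "prostate", "testis",
                                   "skeletal_muscle", "liver", "brain"),
                       replicates_per_tissue = 3,
                       baseline_meanlog = log(30), baseline_sdlog = 1.3,
                       tissue_jitter_sdlog = 0.59,
                       te_fold_range = c(5, 50),
                       replicate_noise_cv = 0.15,
                       joint_pair = c("breast", "ovary"),
                       joint_pair_fraction = 0.05,
                       intergenic_fraction = 0.10,
                       correlation_design = tibble(
                         fraction = c(0.60, 0.25, 0.15),
                         rho = c(0.7, 0, -0.6)),
                       host_meanlog = log(50), host_baseline_sdlog = 1.0,
                       host_sdlog = 0.8,
                       flag_design = tibble(
                         flag = c("box_cd", "target_orphan", "host_noncoding",
                                  "nmd_substrate", "promoter_di"),
                         p_ue = c(0.75, 0.15, 0.20, 0.40, 0.50),
                         or_te = c(0.5, 6, 10, 0.5, 0.3)),
                       cons_mean_ue = 0.55, cons_mean_te = 0.35,
                       cons_concentration = 8,
                       seed = 1L,
                       null_associations = FALSE) {
  if (null_associations) {
    flag_design$or_te <- 1
    correlation_design <- tibble(fraction = 1, rho = 0)
    cons_mean_te <- cons_mean_ue
  }
  if (abs(sum(correlation_design$fraction) - 1) > 1e-9) {
    abort("correlation design fractions must sum to 1.")
  }
  if (n_ue + n_te < 50 && n_te > 0) {
    warn("fewer than 50 genes; threshold estimation will be unstable.")
  }
  if (any(c(baseline_sdlog, tissue_jitter_sdlog, replicate_noise_cv,
            host_sdlog) <= 0)) {
    abort("all scale parameters must be positive.")
  }
  structure(as.list(environment()), class = "sim_params")
}

#' Simulate a synthetic cohort with planted ground truth
#'
#' Generates the abundance matrix (snoRNAs plus their host genes), the
#' annotation table and a truth table from a [sim_params()] design, fully
#' reproducibly from the design's seed. UE genes share one baseline across
#' tissues up to log-normal jitter; TE genes get one tissue (or the joint
#' pair) multiplied by the enrichment fold; replicates add log-normal noise
#' around the tissue means; host log2 abundances are built from the
#' realized snoRNA log abundances at the planted correlation.
#'
#' @param params A [sim_params()] object.
#' @return List with elements `matrix` ([abundance_matrix()]),
#'   `annotation` (tibble), `truth` (tibble) and `params`.
#' @export
simulate_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  tiss <- params$tissues
  n_t <- length(tiss)
  n_rep <- params$replicates_per_tissue
  n <- params$n_ue + params$n_te
  if (n < 1) abort("need at least one gene.")
  classes <- rep(c("UE", "TE"), c(params$n_ue, params$n_te))
  sno_ids <- sprintf("SNOSIM%04d", seq_len(n))
  sample_ids <- paste(rep(tiss, each = n_rep), seq_len(n_rep), sep = "_")
  sample_tissue <- setNames(rep(tiss, each = n_rep), sample_ids)

  baseline <- exp(rnorm(n, params$baseline_meanlog, params$baseline_sdlog))
  jitter <- matrix(exp(rnorm(n * n_t, 0, params$tissue_jitter_sdlog)),
                   nrow = n, dimnames = list(sno_ids, tiss))
  true_means <- baseline * jitter

  planted_tissues <- rep("", n)
  planted_fold <- rep(NA_real_, n)
  te_idx <- which(classes == "TE")
  for (i in te_idx) {
    fold <- runif(1, params$te_fold_range[1], params$te_fold_range[2])
    planted_fold[i] <- fold
    if (runif(1) < params$joint_pair_fraction) {
      second_fold <- fold / runif(1, 1, 2)
      true_means[i, params$joint_pair[1]] <-
        true_means[i, params$joint_pair[1]] * fold
      true_means[i, params$joint_pair[2]] <-
        true_means[i, params$joint_pair[2]] * second_fold
      planted_tissues[i] <- paste(sort(params$joint_pair), collapse = ";")
    } else {
      tt <- sample(tiss, 1)
      true_means[i, tt] <- true_means[i, tt] * fold
      planted_tissues[i] <- tt
    }
  }

  s_r <- sqrt(log(1 + params$replicate_noise_cv^2))
  rep_noise <- matrix(exp(rnorm(n * n_t * n_rep, -s_r^2 / 2, s_r)),
                      nrow = n)
  values <- true_means[, rep(seq_len(n_t), each = n_rep), drop = FALSE] * rep_noise
  colnames(values) <- sample_ids
  rownames(values) <- sno_ids

  # class-dependent binary flags from the odds-ratio design
  fd <- params$flag_design
  flags <- sapply(seq_len(nrow(fd)), function(k) {
    p <- ifelse(classes == "TE", odds_p(fd$p_ue[k], fd$or_te[k]), fd$p_ue[k])
    runif(n) < p
  })
  colnames(flags) <- fd$flag
  flags <- as_tibble(flags)

  intergenic <- runif(n) < params$intergenic_fraction
  host_ids <- ifelse(intergenic, NA_character_,
                     sprintf("HGSIM%04d", seq_len(n)))

  # planted correlation cells among intron-embedded snoRNAs
  cdz <- params$correlation_design
  planted_rho <- rep(NA_real_, n)
  intronic_idx <- which(!intergenic)
  if (length(intronic_idx) > 0) {
    cell <- sample.int(nrow(cdz), length(intronic_idx), replace = TRUE,
                       prob = cdz$fraction)
    planted_rho[intronic_idx] <- cdz$rho[cell]
  }

  host_values <- NULL
  if (length(intronic_idx) > 0) {
    host_base <- rnorm(length(intronic_idx), params$host_meanlog,
                       params$host_baseline_sdlog)
    host_values <- t(vapply(seq_along(intronic_idx), function(k) {
      i <- intronic_idx[k]
      z <- as.numeric(scale(log2(values[i, ])))
      rho <- planted_rho[i]
      e <- rnorm(length(z))
      h <- rho * z + sqrt(1 - rho^2) * e
      exp(host_base[k]) * 2^(params$host_sdlog * h)
    }, numeric(ncol(values))))
    rownames(host_values) <- host_ids[intronic_idx]
    colnames(host_values) <- sample_ids
  }

  all_values <- rbind(values, host_values)
  mat <- abundance_matrix(all_values, sample_tissue)

  cons_mean <- ifelse(classes == "TE", params$cons_mean_te, params$cons_mean_ue)
  kappa <- params$cons_concentration
  cons_vert <- rbeta(n, cons_mean * kappa, (1 - cons_mean) * kappa)
  cons_prim <- rbeta(n, pmin(cons_mean + 0.15, 0.95) * kappa,
                     (1 - pmin(cons_mean + 0.15, 0.95)) * kappa)

  target_class <- ifelse(flags$target_orphan, "orphan",
                         ifelse(runif(n) < 0.8, "rRNA", "snRNA"))
  host_biotype_raw <- ifelse(intergenic, NA_character_,
                             ifelse(flags$host_noncoding, "lincRNA",
                                    "protein_coding"))
  fn_groups <- c("ribosomal protein", "RNA processing / ribosome biogenesis",
                 "other", "unknown")
  host_function <- ifelse(
    !intergenic & !flags$host_noncoding,
    sample(fn_groups, n, replace = TRUE, prob = c(0.2, 0.3, 0.4, 0.1)),
    NA_character_)

  sno_ann <- tibble(
    gene_id = sno_ids,
    gene_name = sprintf("SIMSNO%04d", seq_len(n)),
    biotype_raw = "snoRNA",
    genomic_context = ifelse(intergenic, "intergenic", "intronic"),
    host_gene_id = host_ids,
    host_biotype_raw = host_biotype_raw,
    host_function_group = host_function,
    box_type = ifelse(flags$box_cd, "CD", "HACA"),
    target_class = target_class,
    nmd_substrate = ifelse(intergenic, NA, flags$nmd_substrate),
    promoter_type = ifelse(intergenic, NA_character_,
                           ifelse(flags$promoter_di, "DI", "SI")),
    conservation_vertebrates = cons_vert,
    conservation_primates = cons_prim
  )
  host_ann <- tibble(
    gene_id = host_ids[intronic_idx],
    gene_name = host_ids[intronic_idx],
    biotype_raw = host_biotype_raw[intronic_idx]
  )
  annotation <- complete_annotation(dplyr::bind_rows(sno_ann, host_ann))

  truth <- dplyr::bind_cols(
    tibble(gene_id = sno_ids,
           planted_class = classes,
           planted_tissues = planted_tissues,
           planted_fold = planted_fold,
           planted_rho = planted_rho,
           host_gene_id = host_ids,
           intergenic = intergenic),
    flags)

  list(matrix = mat, annotation = annotation, truth = truth, params = params)
}

#' Write a simulated cohort as plain-text fixture files
#'
#' Writes `abundance.tsv`, `samples.tsv`, `annotation.tsv` and `truth.tsv`
#' into a directory, in the formats [read_abundance_table()] and
#' [read_gene_annotation()] read back (round-trip exact to writing
#' precision).
#'
#' @param sim Result of [simulate_cohort()].
#' @param directory Output directory (created if missing).
#' @return Invisibly, a named list of the four file paths.
#' @export
write_fixture <- function(sim, directory) {
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create directory %s", directory))
  }
  paths <- list(
    abundance = file.path(directory, "abundance.tsv"),
    samples = file.path(directory, "samples.tsv"),
    annotation = file.path(directory, "annotation.tsv"),
    truth = file.path(directory, "truth.tsv")
  )
  ab <- as_tibble(sim$matrix$values, rownames = "gene_id")
  readr::write_tsv(ab, paths$abundance, progress = FALSE)
  readr::write_tsv(tibble(sample = names(sim$matrix$sample_tissue),
                          tissue = unname(sim$matrix$sample_tissue)),
                   paths$samples, progress = FALSE)
  readr::write_tsv(sim$annotation, paths$annotation, progress = FALSE)
  readr::write_tsv(sim$truth, paths$truth, progress = FALSE)
  invisible(paths)
}
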