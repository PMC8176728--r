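# Pipeline orchestration: a single validated config carrying every analysis
# constant, the staged filter -> CV -> threshold -> classify -> enrich ->
# correlate -> associate run with stage outputs and a JSON summary report,
# and a reproduction entry point for supplementary abundance tables.

#' Default analysis configuration
#'
#' One flat list holding every tunable constant of the analysis with its
#' published default: the 1 TPM expression threshold, the SCARNA name
#' exclusion, sample sd (ddof = 1), the KDE bandwidth rule and grid, the
#' correlation level and the +/- 0.25 class cut-offs, significance
#' alpha = 0.05, the breast/ovary joint-enrichment pair with fold 2, and
#' the 1 TPM pseudocount for log ratios. Override entries via `...`.
#'
#' @param ... Named overrides of default entries (unknown names error).
#' @return A list of class `snoscape_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    abundance_path = NULL,
    sample_sheet_path = NULL,
    annotation_path = NULL,
    out_dir = NULL,
    expression_threshold_tpm = 1,
    exclude_name_prefixes = "SCARNA",
    cv_ddof = 1,
    cv_level = "tissue-means",
    kde_bandwidth_rule = "scott",
    kde_grid_points = 1024,
    correlation_level = "samples",
    correlation_transform = "linear",
    correlation_cutoff = 0.25,
    alpha = 0.05,
    joint_pair = c("breast", "ovary"),
    joint_fold = 2,
    ratio_pseudocount = 1
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("unknown config entries: %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "snoscape_config")
}

#' Validate an analysis configuration
#' @param cfg A config list.
#' @return The validated config (invisibly errors otherwise).
#' @export
validate_config <- function(cfg) {
  num_pos <- c("expression_threshold_tpm", "kde_grid_points",
               "correlation_cutoff", "alpha", "joint_fold",
               "ratio_pseudocount")
  for (k in num_pos) {
    if (!is.numeric(cfg[[k]]) || length(cfg[[k]]) != 1 || cfg[[k]] <= 0) {
      abort(sprintf("config entry `%s` must be a positive number.", k))
    }
  }
  if (!cfg$cv_ddof %in% c(0, 1)) abort("config entry `cv_ddof` must be 0 or 1.")
  if (!cfg$cv_level %in% c("tissue-means", "samples")) {
    abort("config entry `cv_level` must be 'tissue-means' or 'samples'.")
  }
  if (!cfg$correlation_level %in% c("samples", "tissue-means")) {
    abort("config entry `correlation_level` must be 'samples' or 'tissue-means'.")
  }
  if (!cfg$correlation_transform %in% c("linear", "log2")) {
    abort("config entry `correlation_transform` must be 'linear' or 'log2'.")
  }
  if (length(cfg$joint_pair) != 2) abort("`joint_pair` must name two tissues.")
  invisible(cfg)
}

#' Read / write configs as YAML
#' @param path YAML file path.
#' @return For `read_config`, a validated `snoscape_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(default_config, raw)
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @param cfg Config list to serialize.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Run the full abundance-class and host-correlation pipeline
#'
#' Executes expression filtering, replicate averaging, CV computation, KDE
#' tangent threshold detection, UE/TE classification, tissue-enrichment
#' assignment, host-gene pairing and correlation with BH FDR, log-ratio
#' computation and the association battery. When `config$out_dir` is set,
#' every stage table is written as TSV plus a JSON summary report.
#'
#' @param config A [default_config()] list; either file paths
#'   (`abundance_path`, `sample_sheet_path`, `annotation_path`) or in-memory
#'   `matrix` / `annotation` arguments must be supplied.
#' @param matrix Optional pre-loaded [abundance_matrix()] (overrides paths).
#' @param annotation Optional pre-loaded annotation tibble.
#' @return A `snoscape_report` list: filter counts, threshold diagnostics,
#'   class counts, enrichment tally, correlation summary, the association
#'   battery table and the stage tables themselves.
#' @export
run_pipeline <- function(config = default_config(), matrix = NULL,
                         annotation = NULL) {
  validate_config(config)
  if (is.null(matrix)) {
    if (is.null(config$abundance_path) || is.null(config$sample_sheet_path)) {
      abort("stage load: no matrix supplied and no abundance/sample-sheet paths configured.")
    }
    matrix <- read_abundance_table(config$abundance_path,
                                   config$sample_sheet_path)
  }
  if (is.null(annotation)) {
    if (is.null(config$annotation_path)) {
      abort("stage load: no annotation supplied and no annotation path configured.")
    }
    annotation <- read_gene_annotation(config$annotation_path)
  }
  annotation <- complete_annotation(annotation)

  filtered <- filter_expressed(matrix, annotation,
                               threshold_tpm = config$expression_threshold_tpm,
                               exclude_name_prefixes = config$exclude_name_prefixes)
  profile <- tissue_means(filtered)

  sno_ids <- intersect(rownames(filtered$values),
                       annotation$gene_id[annotation$biotype_group == "snoRNA"])
  if (length(sno_ids) < 10) {
    abort("stage cv: fewer than 10 expressed snoRNAs; cannot estimate the CV density.")
  }
  cv_input <- if (config$cv_level == "tissue-means") profile else filtered$values
  cv_table <- compute_cv(cv_input[sno_ids, , drop = FALSE], ddof = config$cv_ddof)

  curve <- estimate_density(cv_table$cv,
                            bandwidth_rule = config$kde_bandwidth_rule,
                            grid_points = config$kde_grid_points)
  thr <- steepest_descent_threshold(curve)
  assignments <- classify_abundance(cv_table, thr)
  assignments <- assign_tissue_enrichment(profile, assignments,
                                          joint_pair = config$joint_pair,
                                          joint_fold = config$joint_fold)
  log_stage("classify", "ue_genes", sum(assignments$abundance_class == "UE"))
  log_stage("classify", "te_genes", sum(assignments$abundance_class == "TE"))

  pairs <- pair_snorna_host(
    dplyr::filter(annotation, .data$gene_id %in% sno_ids), filtered)
  correlations <- NULL
  ratios <- NULL
  if (nrow(pairs) > 0) {
    correlations <- correlate_pairs(pairs, filtered,
                                    level = config$correlation_level,
                                    transform = config$correlation_transform)
    correlations <- finalize_correlations(correlations, alpha = config$alpha,
                                          cutoff = config$correlation_cutoff)
    ratios <- abundance_ratio(pairs, profile,
                              pseudocount = config$ratio_pseudocount)
  }

  battery <- class_association_battery(assignments, correlations, annotation,
                                       ratios = ratios)

  corr_counts <- if (!is.null(correlations)) {
    cc <- table(correlations$correlation_class)
    tibble(correlation_class = names(cc), n = as.integer(cc),
           percent = 100 * as.integer(cc) / sum(cc))
  } else tibble(correlation_class = character(), n = integer(),
                percent = numeric())

  report <- list(
    n_genes_loaded = nrow(matrix$values),
    n_genes_expressed = nrow(filtered$values),
    filter_counts = as.list(attr(filtered, "filter_counts")),
    n_snornas_analyzed = length(sno_ids),
    threshold = list(threshold = thr$threshold,
                     tangent_point_x = thr$tangent_point_x,
                     density_at_point = thr$density_at_point,
                     derivative_at_point = thr$derivative_at_point,
                     bandwidth = curve$bandwidth,
                     grid_points = length(curve$grid)),
    n_ue = sum(assignments$abundance_class == "UE"),
    n_te = sum(assignments$abundance_class == "TE"),
    enrichment_tally = as.list(table(
      assignments$enriched_tissues[assignments$abundance_class == "TE"])),
    n_pairs = if (is.null(correlations)) 0L else nrow(correlations),
    n_significant_correlations =
      if (is.null(correlations)) 0L else sum(correlations$significant),
    correlation_class_counts = corr_counts,
    battery = battery,
    assignments = assignments,
    correlations = correlations,
    ratios = ratios
  )
  class(report) <- "snoscape_report"

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(assignments, file.path(config$out_dir, "assignments.tsv"),
                     progress = FALSE)
    if (!is.null(correlations)) {
      readr::write_tsv(correlations,
                       file.path(config$out_dir, "correlations.tsv"),
                       progress = FALSE)
      readr::write_tsv(ratios, file.path(config$out_dir, "ratios.tsv"),
                       progress = FALSE)
    }
    readr::write_tsv(battery, file.path(config$out_dir, "associations.tsv"),
                     progress = FALSE)
    jsonlite::write_json(
      report[c("n_genes_loaded", "n_genes_expressed", "filter_counts",
               "n_snornas_analyzed", "threshold", "n_ue", "n_te",
               "enrichment_tally", "n_pairs",
               "n_significant_correlations")],
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.snoscape_report <- function(x, ...) {
  cat(sprintf(paste0("<snoscape_report> %d genes loaded, %d expressed; ",
                     "%d snoRNAs analyzed\n"),
              x$n_genes_loaded, x$n_genes_expressed, x$n_snornas_analyzed))
  cat(sprintf("  CV threshold %.2f -> %d UE / %d TE\n",
              x$threshold$threshold, x$n_ue, x$n_te))
  cat(sprintf("  %d host pairs, %d significant correlations\n",
              x$n_pairs, x$n_significant_correlations))
  invisible(x)
}

#' Reproduce the classification from a supplementary abundance table
#'
#' Runs the CV / threshold / classification / enrichment stages directly on
#' a wide per-gene supplementary table (one abundance column per tissue),
#' adapting to the export's column names through a column map, and emits a
#' side-by-side comparison against published reference counts. The
#' correlation stage runs only when host abundance columns are mapped;
#' otherwise it is reported as skipped.
#'
#' @param path TSV/CSV export of the supplementary table.
#' @param column_map List with entries `gene_id` (column name), `tissues`
#'   (named character vector mapping tissue name -> abundance column), and
#'   optionally `gene_name`, `host_gene_id` and `host_tissues` (named vector
#'   like `tissues`, host abundance columns).
#' @param config A [default_config()] for the analysis constants.
#' @param reference Named numeric vector of published headline values to
#'   compare against (expressed snoRNAs, UE count, TE count, CV threshold).
#' @return List with `report` (classification outputs), `comparison`
#'   (tibble: quantity, reference, recomputed) and `correlation_status`.
#' @export
reproduce_from_supplementary <- function(path, column_map,
                                         config = default_config(),
                                         reference = c(expressed = 475,
                                                       ue = 390, te = 85,
                                                       threshold = 125)) {
  required <- c("gene_id", "tissues")
  missing <- setdiff(required, names(column_map))
  if (length(missing) > 0) {
    abort(sprintf("column map is missing required field(s): %s",
                  paste(missing, collapse = ", ")))
  }
  delim <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  absent <- setdiff(c(column_map$gene_id, unname(column_map$tissues)),
                    names(tab))
  if (length(absent) > 0) {
    abort(sprintf("mapped column(s) absent from table: %s",
                  paste(absent, collapse = ", ")))
  }
  profile <- as.matrix(tab[, unname(column_map$tissues), drop = FALSE])
  storage.mode(profile) <- "double"
  rownames(profile) <- as.character(tab[[column_map$gene_id]])
  colnames(profile) <- names(column_map$tissues)
  keep <- rowSums(is.na(profile)) == 0 & rowMeans(profile) > 0
  if (any(!keep)) log_stage("reproduce", "genes_dropped", sum(!keep))
  profile <- profile[keep, , drop = FALSE]

  cv_table <- compute_cv(profile, ddof = config$cv_ddof)
  curve <- estimate_density(cv_table$cv,
                            bandwidth_rule = config$kde_bandwidth_rule,
                            grid_points = config$kde_grid_points)
  thr <- steepest_descent_threshold(curve)
  assignments <- classify_abundance(cv_table, thr)
  assignments <- assign_tissue_enrichment(profile, assignments,
                                          joint_pair = config$joint_pair,
                                          joint_fold = config$joint_fold)

  correlation_status <- "skipped: no host abundance columns mapped"
  correlations <- NULL
  if (all(c("host_gene_id", "host_tissues") %in% names(column_map))) {
    host_profile <- as.matrix(tab[keep, unname(column_map$host_tissues),
                                  drop = FALSE])
    storage.mode(host_profile) <- "double"
    host_ids <- as.character(tab[[column_map$host_gene_id]])[keep]
    has_host <- !is.na(host_ids) & host_ids != ""
    r <- vapply(which(has_host), function(i) {
      x <- profile[i, ]
      y <- host_profile[i, ]
      if (sd(x) == 0 || sd(y) == 0 || anyNA(y)) return(NA_real_)
      cor(x, y)
    }, numeric(1))
    correlations <- tibble(sno_gene_id = rownames(profile)[has_host],
                           host_gene_id = host_ids[has_host], r = r,
                           correlation_class = classify_correlation(
                             r, cutoff = config$correlation_cutoff))
    correlation_status <- "ok"
  } else {
    log_stage("reproduce", "correlation_stage_skipped", 1)
  }

  comparison <- tibble(
    quantity = c("expressed", "ue", "te", "threshold"),
    reference = unname(reference[c("expressed", "ue", "te", "threshold")]),
    recomputed = c(nrow(profile),
                   sum(assignments$abundance_class == "UE"),
                   sum(assignments$abundance_class == "TE"),
                   thr$threshold)
  )
  list(report = list(assignments = assignments, threshold = thr,
                     correlations = correlations),
       comparison = comparison,
       correlation_status = correlation_status)
}
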