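# Containers and loading/grouping rules applied before any analysis:
# the gene x sample TPM matrix, the per-gene annotation record, biotype
# grouping, expression filtering, replicate averaging and conservation
# averaging.

#' Construct an abundance matrix
#'
#' Bundles a non-negative gene x sample TPM matrix with the mapping from
#' sample to tissue. This is the container every downstream stage consumes.
#'
#' @param values Numeric matrix of TPM values; rownames are gene identifiers,
#'   colnames are sample identifiers. Must be non-negative with no missing
#'   values (loading via [read_abundance_table()] drops incomplete genes).
#' @param sample_tissue Named character vector mapping every sample id
#'   (names) to a tissue name (values).
#' @return An object of class `abundance_matrix`: a list with elements
#'   `values` and `sample_tissue`.
#' @export
abundance_matrix <- function(values, sample_tissue) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry gene ids as rownames and sample ids as colnames.")
  }
  if (anyDuplicated(rownames(values))) abort("duplicate gene ids in matrix.")
  if (anyDuplicated(colnames(values))) abort("duplicate sample ids in matrix.")
  if (anyNA(values)) abort("missing values in abundance matrix; drop incomplete genes before construction.")
  if (any(values < 0)) abort("negative abundance values are not allowed (TPM).")
  missing_samples <- setdiff(colnames(values), names(sample_tissue))
  if (length(missing_samples) > 0) {
    abort(sprintf("samples absent from sample sheet: %s",
                  paste(missing_samples, collapse = ", ")))
  }
  sample_tissue <- sample_tissue[colnames(values)]
  structure(list(values = values, sample_tissue = sample_tissue),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> %d genes x %d samples, %d tissues\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$sample_tissue))))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Tissues present in an abundance matrix
#' @param x An `abundance_matrix`.
#' @return Character vector of tissue names, in first-appearance order.
#' @export
tissues <- function(x) unique(unname(x$sample_tissue))

#' Read a TPM abundance table and its sample sheet
#'
#' Expects a tab-separated table whose first column holds gene identifiers
#' and remaining columns one sample each, plus a two-column sample sheet
#' (`sample`, `tissue`). Genes with any missing abundance value are dropped
#' (with a warning reporting the count), matching the rule that genes with a
#' missing value in any tissue sample are not considered.
#'
#' @param path Path to the tab-separated abundance table.
#' @param sample_sheet Path to the tab-separated sample sheet.
#' @return An [abundance_matrix()].
#' @export
read_abundance_table <- function(path, sample_sheet) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  sheet <- readr::read_tsv(sample_sheet, show_col_types = FALSE, progress = FALSE)
  if (ncol(sheet) < 2) abort("sample sheet must have two columns: sample, tissue.")
  names(sheet)[1:2] <- c("sample", "tissue")
  if (anyDuplicated(sheet$sample)) abort("duplicate sample ids in sample sheet.")

  gene_ids <- as.character(tab[[1]])
  if (anyDuplicated(gene_ids)) abort("duplicate gene ids in abundance table.")
  values <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- gene_ids

  incomplete <- rowSums(is.na(values)) > 0
  if (any(incomplete)) {
    warn(sprintf("dropping %d gene(s) with missing abundance values.",
                 sum(incomplete)))
    log_stage("load", "genes_dropped_missing", sum(incomplete))
    values <- values[!incomplete, , drop = FALSE]
  }

  st <- setNames(as.character(sheet$tissue), as.character(sheet$sample))
  extra_sheet <- setdiff(names(st), colnames(values))
  if (length(extra_sheet) > 0) {
    warn(sprintf("sample sheet entries absent from matrix ignored: %s",
                 paste(extra_sheet, collapse = ", ")))
    st <- st[setdiff(names(st), extra_sheet)]
  }
  abundance_matrix(values, st)
}

# Ensembl-style biotype groups, per-group membership lists
.biotype_groups <- list(
  `protein-coding` = c("IG_C_gene", "IG_D_gene", "IG_J_gene", "IG_V_gene",
                       "TR_C_gene", "TR_D_gene", "TR_J_gene", "TR_V_gene",
                       "polymorphic_pseudogene", "protein_coding"),
  pseudogene = c("unitary_pseudogene", "unprocessed_pseudogene",
                 "processed_pseudogene", "transcribed_unprocessed_pseudogene",
                 "transcribed_unitary_pseudogene",
                 "transcribed_processed_pseudogene", "IG_pseudogene",
                 "IG_C_pseudogene", "IG_J_pseudogene", "IG_V_pseudogene",
                 "TR_J_pseudogene", "TR_V_pseudogene", "pseudogene"),
  lncRNA = c("3prime_overlapping_ncRNA", "antisense", "lincRNA",
             "macro_lncRNA", "bidirectional_promoter_lncRNA",
             "processed_transcript", "sense_intronic", "sense_overlapping",
             "non_coding", "lncRNA"),
  tRNA = c("Mt_tRNA", "tRNA"),
  snRNA = "snRNA",
  snoRNA = "snoRNA",
  miRNA = "miRNA",
  other = c("rRNA", "Mt_rRNA", "ribozyme", "scRNA", "vaultRNA", "sRNA")
)

#' Sentinel biotype group marking genes excluded from the analysis
#' @export
BIOTYPE_EXCLUDE <- "exclude"

#' Collapse raw Ensembl biotypes into generic groups
#'
#' Maps raw biotype strings onto the generic groups protein-coding,
#' pseudogene, lncRNA, tRNA, snRNA, snoRNA, miRNA and other. The "TEC"
#' biotype maps to the [BIOTYPE_EXCLUDE] sentinel (such genes are removed by
#' [filter_expressed()]); unknown strings map to "other" with a message.
#'
#' @param biotype_raw Character vector of raw biotype strings.
#' @return Character vector of biotype groups (total function, never errors).
#' @export
group_biotype <- function(biotype_raw) {
  biotype_raw <- as.character(biotype_raw)
  lookup <- unlist(lapply(names(.biotype_groups), function(g) {
    setNames(rep(g, length(.biotype_groups[[g]])), .biotype_groups[[g]])
  }))
  out <- unname(lookup[biotype_raw])
  out[biotype_raw == "TEC"] <- BIOTYPE_EXCLUDE
  unknown <- is.na(out) & !is.na(biotype_raw) & biotype_raw != "TEC"
  if (any(unknown)) {
    log_stage("biotype", "unknown_biotypes_mapped_to_other",
              length(unique(biotype_raw[unknown])))
    out[unknown] <- "other"
  }
  out[is.na(biotype_raw)] <- "other"
  out
}

#' Collapse host-gene biotypes into three generic groups
#'
#' Protein-coding raw biotypes map to "protein-coding", an empty/missing host
#' (an independently transcribed, intergenic snoRNA) maps to "intergenic",
#' and everything else to "non-coding".
#'
#' @param host_biotype_raw Character vector; `NA` or `""` means no host gene.
#' @return Character vector in {protein-coding, non-coding, intergenic}.
#' @export
group_host_biotype <- function(host_biotype_raw) {
  host_biotype_raw <- as.character(host_biotype_raw)
  pc <- .biotype_groups[["protein-coding"]]
  dplyr::case_when(
    is.na(host_biotype_raw) | host_biotype_raw == "" ~ "intergenic",
    host_biotype_raw %in% pc ~ "protein-coding",
    TRUE ~ "non-coding"
  )
}

#' Read a gene annotation table
#'
#' Reads a tab-separated annotation table carrying, per gene, the raw
#' biotype, genomic context, host-gene attributes, snoRNA box type and
#' target class, NMD-substrate and promoter-type flags and conservation
#' scores. Missing columns are filled with an explicit unknown state (`NA`);
#' `biotype_group` and `host_biotype_group` are derived from the raw columns
#' when absent.
#'
#' @param path Path to the tab-separated annotation table. Must contain a
#'   `gene_id` column.
#' @return A tibble with the full annotation schema.
#' @export
read_gene_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"gene_id" %in% names(ann)) abort("annotation table must have a gene_id column.")
  if (anyDuplicated(ann$gene_id)) abort("duplicate gene ids in annotation table.")
  complete_annotation(ann)
}

#' Fill in derived/missing annotation columns
#'
#' @param ann A data frame with at least `gene_id`.
#' @return A tibble with the canonical annotation columns present.
#' @export
complete_annotation <- function(ann) {
  ann <- as_tibble(ann)
  chr_cols <- c("gene_name", "biotype_raw", "genomic_context", "host_gene_id",
                "host_biotype_raw", "host_biotype_group", "host_function_group",
                "box_type", "target_class", "promoter_type")
  for (col in chr_cols) {
    if (!col %in% names(ann)) ann[[col]] <- NA_character_
  }
  if (!"nmd_substrate" %in% names(ann)) ann$nmd_substrate <- NA
  for (col in c("conservation_vertebrates", "conservation_primates")) {
    if (!col %in% names(ann)) ann[[col]] <- NA_real_
    bad <- !is.na(ann[[col]]) & (ann[[col]] < 0 | ann[[col]] > 1)
    if (any(bad)) abort(sprintf("%s outside [0,1] for %d gene(s).", col, sum(bad)))
  }
  if (!"biotype_group" %in% names(ann)) {
    ann$biotype_group <- group_biotype(ann$biotype_raw)
  }
  no_group <- is.na(ann$host_biotype_group)
  ann$host_biotype_group[no_group] <- group_host_biotype(ann$host_biotype_raw[no_group])
  ctx_missing <- is.na(ann$genomic_context)
  ann$genomic_context[ctx_missing] <-
    ifelse(is.na(ann$host_gene_id[ctx_missing]) | ann$host_gene_id[ctx_missing] == "",
           "intergenic", "intronic")
  ann$host_gene_id[!is.na(ann$host_gene_id) & ann$host_gene_id == ""] <- NA_character_
  ann
}

#' Filter an abundance matrix to expressed, analyzable genes
#'
#' Retains genes whose maximum per-sample abundance strictly exceeds
#' `threshold_tpm` (the "greater than 1 TPM in at least one tissue sample"
#' rule, interpreted per sample), removes genes whose biotype collapses to
#' the exclusion sentinel ("TEC"), and removes snoRNA-biotype genes whose
#' gene name starts with an excluded prefix (by default `SCARNA`, the
#' manually excluded small Cajal-body RNAs). Removal counts per rule are
#' logged and attached as the `filter_counts` attribute.
#'
#' @param matrix An [abundance_matrix()].
#' @param annotation Annotation tibble (see [read_gene_annotation()]), or
#'   `NULL`. Genes absent from the annotation are retained and counted.
#' @param threshold_tpm Positive expression threshold in TPM (default 1).
#' @param exclude_name_prefixes Character vector of gene-name prefixes whose
#'   snoRNA-biotype carriers are removed (default `"SCARNA"`).
#' @return A filtered `abundance_matrix` with attribute `filter_counts`.
#' @export
filter_expressed <- function(matrix, annotation = NULL, threshold_tpm = 1,
                             exclude_name_prefixes = "SCARNA") {
  stopifnot(inherits(matrix, "abundance_matrix"))
  if (!is.numeric(threshold_tpm) || threshold_tpm <= 0) {
    abort("`threshold_tpm` must be a positive number.")
  }
  v <- matrix$values
  keep_expr <- apply(v, 1, max) > threshold_tpm

  drop_biotype <- rep(FALSE, nrow(v))
  drop_prefix <- rep(FALSE, nrow(v))
  n_unannotated <- 0L
  if (!is.null(annotation)) {
    annotation <- complete_annotation(annotation)
    idx <- match(rownames(v), annotation$gene_id)
    n_unannotated <- sum(is.na(idx))
    grp <- annotation$biotype_group[idx]
    nm <- annotation$gene_name[idx]
    drop_biotype <- !is.na(grp) & grp == BIOTYPE_EXCLUDE
    if (length(exclude_name_prefixes) > 0) {
      is_sno <- !is.na(grp) & grp == "snoRNA" & !is.na(nm)
      hit <- Reduce(`|`, lapply(exclude_name_prefixes, function(p) {
        is_sno & startsWith(nm, p)
      }), init = rep(FALSE, nrow(v)))
      drop_prefix <- hit
    }
  }

  keep <- keep_expr & !drop_biotype & !drop_prefix
  counts <- c(
    low_abundance = sum(!keep_expr),
    excluded_biotype = sum(drop_biotype & keep_expr),
    name_prefix = sum(drop_prefix & keep_expr & !drop_biotype),
    unannotated_kept = n_unannotated
  )
  log_stage("filter", "removed_low_abundance", counts[["low_abundance"]])
  log_stage("filter", "removed_excluded_biotype", counts[["excluded_biotype"]])
  log_stage("filter", "removed_name_prefix", counts[["name_prefix"]])
  out <- abundance_matrix(v[keep, , drop = FALSE], matrix$sample_tissue)
  attr(out, "filter_counts") <- counts
  out
}

#' Average replicate samples into per-tissue mean profiles
#'
#' @param matrix An [abundance_matrix()].
#' @return A numeric gene x tissue matrix of arithmetic replicate means
#'   (a "tissue profile"); tissue order follows first appearance in the
#'   sample sheet.
#' @export
tissue_means <- function(matrix) {
  stopifnot(inherits(matrix, "abundance_matrix"))
  tiss <- tissues(matrix)
  out <- vapply(tiss, function(tt) {
    cols <- names(matrix$sample_tissue)[matrix$sample_tissue == tt]
    rowMeans(matrix$values[, cols, drop = FALSE])
  }, numeric(nrow(matrix$values)))
  if (nrow(matrix$values) == 1L) {
    out <- base::matrix(out, nrow = 1, dimnames = list(rownames(matrix$values), tiss))
  }
  out
}

#' Per-gene conservation score from per-nucleotide scores
#'
#' The per-gene phastCons-style conservation score is the arithmetic mean of
#' the per-nucleotide scores over the gene body.
#'
#' @param per_base_scores Non-empty numeric vector of scores in \[0, 1\].
#' @return The mean score.
#' @export
mean_conservation <- function(per_base_scores) {
  if (length(per_base_scores) == 0) abort("empty conservation score vector.")
  if (anyNA(per_base_scores)) abort("missing values in conservation scores.")
  if (any(per_base_scores < 0 | per_base_scores > 1)) {
    abort("conservation scores must lie in [0, 1].")
  }
  mean(per_base_scores)
}

#' Per-tissue abundance share of each biotype group
#'
#' For every tissue, sums the tissue-mean TPM per biotype group and reports
#' each group's fraction of the non-excluded total (fractions sum to 1 per
#' tissue). Apply [filter_expressed()] first.
#'
#' @param matrix A filtered [abundance_matrix()].
#' @param annotation Annotation tibble covering the matrix genes.
#' @return Tibble with columns tissue, biotype_group, total_tpm, fraction.
#' @export
biotype_abundance_breakdown <- function(matrix, annotation) {
  prof <- tissue_means(matrix)
  annotation <- complete_annotation(annotation)
  grp <- annotation$biotype_group[match(rownames(prof), annotation$gene_id)]
  grp[is.na(grp)] <- "other"
  df <- as_tibble(prof)
  df$biotype_group <- grp
  df |>
    tidyr::pivot_longer(-"biotype_group", names_to = "tissue",
                        values_to = "tpm") |>
    dplyr::group_by(.data$tissue, .data$biotype_group) |>
    dplyr::summarise(total_tpm = sum(.data$tpm), .groups = "drop_last") |>
    dplyr::mutate(fraction = .data$total_tpm / sum(.data$total_tpm)) |>
    dplyr::ungroup()
}
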