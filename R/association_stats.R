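# Categorical and rank tests linking abundance classes and correlation
# classes to snoRNA / host-gene annotations: Fisher's exact test (2x2 and
# 2xk), Mann-Whitney U, and the full association battery.

association_result <- function(test_id, description, test_type,
                               statistic_name, statistic, p_value, n,
                               status = "ok", note = "") {
  tibble(test_id = test_id, description = description, test_type = test_type,
         statistic_name = statistic_name, statistic = statistic,
         p_value = p_value, stars = stars_for_p(p_value), n = n,
         status = status, note = note)
}

check_count_table <- function(tab) {
  if (!is.matrix(tab)) tab <- as.matrix(tab)
  storage.mode(tab) <- "double"
  if (anyNA(tab) || any(tab < 0)) abort("contingency table must be non-negative.")
  if (any(tab != round(tab))) abort("contingency table counts must be integers.")
  tab
}

#' Fisher's exact test on a 2x2 contingency table
#'
#' Two-sided exact p value (sum of hypergeometric probabilities no larger
#' than that of the observed table, the usual probability-ordering rule).
#' The reported odds ratio is the sample cross-product ratio `ad / bc`
#' (convention: `Inf` when `bc = 0` with `ad > 0`, `0` when `ad = 0` with
#' `bc > 0`, `NaN` when both products vanish).
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param description Optional label carried into the result.
#' @return One-row tibble (an association result) with the odds ratio and
#'   two-sided p value.
#' @export
fisher_exact_2x2 <- function(table, description = "2x2 association") {
  tab <- check_count_table(table)
  if (!all(dim(tab) == c(2, 2))) abort("expected a 2x2 table.")
  p <- fisher.test(tab)$p.value
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  association_result("fisher_2x2", description, "fisher_exact",
                     "odds_ratio", or, p, sum(tab))
}

#' Fisher's exact test on a 2xk contingency table
#'
#' Exact conditional p value over all tables with the observed margins,
#' two-sided by probability ordering. Enumeration is practical only for
#' small tables: at most 4 columns and a grand total of at most 500
#' (collapse categories otherwise).
#'
#' @param table 2xk matrix of non-negative integer counts, k <= 4.
#' @param description Optional label carried into the result.
#' @return One-row tibble (an association result); no odds ratio is defined
#'   beyond 2x2, so the statistic is `NA`.
#' @export
fisher_exact_2xk <- function(table, description = "2xk association") {
  tab <- check_count_table(table)
  if (nrow(tab) != 2) abort("expected a table with 2 rows.")
  if (ncol(tab) > 4) abort("at most 4 columns supported; collapse categories.")
  if (sum(tab) > 500) {
    abort("table total exceeds 500; collapse categories for exact enumeration.")
  }
  p <- fisher.test(tab, workspace = 2e7)$p.value
  association_result("fisher_2xk", description, "fisher_exact",
                     "odds_ratio", NA_real_, p, sum(tab))
}

#' Mann-Whitney U test for two groups
#'
#' Two-sided rank-sum comparison. The exact null distribution is used when
#' both groups have at most 20 observations and there are no ties; a
#' tie-corrected normal approximation (with continuity correction)
#' otherwise. If every value in both groups is identical, p = 1 is returned
#' with a warning.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param description Optional label carried into the result.
#' @return One-row tibble (an association result) with the U statistic for
#'   `x` relative to `y` and the two-sided p value.
#' @export
mann_whitney_u <- function(x, y, description = "two-group comparison") {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) abort("both groups must be non-empty.")
  n <- length(x) + length(y)
  if (length(unique(c(x, y))) == 1L) {
    warn("all values identical across both groups; p = 1.")
    return(association_result("mann_whitney", description, "mann_whitney_u",
                              "U", length(x) * length(y) / 2, 1, n))
  }
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- length(x) <= 20 && length(y) <= 20 && !has_ties
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE))
  association_result("mann_whitney", description, "mann_whitney_u",
                     "U", unname(wt$statistic), wt$p.value, n)
}

skipped_result <- function(test_id, description, test_type, note) {
  association_result(test_id, description, test_type, NA_character_,
                     NA_real_, NA_real_, 0L, status = "skipped", note = note)
}

# run one battery entry; insufficient / degenerate data become a skipped row
run_battery_test <- function(test_id, description, test_type, expr) {
  out <- tryCatch(expr, error = function(e) conditionMessage(e))
  if (is.character(out)) {
    log_stage("battery", paste0("skipped_", test_id), 1)
    return(skipped_result(test_id, description, test_type, out))
  }
  out$test_id <- test_id
  out$description <- description
  out
}

two_way_counts <- function(a, b, a_levels = NULL, b_levels = NULL) {
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  if (!is.null(a_levels)) { keep2 <- a %in% a_levels; a <- a[keep2]; b <- b[keep2] }
  if (!is.null(b_levels)) { keep3 <- b %in% b_levels; a <- a[keep3]; b <- b[keep3] }
  if (length(a) == 0) abort("no pairwise-complete observations.")
  a_levels <- if (is.null(a_levels)) sort(unique(a)) else a_levels
  b_levels <- if (is.null(b_levels)) sort(unique(b)) else b_levels
  tab <- table(factor(a, levels = a_levels), factor(b, levels = b_levels))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) abort("fewer than two non-empty levels on a margin.")
  unclass(tab)
}

fisher_auto <- function(tab, description) {
  if (ncol(tab) == 2 && nrow(tab) == 2) fisher_exact_2x2(tab, description)
  else {
    if (nrow(tab) > 2 && ncol(tab) == 2) tab <- t(tab)
    fisher_exact_2xk(tab, description)
  }
}

#' Battery of class-annotation association tests
#'
#' Runs, with pairwise-complete data, the standard set of comparisons
#' between the abundance classes (UE/TE), the host-correlation classes and
#' the per-gene annotations: box type, target class and host biotype versus
#' abundance class; conservation (vertebrates and primates) between
#' abundance classes and between correlation classes; the NMD flag versus
#' correlation class within each host-biotype group; host function group
#' versus correlation sign for protein-coding hosts; promoter type versus
#' correlation class and abundance class; the NMD flag versus promoter
#' type; and, when ratios are supplied, the log2 snoRNA/host ratio between
#' correlation classes. Tests whose stratum is empty or single-level are
#' reported with status `"skipped"` and the reason, never dropped silently.
#'
#' @param assignments Tibble from [assign_tissue_enrichment()] /
#'   [classify_abundance()].
#' @param correlations Tibble from [finalize_correlations()], or `NULL` to
#'   skip correlation-based tests.
#' @param annotation Annotation tibble covering the assigned genes.
#' @param ratios Optional tibble from [abundance_ratio()].
#' @return Tibble of association results, one row per battery entry,
#'   deterministic given identical inputs.
#' @export
class_association_battery <- function(assignments, correlations = NULL,
                                      annotation, ratios = NULL) {
  annotation <- complete_annotation(annotation)
  d <- dplyr::left_join(assignments, annotation, by = "gene_id")
  d <- dplyr::filter(d, is.na(.data$biotype_group) | .data$biotype_group == "snoRNA")

  cd <- NULL
  if (!is.null(correlations)) {
    cd <- correlations |>
      dplyr::left_join(dplyr::select(annotation, "gene_id",
                                     "host_biotype_group",
                                     "host_function_group", "nmd_substrate",
                                     "promoter_type",
                                     "conservation_vertebrates"),
                       by = c(sno_gene_id = "gene_id")) |>
      dplyr::left_join(dplyr::select(assignments, "gene_id", "abundance_class"),
                       by = c(sno_gene_id = "gene_id"))
  }

  res <- list()
  res$box <- run_battery_test(
    "box_type_x_class", "box type (C/D vs H/ACA) x abundance class",
    "fisher_exact",
    fisher_auto(two_way_counts(d$box_type, d$abundance_class,
                               a_levels = c("CD", "HACA"),
                               b_levels = c("UE", "TE")), ""))
  res$target <- run_battery_test(
    "target_x_class", "target class (rRNA/snRNA/orphan) x abundance class",
    "fisher_exact",
    fisher_auto(two_way_counts(d$abundance_class, d$target_class,
                               a_levels = c("UE", "TE"),
                               b_levels = c("rRNA", "snRNA", "orphan")), ""))
  res$hostbio <- run_battery_test(
    "host_biotype_x_class", "host biotype group x abundance class",
    "fisher_exact",
    fisher_auto(two_way_counts(d$abundance_class, d$host_biotype_group,
                               a_levels = c("UE", "TE"),
                               b_levels = c("protein-coding", "non-coding",
                                            "intergenic")), ""))
  res$cons_vert <- run_battery_test(
    "conservation_vert_x_class",
    "vertebrate conservation between abundance classes", "mann_whitney_u",
    mann_whitney_u(d$conservation_vertebrates[d$abundance_class == "UE"],
                   d$conservation_vertebrates[d$abundance_class == "TE"], ""))
  res$cons_prim <- run_battery_test(
    "conservation_prim_x_class",
    "primate conservation between abundance classes", "mann_whitney_u",
    mann_whitney_u(d$conservation_primates[d$abundance_class == "UE"],
                   d$conservation_primates[d$abundance_class == "TE"], ""))

  if (!is.null(cd)) {
    for (hb in c("protein-coding", "non-coding")) {
      id <- paste0("nmd_x_corr_", sub("-.*", "", hb))
      sub_d <- cd[!is.na(cd$host_biotype_group) & cd$host_biotype_group == hb, ]
      res[[id]] <- run_battery_test(
        id, sprintf("NMD substrate x correlation class (%s hosts)", hb),
        "fisher_exact",
        fisher_auto(two_way_counts(as.character(sub_d$nmd_substrate),
                                   sub_d$correlation_class,
                                   b_levels = c("anticorrelated",
                                                "non-correlated",
                                                "positive")), ""))
    }
    res$hostfun <- run_battery_test(
      "host_function_x_corr_sign",
      "host function group x correlation sign (protein-coding hosts)",
      "fisher_exact",
      {
        sub_d <- cd[!is.na(cd$host_biotype_group) &
                      cd$host_biotype_group == "protein-coding", ]
        fisher_auto(two_way_counts(
          sub_d$correlation_class, sub_d$host_function_group,
          a_levels = c("anticorrelated", "positive"),
          b_levels = c("ribosomal protein",
                       "RNA processing / ribosome biogenesis", "other")), "")
      })
    res$prom_corr <- run_battery_test(
      "promoter_x_corr", "promoter type (DI/SI) x correlation class",
      "fisher_exact",
      fisher_auto(two_way_counts(cd$promoter_type, cd$correlation_class,
                                 a_levels = c("DI", "SI"),
                                 b_levels = c("anticorrelated",
                                              "non-correlated",
                                              "positive")), ""))
    res$cons_corr <- run_battery_test(
      "conservation_x_corr",
      "vertebrate conservation: positive vs non/anticorrelated pairs",
      "mann_whitney_u",
      mann_whitney_u(
        cd$conservation_vertebrates[!is.na(cd$correlation_class) &
                                      cd$correlation_class == "positive"],
        cd$conservation_vertebrates[!is.na(cd$correlation_class) &
                                      cd$correlation_class != "positive"], ""))
  }
  res$prom_class <- run_battery_test(
    "promoter_x_class", "promoter type (DI/SI) x abundance class",
    "fisher_exact",
    fisher_auto(two_way_counts(d$promoter_type, d$abundance_class,
                               a_levels = c("DI", "SI"),
                               b_levels = c("UE", "TE")), ""))
  res$nmd_prom <- run_battery_test(
    "nmd_x_promoter", "NMD substrate x promoter type",
    "fisher_exact",
    fisher_auto(two_way_counts(as.character(d$nmd_substrate), d$promoter_type,
                               b_levels = c("DI", "SI")), ""))

  if (!is.null(ratios) && !is.null(cd)) {
    res$ratio <- run_battery_test(
      "log_ratio_x_corr",
      "log2 sno/host ratio: positive vs non/anticorrelated pairs",
      "mann_whitney_u",
      {
        per_pair <- ratios |>
          dplyr::group_by(.data$sno_gene_id) |>
          dplyr::summarise(mean_ratio = mean(.data$log2_ratio), .groups = "drop") |>
          dplyr::left_join(dplyr::select(cd, "sno_gene_id", "correlation_class"),
                           by = "sno_gene_id")
        mann_whitney_u(
          per_pair$mean_ratio[!is.na(per_pair$correlation_class) &
                                per_pair$correlation_class == "positive"],
          per_pair$mean_ratio[!is.na(per_pair$correlation_class) &
                                per_pair$correlation_class != "positive"], "")
      })
  }
  dplyr::bind_rows(res)
}
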