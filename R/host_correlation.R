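# snoRNA / host-gene correlation: pairing of intron-embedded snoRNAs with
# their hosts, Pearson correlation with BH-adjusted p values, correlation
# classes at the +/- 0.25 cut-offs, and log2 snoRNA-to-host abundance ratios.

#' Pair intron-embedded snoRNAs with their host genes
#'
#' One pair per intron-embedded, expressed snoRNA; intergenic snoRNAs carry
#' no pair and are tallied. Two snoRNAs hosted by the same gene yield two
#' pairs. The annotation's `host_gene_id` is authoritative.
#'
#' @param annotation Annotation tibble (see [read_gene_annotation()]).
#' @param matrix Optional [abundance_matrix()]; pairs whose host is absent
#'   from the matrix are dropped with a warning.
#' @return Tibble sno_gene_id, host_gene_id, with attribute
#'   `n_intergenic`.
#' @export
pair_snorna_host <- function(annotation, matrix = NULL) {
  annotation <- complete_annotation(annotation)
  sno <- dplyr::filter(annotation, .data$biotype_group == "snoRNA")
  intergenic <- is.na(sno$host_gene_id)
  log_stage("pairing", "intergenic_snornas_excluded", sum(intergenic))
  pairs <- tibble(sno_gene_id = sno$gene_id[!intergenic],
                  host_gene_id = sno$host_gene_id[!intergenic])
  if (!is.null(matrix)) {
    absent <- !(pairs$host_gene_id %in% rownames(matrix$values))
    if (any(absent)) {
      warn(sprintf("dropping %d pair(s) whose host gene is absent from the matrix.",
                   sum(absent)))
      pairs <- pairs[!absent, , drop = FALSE]
    }
  }
  attr(pairs, "n_intergenic") <- sum(intergenic)
  pairs
}

#' Pearson correlation of snoRNA and host-gene abundance
#'
#' Computes Pearson's r and its two-sided p value for every pair, across
#' either the individual samples (default; all replicates as observations)
#' or the per-tissue means. Pairs with zero variance in either series get
#' `r = NA` and status `"degenerate"`; they are excluded from the FDR family
#' by [finalize_correlations()].
#'
#' @param pairs Tibble from [pair_snorna_host()].
#' @param matrix An [abundance_matrix()] containing both genes of each pair.
#' @param level `"samples"` (default) or `"tissue-means"`.
#' @param transform `"linear"` (default; Pearson on TPM) or `"log2"`
#'   (Pearson on `log2(TPM + pseudocount)`).
#' @param pseudocount Pseudocount for the log2 transform (default 1).
#' @return Tibble sno_gene_id, host_gene_id, r, p_raw, n_obs, status.
#' @export
correlate_pairs <- function(pairs, matrix,
                            level = c("samples", "tissue-means"),
                            transform = c("linear", "log2"),
                            pseudocount = 1) {
  level <- match.arg(level)
  transform <- match.arg(transform)
  obs <- switch(level,
                samples = matrix$values,
                `tissue-means` = tissue_means(matrix))
  if (transform == "log2") {
    if (pseudocount <= 0) abort("`pseudocount` must be positive.")
    obs <- log2(obs + pseudocount)
  }
  if (ncol(obs) < 3) abort("at least 3 observations are required for correlation.")
  missing <- setdiff(unique(c(pairs$sno_gene_id, pairs$host_gene_id)),
                     rownames(obs))
  if (length(missing) > 0) {
    abort(sprintf("gene(s) absent from matrix: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- obs[pairs$sno_gene_id[i], ]
    y <- obs[pairs$host_gene_id[i], ]
    if (sd(x) == 0 || sd(y) == 0) {
      return(tibble(r = NA_real_, p_raw = NA_real_, n_obs = length(x),
                    status = "degenerate"))
    }
    ct <- cor.test(x, y, method = "pearson")
    # a perfect fit gives p = 0 exactly; clamp into (0, 1] for the BH step
    tibble(r = unname(ct$estimate),
           p_raw = max(ct$p.value, .Machine$double.xmin),
           n_obs = length(x), status = "ok")
  })
  out <- dplyr::bind_cols(pairs, dplyr::bind_rows(res))
  n_deg <- sum(out$status == "degenerate")
  if (n_deg > 0) log_stage("correlation", "degenerate_pairs_flagged", n_deg)
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard BH step-up applied to one family of raw p values, returned in
#' input order and capped at 1.
#'
#' @param p_values Numeric vector of p values in (0, 1\].
#' @return Vector of q values, `q >= p` elementwise.
#' @export
adjust_fdr <- function(p_values) {
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1)) {
    abort("p values must lie in (0, 1] with no missing values.")
  }
  p.adjust(p_values, method = "BH")
}

#' Correlation class from Pearson's r
#'
#' `r < -0.25` is anticorrelated, `r > 0.25` positive, and the inclusive
#' middle band non-correlated; the three classes partition \[-1, 1\].
#'
#' @param r Numeric vector of Pearson coefficients in \[-1, 1\].
#' @param cutoff Positive band half-width (default 0.25).
#' @return Character vector in {anticorrelated, non-correlated, positive}.
#' @export
classify_correlation <- function(r, cutoff = 0.25) {
  if (cutoff <= 0) abort("`cutoff` must be positive.")
  if (any(abs(r) > 1, na.rm = TRUE)) abort("Pearson's r must lie in [-1, 1].")
  dplyr::case_when(
    is.na(r) ~ NA_character_,
    r < -cutoff ~ "anticorrelated",
    r > cutoff ~ "positive",
    TRUE ~ "non-correlated"
  )
}

#' Attach q values, correlation classes and significance calls
#'
#' The FDR family is the set of pairs with a defined r in one run;
#' degenerate records keep `NA` q and class.
#'
#' @param records Tibble from [correlate_pairs()].
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @param cutoff Correlation-class cut-off (default 0.25).
#' @return `records` plus columns q, correlation_class, significant.
#' @export
finalize_correlations <- function(records, alpha = 0.05, cutoff = 0.25) {
  ok <- records$status == "ok"
  records$q <- NA_real_
  records$q[ok] <- adjust_fdr(records$p_raw[ok])
  records$correlation_class <- classify_correlation(records$r, cutoff = cutoff)
  records$significant <- !is.na(records$q) & records$q < alpha
  records
}

#' Log2 snoRNA-to-host abundance ratios per tissue
#'
#' @param pairs Tibble from [pair_snorna_host()].
#' @param profile Gene x tissue matrix of means (see [tissue_means()]).
#' @param pseudocount Positive pseudocount (default 1 TPM).
#' @return Tibble sno_gene_id, host_gene_id, tissue, log2_ratio, where
#'   `log2_ratio = log2((sno + pc) / (host + pc))`.
#' @export
abundance_ratio <- function(pairs, profile, pseudocount = 1) {
  if (pseudocount <= 0) abort("`pseudocount` must be positive.")
  stopifnot(is.matrix(profile))
  tiss <- colnames(profile)
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    s <- profile[pairs$sno_gene_id[i], ]
    h <- profile[pairs$host_gene_id[i], ]
    tibble(sno_gene_id = pairs$sno_gene_id[i],
           host_gene_id = pairs$host_gene_id[i],
           tissue = tiss,
           log2_ratio = unname(log2((s + pseudocount) / (h + pseudocount))))
  })
  dplyr::bind_rows(out)
}
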