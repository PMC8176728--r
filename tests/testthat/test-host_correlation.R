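test_that("snoRNA/host pairing excludes intergenic genes and keeps shared hosts", {
  ann <- tibble::tibble(
    gene_id = c("S1", "S2", "S3", "S4"),
    biotype_raw = "snoRNA",
    host_gene_id = c("H1", "H1", NA, "H9")
  )
  pairs <- suppressMessages(pair_snorna_host(ann))
  expect_equal(nrow(pairs), 3)           # two snoRNAs sharing H1 -> two pairs
  expect_equal(attr(pairs, "n_intergenic"), 1)
  # hosts absent from the matrix are dropped with a warning
  v <- matrix(runif(4 * 6, 1, 10), 4,
              dimnames = list(c("S1", "S2", "S3", "H1"), paste0("s", 1:6)))
  m <- abundance_matrix(v, setNames(rep(c("a", "b"), each = 3), paste0("s", 1:6)))
  expect_warning(pairs2 <- suppressMessages(pair_snorna_host(ann, m)),
                 "absent from the matrix")
  expect_equal(pairs2$sno_gene_id, c("S1", "S2"))
})

test_that("Pearson correlation matches hand-computed values", {
  v <- rbind(sno = c(1, 2, 3, 4, 5, 6),
             double = c(2, 4, 6, 8, 10, 12),
             flip = c(99, 98, 97, 96, 95, 94),
             shuffle = c(2, 1, 4, 3, 6, 5),
             flat = rep(3, 6))
  colnames(v) <- paste0("s", 1:6)
  m <- abundance_matrix(v, setNames(rep(c("a", "b"), each = 3), colnames(v)))
  pairs <- tibble::tibble(sno_gene_id = "sno",
                          host_gene_id = c("double", "flip", "shuffle", "flat"))
  rec <- suppressMessages(correlate_pairs(pairs, m))
  expect_equal(rec$r[1], 1)
  expect_equal(rec$r[2], -1)
  # hand arithmetic: cross-products 14.5, both sums of squares 17.5
  expect_equal(rec$r[3], 14.5 / 17.5, tolerance = 1e-6)
  expect_equal(rec$status[4], "degenerate")
  expect_true(is.na(rec$r[4]))
  fin <- finalize_correlations(rec)
  expect_true(is.na(fin$q[4]))           # degenerate excluded from FDR family
  expect_equal(sum(!is.na(fin$q)), 3)
})

test_that("BH adjustment follows the step-up rule and matches brute force", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.37), 0.37)
  set.seed(9)
  for (i in 1:25) {
    p <- runif(sample(1:40, 1))
    q <- adjust_fdr(p)
    expect_equal(q, bh_oracle(p))
    expect_true(all(q >= p))
  }
  expect_error(adjust_fdr(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("correlation classes partition [-1, 1] at the +/-0.25 cut-offs", {
  expect_equal(classify_correlation(c(0.30, -0.25, 0, 0.25, -0.26, 1, -1)),
               c("positive", "non-correlated", "non-correlated",
                 "non-correlated", "anticorrelated", "positive",
                 "anticorrelated"))
  set.seed(2)
  r <- runif(500, -1, 1)
  cls <- classify_correlation(r)
  expect_true(all(cls %in% c("anticorrelated", "non-correlated", "positive")))
  expect_equal(cls == "anticorrelated", r < -0.25)
  expect_equal(cls == "positive", r > 0.25)
  expect_error(classify_correlation(1.5), "\\[-1, 1\\]")
})

test_that("log2 abundance ratios are exact and antisymmetric", {
  prof <- matrix(c(31, 3, 7, 3), 2, byrow = TRUE,
                 dimnames = list(c("sno", "host"), c("t1", "t2")))
  pairs <- tibble::tibble(sno_gene_id = "sno", host_gene_id = "host")
  rr <- abundance_ratio(pairs, prof, pseudocount = 1)
  expect_equal(rr$log2_ratio[rr$tissue == "t1"], 2)   # log2(32/8)
  expect_equal(rr$log2_ratio[rr$tissue == "t2"], 0)
  swapped <- abundance_ratio(
    tibble::tibble(sno_gene_id = "host", host_gene_id = "sno"), prof)
  expect_equal(swapped$log2_ratio, -rr$log2_ratio)
  expect_error(abundance_ratio(pairs, prof, pseudocount = 0), "positive")
})

test_that("planted correlations are recovered on the log2 scale", {
  by_cell <- list()
  for (s in 1:3) {
    sim <- simulate_cohort(sim_params(seed = 500 + s))
    pairs <- suppressMessages(pair_snorna_host(sim$annotation, sim$matrix))
    rec <- suppressMessages(correlate_pairs(pairs, sim$matrix,
                                            transform = "log2"))
    rec$rho <- sim$truth$planted_rho[match(rec$sno_gene_id,
                                           sim$truth$gene_id)]
    by_cell[[s]] <- tapply(rec$r, rec$rho, mean)
  }
  means <- Reduce(`+`, by_cell) / length(by_cell)
  expect_lt(abs(means[["-0.6"]] - (-0.6)), 0.05)
  expect_lt(abs(means[["0"]] - 0), 0.05)
  expect_lt(abs(means[["0.7"]] - 0.7), 0.05)
})

test_that("BH keeps the null discovery fraction controlled", {
  fracs <- vapply(1:5, function(s) {
    set.seed(600 + s)
    n <- 200
    x <- matrix(rnorm(n * 21), n)
    y <- matrix(rnorm(n * 21), n)
    p <- vapply(seq_len(n), function(i) cor.test(x[i, ], y[i, ])$p.value,
                numeric(1))
    mean(adjust_fdr(p) < 0.05)
  }, numeric(1))
  expect_lte(mean(fracs), 0.05 + 2 * sd(fracs) + 1e-12)
})
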