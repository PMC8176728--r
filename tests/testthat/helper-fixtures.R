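# Small in-code fixtures shared across test files.

# 3-gene x 6-sample matrix over two tissues
make_tiny_matrix <- function() {
  v <- matrix(c(2, 4, 6, 10, 12, 14,
                1, 1, 1, 1, 1, 1,
                0, 0, 1.2, 5, 8, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("G1", "G2", "G3"),
                              c("b1", "b2", "b3", "l1", "l2", "l3")))
  abundance_matrix(v, setNames(rep(c("brain", "liver"), each = 3),
                               colnames(v)))
}

write_tiny_files <- function(dir, with_na = FALSE) {
  m <- make_tiny_matrix()
  tab <- tibble::as_tibble(m$values, rownames = "gene_id")
  if (with_na) tab[2, 3] <- NA
  ab <- file.path(dir, "abundance.tsv")
  ss <- file.path(dir, "samples.tsv")
  readr::write_tsv(tab, ab)
  readr::write_tsv(tibble::tibble(sample = names(m$sample_tissue),
                                  tissue = unname(m$sample_tissue)), ss)
  list(abundance = ab, samples = ss)
}

make_tiny_annotation <- function() {
  tibble::tibble(
    gene_id = c("G1", "G2", "G3"),
    gene_name = c("SNORD1", "SCARNA5", "ACT1"),
    biotype_raw = c("snoRNA", "snoRNA", "protein_coding"),
    host_gene_id = c("G3", NA, NA)
  )
}

# independent enumeration oracle for the two-sided Fisher 2x2 p value:
# sum of probabilities (computed from binomial coefficients directly) of
# all tables with the observed margins that are no more probable than the
# observed one (relative tolerance for float ties, as in the standard rule)
fisher2x2_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_vals <- max(0, c1 - r2):min(r1, c1)
  prob <- vapply(a_vals, function(a) {
    exp(lchoose(r1, a) + lchoose(r2, c1 - a) - lchoose(n, c1))
  }, numeric(1))
  p_obs <- prob[a_vals == tab[1, 1]]
  sum(prob[prob <= p_obs * (1 + 1e-7)])
}

# complete margin-preserving enumeration oracle for 2x3 tables,
# probability-ordered two-sided rule
fisher2x3_oracle <- function(tab) {
  r1 <- sum(tab[1, ]); cs <- colSums(tab); n <- sum(tab)
  logp <- function(a, b, c) {
    lchoose(cs[1], a) + lchoose(cs[2], b) + lchoose(cs[3], c) -
      lchoose(n, r1)
  }
  probs <- c()
  for (a in 0:min(cs[1], r1)) {
    for (b in 0:min(cs[2], r1 - a)) {
      c <- r1 - a - b
      if (c >= 0 && c <= cs[3]) probs <- c(probs, exp(logp(a, b, c)))
    }
  }
  p_obs <- exp(logp(tab[1, 1], tab[1, 2], tab[1, 3]))
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force Benjamini-Hochberg: q_(i) = min_{j>=i} p_(j)*m/j, input order
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(pmin(ps[i:m] * m / (i:m), 1))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# exhaustive permutation oracle for the exact two-sided Mann-Whitney test
mwu_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  lo <- mean(u_all <= u_obs)
  hi <- mean(u_all >= u_obs)
  min(1, 2 * min(lo, hi))
}
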