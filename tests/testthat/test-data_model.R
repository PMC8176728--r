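test_that("abundance tables round-trip through files with their sample sheet", {
  dir <- withr::local_tempdir()
  paths <- write_tiny_files(dir)
  m <- read_abundance_table(paths$abundance, paths$samples)
  expect_s3_class(m, "abundance_matrix")
  expect_equal(dim(m), c(3L, 6L))
  expect_equal(tissues(m), c("brain", "liver"))
  expect_equal(m$values, make_tiny_matrix()$values)
})

test_that("genes with missing values are dropped with a warning", {
  dir <- withr::local_tempdir()
  paths <- write_tiny_files(dir, with_na = TRUE)
  expect_warning(m <- read_abundance_table(paths$abundance, paths$samples),
                 "missing abundance")
  expect_equal(rownames(m$values), c("G1", "G3"))
})

test_that("loader enforces the matrix/sheet contract", {
  dir <- withr::local_tempdir()
  paths <- write_tiny_files(dir)
  # sample present in matrix but absent from sheet is a hard error
  sheet <- readr::read_tsv(paths$samples, show_col_types = FALSE)
  readr::write_tsv(sheet[sheet$sample != "b2", ], paths$samples)
  expect_error(read_abundance_table(paths$abundance, paths$samples),
               "absent from sample sheet")
  # duplicate gene ids are a hard error
  paths <- write_tiny_files(dir)
  tab <- readr::read_tsv(paths$abundance, show_col_types = FALSE)
  readr::write_tsv(rbind(tab, tab[1, ]), paths$abundance)
  expect_error(read_abundance_table(paths$abundance, paths$samples),
               "duplicate gene ids")
  expect_error(abundance_matrix(matrix(-1, 1, 1, dimnames = list("g", "s")),
                                c(s = "t")),
               "negative")
})

test_that("raw biotypes collapse onto their generic groups (table-driven)", {
  cases <- c(
    IG_C_gene = "protein-coding", IG_D_gene = "protein-coding",
    IG_J_gene = "protein-coding", IG_V_gene = "protein-coding",
    TR_C_gene = "protein-coding", TR_D_gene = "protein-coding",
    TR_J_gene = "protein-coding", TR_V_gene = "protein-coding",
    polymorphic_pseudogene = "protein-coding", protein_coding = "protein-coding",
    unitary_pseudogene = "pseudogene", unprocessed_pseudogene = "pseudogene",
    processed_pseudogene = "pseudogene",
    transcribed_unprocessed_pseudogene = "pseudogene",
    transcribed_unitary_pseudogene = "pseudogene",
    transcribed_processed_pseudogene = "pseudogene",
    IG_pseudogene = "pseudogene", IG_C_pseudogene = "pseudogene",
    IG_J_pseudogene = "pseudogene", IG_V_pseudogene = "pseudogene",
    TR_J_pseudogene = "pseudogene", TR_V_pseudogene = "pseudogene",
    pseudogene = "pseudogene",
    `3prime_overlapping_ncRNA` = "lncRNA", antisense = "lncRNA",
    lincRNA = "lncRNA", macro_lncRNA = "lncRNA",
    bidirectional_promoter_lncRNA = "lncRNA", processed_transcript = "lncRNA",
    sense_intronic = "lncRNA", sense_overlapping = "lncRNA",
    non_coding = "lncRNA", lncRNA = "lncRNA",
    Mt_tRNA = "tRNA", tRNA = "tRNA",
    snRNA = "snRNA", snoRNA = "snoRNA", miRNA = "miRNA",
    rRNA = "other", Mt_rRNA = "other", ribozyme = "other",
    scRNA = "other", vaultRNA = "other", sRNA = "other"
  )
  expect_equal(group_biotype(names(cases)), unname(cases))
  expect_equal(group_biotype("TEC"), BIOTYPE_EXCLUDE)
  expect_equal(suppressMessages(group_biotype("made_up_biotype")), "other")
})

test_that("host biotypes collapse to protein-coding / non-coding / intergenic", {
  expect_equal(group_host_biotype(c("protein_coding", "", "lincRNA", NA,
                                    "IG_C_gene", "snoRNA")),
               c("protein-coding", "intergenic", "non-coding", "intergenic",
                 "protein-coding", "non-coding"))
})

test_that("expression filter applies the strict >1 TPM, TEC and name-prefix rules", {
  m <- make_tiny_matrix()
  ann <- make_tiny_annotation()
  f <- suppressMessages(filter_expressed(m, ann))
  # G2 is all 1 TPM (not strictly above), and SCARNA-named; G1 and G3 stay
  expect_setequal(rownames(f$values), c("G1", "G3"))
  # boundary: (0, 0, 1.2) exceeds the threshold in one sample -> retained
  expect_true("G3" %in% rownames(f$values))
  # SCARNA snoRNA removed even when abundant
  m2 <- m
  m2$values["G2", ] <- 50
  f2 <- suppressMessages(filter_expressed(m2, ann))
  expect_false("G2" %in% rownames(f2$values))
  expect_equal(attr(f2, "filter_counts")[["name_prefix"]], 1L)
  # TEC biotype removed
  ann3 <- ann
  ann3$biotype_raw[3] <- "TEC"
  f3 <- suppressMessages(filter_expressed(m, ann3))
  expect_false("G3" %in% rownames(f3$values))
  expect_error(filter_expressed(m, ann, threshold_tpm = 0), "positive")
})

test_that("expression filtering is idempotent", {
  sim <- simulate_cohort(sim_params(n_ue = 60, n_te = 15, seed = 7))
  f1 <- suppressMessages(filter_expressed(sim$matrix, sim$annotation))
  f2 <- suppressMessages(filter_expressed(f1, sim$annotation))
  expect_equal(f2$values, f1$values)
})

test_that("tissue means average replicates and commute with gene subsetting", {
  m <- make_tiny_matrix()
  prof <- tissue_means(m)
  expect_equal(prof["G1", "brain"], 4)   # mean of (2, 4, 6)
  expect_equal(prof["G1", "liver"], 12)
  expect_equal(prof["G2", ], c(brain = 1, liver = 1))
  sub <- m
  sub$values <- sub$values[c("G3", "G1"), ]
  expect_equal(tissue_means(sub), prof[c("G3", "G1"), ])
  # single-replicate tissue: mean equals the replicate
  v <- matrix(c(3, 9), 1, dimnames = list("g", c("s1", "s2")))
  m1 <- abundance_matrix(v, c(s1 = "a", s2 = "b"))
  expect_equal(tissue_means(m1), matrix(c(3, 9), 1,
                                        dimnames = list("g", c("a", "b"))))
})

test_that("per-gene conservation is the mean of per-nucleotide scores", {
  expect_equal(mean_conservation(c(0.5, 0.5, 0.5)), 0.5)
  expect_equal(mean_conservation(c(1, 0, 1, 0)), 0.5)
  set.seed(42)
  scores <- runif(100)
  acc <- 0
  for (s in scores) acc <- acc + s   # independent second-pass accumulation
  expect_equal(mean_conservation(scores), acc / 100)
  expect_error(mean_conservation(numeric(0)), "empty")
  expect_error(mean_conservation(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("biotype abundance breakdown fractions are normalized per tissue", {
  m <- make_tiny_matrix()
  ann <- make_tiny_annotation()
  ann$gene_name[2] <- "SNORD2"  # keep all three genes in play
  bd <- biotype_abundance_breakdown(m, ann)
  liver <- bd[bd$tissue == "liver", ]
  # snoRNA sum 13, protein-coding sum 5 -> shares 13/18 and 5/18
  expect_equal(liver$fraction[liver$biotype_group == "snoRNA"], 13 / 18)
  expect_equal(liver$fraction[liver$biotype_group == "protein-coding"], 5 / 18)
  # property: fractions sum to one per tissue on a random fixture
  set.seed(1)
  sim <- simulate_cohort(sim_params(n_ue = 40, n_te = 10, seed = 3))
  bd2 <- biotype_abundance_breakdown(sim$matrix, sim$annotation)
  sums <- tapply(bd2$fraction, bd2$tissue, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})
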