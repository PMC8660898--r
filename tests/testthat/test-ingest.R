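test_that("read_score_table parses shape, missing cells and bad files", {
  df <- data.frame(variant_id = c("v1", "v2", "v3"),
                   gene_id = c("g1", "g1", "g2"))
  for (s in snmtf_score_names()) df[[s]] <- c(0.1, 0.5, 0.9)
  df$PROVEAN <- c("0.1", "NA", "0.7")
  tab <- read_score_table(write_score_tsv(df))
  expect_s3_class(tab, "score_table")
  expect_equal(dim(tab), c(3L, 9L))
  expect_identical(tab$score_names, snmtf_score_names())
  expect_true(is.na(tab$values["v2", "PROVEAN"]))
  expect_equal(sum(is.na(tab$values)), 1L)

  # "." and empty cells are missing; unparseable text is missing
  df$SIFT <- c(".", "", "xyz")
  tab2 <- read_score_table(write_score_tsv(df))
  expect_true(all(is.na(tab2$values[, "SIFT"])))

  expect_error(read_score_table(write_score_tsv(df[, -2])), "gene_id")
  df_dup <- df; df_dup$variant_id <- c("v1", "v1", "v3")
  expect_error(read_score_table(write_score_tsv(df_dup)), "duplicate")
})

test_that("filter_missing removes incomplete rows, is idempotent, errors when empty", {
  tab <- tiny_table(m = 5, n = 3)
  tab$values[2, 1] <- NA
  tab$values[4, 3] <- NA
  labels <- c(1L, 0L, 1L, 0L, 1L)
  expect_message(flt <- filter_missing(tab, labels), "removed 2 of 5")
  expect_equal(nrow(flt$table$values), 3L)
  expect_equal(flt$labels, labels[c(1, 3, 5)])
  expect_equal(flt$n_removed, 2L)
  # idempotent
  again <- filter_missing(flt$table, flt$labels)
  expect_identical(again$table$values, flt$table$values)
  expect_equal(again$n_removed, 0L)
  # identity on complete tables
  clean <- tiny_table(m = 4, n = 3)
  expect_identical(filter_missing(clean)$table$values, clean$values)
  # all rows missing the same score
  tab2 <- tiny_table(m = 4, n = 3)
  tab2$values[, 2] <- NA
  expect_error(filter_missing(tab2), "empty-dataset")
})

test_that("orientation fitting flips SIFT/LRT and records training bounds", {
  tab <- score_table(data.frame(variant_id = c("v1", "v2", "v3"),
                                gene_id = "g1"),
                     c("SIFT", "phyloP"),
                     cbind(c(0, 0.5, 1), c(0.2, 0.6, 1.0)))
  omap <- fit_orientation(tab)
  expect_true(omap$flip[["SIFT"]])
  expect_false(omap$flip[["phyloP"]])
  # SIFT flipped to 1-score before bounds
  expect_equal(unname(omap$a_min), c(0, 0.2))
  expect_equal(unname(omap$a_max), c(1, 1.0))

  R <- normalize_scores(tab, omap)
  expect_equal(unname(R[, "phyloP"]), c(0, 0.5, 1))
  # raw SIFT 0 (most damaging) maps to 1
  expect_equal(unname(R[, "SIFT"]), c(1, 0.5, 0))
})

test_that("normalization clips test values outside training bounds", {
  train <- score_table(data.frame(variant_id = c("v1", "v2"), gene_id = "g"),
                       "phyloP", cbind(c(0.2, 1.0)))
  omap <- fit_orientation(train)
  test <- score_table(data.frame(variant_id = c("t1", "t2", "t3"), gene_id = "g"),
                      "phyloP", cbind(c(1.4, 0.1, 0.6)))
  R <- normalize_scores(test, omap)
  # formula first: (1.4 - 0.2)/0.8 = 1.5 -> clipped to 1; (0.1-0.2)/0.8 < 0 -> 0
  expect_equal(unname(R[, 1]), c(1, 0, 0.5))
})

test_that("constant score columns normalize to 0.5", {
  tab <- score_table(data.frame(variant_id = c("v1", "v2"), gene_id = "g"),
                     c("a", "b"), cbind(c(0.4, 0.4), c(0, 1)))
  R <- normalize_scores(tab, fit_orientation(tab, flip_scores = character()))
  expect_equal(unname(R[, "a"]), c(0.5, 0.5))
  expect_equal(unname(R[, "b"]), c(0, 1))
})

test_that("normalized output always lies in [0,1] and flips reverse ordering", {
  set.seed(7)
  for (rep in 1:20) {
    m <- sample(3:30, 1); n <- sample(2:6, 1)
    raw <- matrix(stats::rnorm(m * n, sd = 10), m, n)
    names <- c("SIFT", paste0("s", seq_len(n - 1)))
    tab <- score_table(data.frame(variant_id = paste0("v", 1:m), gene_id = "g"),
                       names, raw)
    omap <- fit_orientation(tab)
    # normalize a different random table against training bounds
    tab2 <- score_table(tab$variants, names, matrix(stats::rnorm(m * n, sd = 10), m, n))
    R <- normalize_scores(tab2, omap)
    expect_true(all(R >= 0 & R <= 1))
    # flip-flagged column: raw a < b implies normalized(a) >= normalized(b)
    ord <- order(tab2$values[, "SIFT"])
    expect_true(all(diff(R[ord, "SIFT"]) <= 1e-12))
  }
})

test_that("read_ppi deduplicates, rescales STRING scores and applies the threshold", {
  path <- tempfile()
  writeLines(c("protein1\tprotein2\tcombined_score",
               "p1\tp2\t800",
               "p2\tp1\t800",       # reverse duplicate
               "p3\tp3\t900",       # self edge
               "p1\tp3\t100",       # 0.10 < 0.15 threshold
               "p2\tp3\t150"),      # 0.15 is not retained (strictly higher)
             path)
  ppi <- read_ppi(path, min_confidence = 0.15)
  expect_equal(nrow(ppi), 1L)
  expect_equal(ppi$protein_a, "p1")
  expect_equal(ppi$protein_b, "p2")
  expect_equal(ppi$confidence, 0.8)

  # unit-scale dialect without header, space separated
  path2 <- tempfile()
  writeLines(c("p1 p2 0.9", "p1 p4 0.2"), path2)
  ppi2 <- read_ppi(path2)
  expect_equal(ppi2$confidence, c(0.9, 0.2))

  path3 <- tempfile()
  writeLines(c("p1 p2 0.9", "p1 0.2"), path3)
  expect_error(read_ppi(path3), "line 2")
})

test_that("labels and gene-disease tables validate and align", {
  lp <- tempfile()
  utils::write.table(data.frame(variant_id = c("v1", "v2"), label = c(1, 0)),
                     lp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_labels(lp, c("v2", "v1")), c(0L, 1L))
  expect_error(read_labels(lp, c("v1", "v3")), "v3")
  bad <- tempfile()
  utils::write.table(data.frame(variant_id = "v1", label = 2),
                     bad, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_labels(bad, "v1"), "0.*1|deleterious")

  gp <- tempfile()
  utils::write.table(data.frame(gene_id = c("g1", "g1", "g2"),
                                disease_id = c("d1", "d1", "d2")),
                     gp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(read_gene_disease(gp)), 2L)
})

test_that("overlap removal utility drops shared variants only on request", {
  tab <- tiny_table(m = 5, n = 3)
  res <- drop_overlapping_variants(tab, c("v01", "v04"), labels = rep(1L, 5))
  expect_equal(res$n_removed, 2L)
  expect_equal(res$table$variants$variant_id, c("v02", "v03", "v05"))
  expect_error(drop_overlapping_variants(tab, tab$variants$variant_id),
               "empty-dataset")
})
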