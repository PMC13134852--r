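test_that("cpm_normalize scales by library size times 1e6", {
  counts <- matrix(c(2, 8, 0, 0, 0, 10), nrow = 3,
                   dimnames = list(c("g1", "g2", "g3"), c("o1", "o2")))
  cpm <- cpm_normalize(expression_matrix(counts))
  expect_equal(cpm["g1", "o1"], 2e5)
  expect_equal(cpm["g3", "o2"], 1e6)  # only expressed gene
  # columns sum to 1e6 over all features of the source matrix
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6))
  # scale invariance: doubling all counts leaves CPM unchanged
  expect_equal(cpm_normalize(expression_matrix(2 * counts)), cpm)
  # zero library size observation dropped with a warning
  counts0 <- cbind(counts, o3 = c(0, 0, 0))
  expect_warning(cpm0 <- cpm_normalize(expression_matrix(counts0)),
                 "zero library size")
  expect_equal(colnames(cpm0), c("o1", "o2"))
})

test_that("pseudolog is the natural log with pseudocount", {
  expect_equal(pseudolog(0), 0)
  expect_equal(pseudolog(exp(1) - 1), 1)
  expect_equal(pseudolog(4, pseudocount = 0.5), log(4.5))
  set.seed(2)
  v <- sort(stats::runif(50, 0, 100))
  expect_true(all(diff(pseudolog(v)) >= 0))  # monotone
  expect_error(pseudolog(-1), "non-negative")
})

test_that("aggregate_with_offtargets sums raw counts then re-normalizes", {
  counts <- matrix(c(5, 3, 12, 0, 7, 3, 0, 0, 20, 4, 6, 10), nrow = 4,
                   dimnames = list(c("tgt", "off1", "off2", "bg"),
                                   c("o1", "o2", "o3")))
  em <- expression_matrix(counts)
  agg <- aggregate_with_offtargets(em, "tgt", c("off1", "off2"))
  manual <- log((counts["tgt", ] + counts["off1", ] + counts["off2", ]) /
                  colSums(counts) * 1e6 + 1)
  expect_equal(as.numeric(agg), as.numeric(manual))
  # no off-targets present: identical to the target-only pipeline
  expect_message(
    solo <- aggregate_with_offtargets(em, "tgt", "absent_gene"),
    "skipped")
  expect_equal(as.numeric(solo),
               as.numeric(pseudolog(cpm_normalize(em))["tgt", ]))
  # aggregated raw signal dominates target-only elementwise
  expect_true(all(agg >= solo))
  # zero-everywhere target + expressed off-target = off-target profile
  agg2 <- aggregate_with_offtargets(em, "bg", "off2")
  expect_equal(as.numeric(agg2),
               as.numeric(log((counts["bg", ] + counts["off2", ]) /
                                colSums(counts) * 1e6 + 1)))
  expect_error(aggregate_with_offtargets(em, "nope", "off1"),
               "target feature absent")
})

test_that("concordance implements RMSE vs identity and the nan contract", {
  # hand arithmetic: a=(0,3,4), b=(0,0,0) -> rmse = sqrt(25/3)
  cc <- concordance(c(0, 3, 4), c(0, 0, 0))
  expect_equal(cc$rmse, sqrt(25 / 3))
  expect_true(is.na(cc$pearson))  # zero-variance b -> missing, never 0

  a <- c(1, 2, 5, 3)
  expect_equal(concordance(a, a)$rmse, 0)
  expect_equal(concordance(a, a)$pearson, 1)
  const <- concordance(c(2, 2, 2), c(2, 2, 2))
  expect_equal(const$rmse, 0)
  expect_true(is.na(const$pearson))
  # rmse is symmetric
  b <- c(0, 1, 7, 2)
  expect_equal(concordance(a, b)$rmse, concordance(b, a)$rmse)
  expect_error(concordance(1:3, 1:4), "length mismatch")
  expect_error(concordance(1, 2), "at least 2")
})

test_that("group_means filters small groups per modality", {
  set.seed(8)
  mat <- matrix(stats::rnorm(2 * 17), nrow = 2,
                dimnames = list(c("g1", "g2"), paste0("o", 1:17)))
  labels <- rep(c("c1", "c2"), c(12, 5))
  gm <- group_means(mat, labels, min_size = 10)
  expect_equal(colnames(gm), "c1")  # the 5-cell group is excluded
  expect_equal(unname(gm[, "c1"]), unname(rowMeans(mat[, 1:12])))

  # modality-aware: a group must clear the minimum in EVERY modality
  labels2 <- rep("c1", 17)
  modality <- rep(c("x", "y"), c(12, 5))
  expect_error(group_means(mat, labels2, 10, modality), "below the minimum")
  gm2 <- group_means(mat, labels2, 5, modality)
  expect_equal(unname(gm2[, "c1"]), unname(rowMeans(mat)))

  # permutation invariance
  perm <- sample(17)
  gm3 <- group_means(mat[, perm], labels[perm], min_size = 10)
  expect_equal(gm3, gm)
})

test_that("offtarget_expression_screen ranks by reference expression", {
  sim <- shared_sim()
  run <- run_all(sim$panel, sim$annotations[[2]], aligner_config(pl = 0))
  ex <- simulate_expression(sim, seed = 3L)
  scr <- offtarget_expression_screen(run$results[[1]]$summaries, ex$y)
  expect_s3_class(scr, "impact_table")
  expect_true(nrow(scr) > 0)
  # within each target, detected entries are in decreasing expression order
  for (t in unique(scr$target_gene)) {
    vals <- scr$mean_log1p_cpm[scr$target_gene == t & scr$detected]
    expect_true(all(diff(vals) <= 0))
  }
  # values equal the log1p mean-CPM bulk profile
  profile <- pseudolog(rowMeans(cpm_normalize(ex$y)))
  i <- which(scr$detected)[1]
  expect_equal(scr$mean_log1p_cpm[i], unname(profile[scr$offtarget_gene[i]]))
  # undetected features are flagged and excluded from the ordering
  s_fake <- run$results[[1]]$summaries
  s_fake[[1]]$predicted$gene_name[!s_fake[[1]]$predicted$on_target][1] <-
    "NOT_IN_MATRIX"
  scr2 <- offtarget_expression_screen(s_fake, ex$y)
  und <- scr2[scr2$offtarget_gene == "NOT_IN_MATRIX", ]
  expect_false(und$detected)
  expect_true(is.na(und$mean_log1p_cpm))
  # observation permutation leaves the screen unchanged
  perm <- sample(ncol(ex$y$counts))
  y_perm <- expression_matrix(ex$y$counts[, perm])
  expect_equal(offtarget_expression_screen(run$results[[1]]$summaries,
                                           y_perm), scr)
})

test_that("ensembl version suffixes are trimmed before matching", {
  counts <- matrix(c(4, 6, 2, 8), nrow = 2,
                   dimnames = list(c("ENSG00000001.5", "ENSG00000002.12"),
                                   c("o1", "o2")))
  summaries <- list(structure(list(
    target_gene_id = "T", target_gene_name = "TGT", n_probes = 2L,
    predicted = data.frame(
      gene_id = c("T", "ENSG00000002.3"),
      gene_name = c("TGT", "ENSG00000002.3"),
      n_probes_aligned = c(2L, 1L), biotype = "protein_coding",
      on_target = c(TRUE, FALSE), readthrough = FALSE,
      stringsAsFactors = FALSE)), class = "gene_summary"))
  scr <- offtarget_expression_screen(summaries, expression_matrix(counts))
  expect_equal(scr$offtarget_gene, "ENSG00000002")
  expect_true(scr$detected)
})
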