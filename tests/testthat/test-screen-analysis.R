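toy_library <- function(n_genes = 3, guides = 4, n_controls = 6, seed = 20) {
  withr::with_seed(seed, {
    n <- n_genes * guides + n_controls
    protos <- character(0)
    while (length(protos) < n) {
      protos <- unique(c(protos, replicate(n, paste0(
        sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = ""))))
    }
    protos <- protos[seq_len(n)]
  })
  tibble::tibble(
    design_id = c(sprintf("g%d_%d", rep(seq_len(n_genes), each = guides),
                          rep(seq_len(guides), n_genes)),
                  sprintf("nt_%03d", seq_len(n_controls))),
    gene_id = c(rep(sprintf("gene%d", seq_len(n_genes)), each = guides),
                rep(NA_character_, n_controls)),
    protospacer = protos
  )
}

write_fastq <- function(reads, path) {
  writeLines(as.vector(rbind(paste0("@r", seq_along(reads)), reads, "+",
                             strrep("I", nchar(reads)))), path)
  path
}

test_that("the read pattern extracts 20-mers and conserves reads", {
  lib <- toy_library()
  known <- lib$protospacer[1]
  reads <- c(
    paste0("AACCTT", "ACCG", known, "TTT", "AGAGC", "GGAA"),     # match
    paste0("ACCG", known, "TT", "AGAGC"),                         # 2 T's ok
    paste0("ACCG", known, "TTTT", "AGAGC"),                       # 4 T's ok
    paste0("ACCG", known, "TTTTT", "AGAGC"),                      # 5 T's: no
    paste0("ACCG", strrep("C", 20), "TTT", "AGAGC"),              # unknown 20mer
    "ACGTACGTACGTACGTACGTACGTACGTACGT"                            # no pattern
  )
  fq <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  counts <- count_guides(fq, lib)
  expect_equal(counts$count[counts$design_id == lib$design_id[1]], 3L)
  expect_equal(sum(counts$count), 3L)
  expect_equal(attr(counts, "unmatched"), 3L)
  expect_equal(sum(counts$count) + attr(counts, "unmatched"),
               attr(counts, "total_reads"))
})

test_that("gzip-compressed FASTQ is accepted", {
  lib <- toy_library()
  reads <- paste0("ACCG", lib$protospacer[2], "TTT", "AGAGC")
  fq <- withr::local_tempfile(fileext = ".fastq.gz")
  con <- gzfile(fq, "w")
  writeLines(c("@r1", reads, "+", strrep("I", nchar(reads))), con)
  close(con)
  counts <- count_guides(fq, lib)
  expect_equal(counts$count[counts$design_id == lib$design_id[2]], 1L)
})

test_that("planted fixture abundances are recovered exactly", {
  lib <- toy_library(n_genes = 4, guides = 5, n_controls = 10)
  fx <- make_screen_fixture(lib, effects = c(gene1 = 4), reads_per_guide = 40,
                            rng_seed = 7, dir = withr::local_tempdir())
  for (s in names(fx$fastqs)) {
    counts <- count_guides(fx$fastqs[[s]], lib)
    expect_identical(counts$count, fx$counts[[s]])
    expect_equal(attr(counts, "unmatched"), 0L)
  }
})

test_that("median normalization is scale-invariant and fold changes behave", {
  lib_ids <- sprintf("d%02d", 1:20)
  nt <- lib_ids[16:20]
  withr::with_seed(9, {
    base <- sample(50:150, 20)
  })
  counts <- tibble::tibble(design_id = lib_ids,
                           t1 = base, t2 = base, c1 = base, c2 = base)
  # identical treated and control -> raw fold change 0 everywhere
  out <- normalize_and_fold_change(counts, c("t1", "t2"), c("c1", "c2"), nt)
  expect_equal(out$raw_l2fc, rep(0, 20))
  # scaling one sample's counts leaves its normalized column unchanged
  scaled <- counts
  scaled$t1 <- scaled$t1 * 17L
  out2 <- normalize_and_fold_change(scaled, c("t1", "t2"), c("c1", "c2"), nt,
                                    pseudocount = 0)
  expect_equal(out2$mean_treated, out$mean_treated)
  expect_equal(out2$mean_control, out$mean_control)
  out0 <- normalize_and_fold_change(counts, c("t1", "t2"), c("c1", "c2"), nt,
                                    pseudocount = 0)
  expect_equal(out2$raw_l2fc, out0$raw_l2fc)
  # exact 4x treated mean -> raw_l2fc = 2 (pseudocount disabled for exactness)
  fourx <- counts
  fourx$t1 <- counts$c1 * 4L; fourx$t2 <- counts$c2 * 4L
  out3 <- normalize_and_fold_change(fourx, c("t1", "t2"), c("c1", "c2"), nt,
                                    pseudocount = 0)
  expect_equal(out3$raw_l2fc, rep(0, 20))  # median normalization absorbs a
  # global 4x; a per-guide effect is what changes the ratio:
  eff <- counts
  eff$t1[1:5] <- eff$t1[1:5] * 4L; eff$t2[1:5] <- eff$t2[1:5] * 4L
  med_ratio <- stats::median(eff$t1) / stats::median(counts$c1)
  out4 <- normalize_and_fold_change(eff, c("t1", "t2"), c("c1", "c2"), nt,
                                    pseudocount = 0)
  expect_equal(out4$raw_l2fc[1:5], rep(log2(4 / med_ratio), 5))
  # centring puts the non-targeting median exactly at zero
  expect_equal(stats::median(out4$centred_l2fc[counts$design_id %in% nt]), 0)
  # zero median is an error naming the sample
  zero <- counts
  zero$c1 <- c(rep(0L, 15), 1L, 0L, 0L, 0L, 0L)
  expect_error(
    normalize_and_fold_change(zero, c("t1", "t2"), c("c1", "c2"), nt), "c1")
})

test_that("the gene test matches the closed-form rank-sum oracle", {
  # 30 gene guides all above all 200 controls: the extreme configuration
  gene_vals <- seq(5, 5.29, by = 0.01)
  ctrl_vals <- seq(-1, 0.99, by = 0.01)
  l2fc <- tibble::tibble(
    design_id = c(sprintf("g_%02d", seq_along(gene_vals)),
                  sprintf("nt_%03d", seq_along(ctrl_vals))),
    centred_l2fc = c(gene_vals, ctrl_vals))
  gm <- tibble::tibble(design_id = sprintf("g_%02d", seq_along(gene_vals)),
                       gene_id = "geneX")
  nt <- sprintf("nt_%03d", seq_along(ctrl_vals))
  res <- gene_test(l2fc, gm, nt, alternative = "greater")
  expect_equal(res$p_value, oracle_wilcox_p(gene_vals, ctrl_vals, "greater"),
               tolerance = 1e-12)
  expect_equal(res$log2fc, stats::median(gene_vals))
  expect_equal(res$n_guides, 30L)

  # a gene sitting exactly on the control median is not enriched
  flat <- tibble::tibble(
    design_id = c(sprintf("g_%02d", 1:10), nt),
    centred_l2fc = c(rep(stats::median(ctrl_vals), 10), ctrl_vals))
  res2 <- gene_test(flat, tibble::tibble(design_id = sprintf("g_%02d", 1:10),
                                         gene_id = "geneY"), nt)
  expect_gt(res2$p_value, 0.5)

  # ties: oracle and implementation agree under heavy tying
  withr::with_seed(33, {
    gv <- sample(c(0, 0.5, 1), 25, replace = TRUE)
    cv <- sample(c(0, 0.5, 1), 100, replace = TRUE)
  })
  tied <- tibble::tibble(
    design_id = c(sprintf("g_%02d", 1:25), sprintf("nt_%03d", 1:100)),
    centred_l2fc = c(gv, cv))
  res3 <- gene_test(tied, tibble::tibble(design_id = sprintf("g_%02d", 1:25),
                                         gene_id = "geneZ"),
                    sprintf("nt_%03d", 1:100))
  expect_equal(res3$p_value, oracle_wilcox_p(gv, cv, "greater"),
               tolerance = 1e-12)
  expect_error(gene_test(tied, tibble::tibble(design_id = "g_01",
                                              gene_id = "g"), character()),
               "empty")
})

test_that("tidy and glance summarize gene results", {
  l2fc <- tibble::tibble(design_id = c(sprintf("g_%d", 1:6),
                                       sprintf("n_%d", 1:8)),
                         centred_l2fc = c(rnorm(6, 2), rnorm(8)))
  gm <- tibble::tibble(design_id = sprintf("g_%d", 1:6),
                       gene_id = rep(c("a", "b"), each = 3))
  res <- gene_test(l2fc, gm, sprintf("n_%d", 1:8))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("gene_id", "log2fc", "p_value", "n_guides"))
  gl <- glance(res)
  expect_equal(gl$n_genes, 2L)
  expect_equal(gl$n_controls, 8L)
  expect_equal(gl$alternative, "greater")
})

test_that("z-score classification labels by the +/-1 thresholds", {
  out <- classify_functional(c(0, 0, 0, 10))
  expect_equal(out$label, c(rep("intermediate", 3), "functional"))
  expect_gt(out$z[4], 1)
  sym <- classify_functional(c(-5, -4, 4, 5))
  expect_equal(sum(sym$label == "functional"),
               sum(sym$label == "non-functional"))
  expect_warning(flat <- classify_functional(c(2, 2, 2)), "zero spread")
  expect_true(all(flat$label == "intermediate"))
  expect_error(classify_functional(3), "length")
})
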