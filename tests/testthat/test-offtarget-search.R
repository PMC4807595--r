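test_that("k-mer index lookups match a naive string scan", {
  g <- genome_assembly(c(chr1 = "ACGTACGT"))
  idx <- build_seed_index(g, k = 4)
  hits <- lookup_kmer(idx, "ACGT")
  expect_setequal(hits$start[hits$strand == "+"], c(0L, 4L))
  expect_setequal(hits$start[hits$strand == "-"], c(0L, 4L))  # rc(ACGT)=ACGT
  expect_equal(nrow(lookup_kmer(idx, "GGGG")), 0)

  g2 <- random_genome(5000, seed = 31)
  idx2 <- build_seed_index(g2, k = 6)
  s <- g2$seq[["chr1"]]
  withr::with_seed(32, {
    for (i in 1:50) {
      kmer <- paste0(sample(c("A", "C", "G", "T"), 6, replace = TRUE),
                     collapse = "")
      got <- lookup_kmer(idx2, kmer)
      naive_fwd <- as.integer(gregexpr(paste0("(?=", kmer, ")"), s,
                                       perl = TRUE)[[1]]) - 1L
      naive_fwd <- naive_fwd[naive_fwd >= 0]
      rc <- oracle_revcomp(kmer)
      naive_rev <- as.integer(gregexpr(paste0("(?=", rc, ")"), s,
                                       perl = TRUE)[[1]]) - 1L
      naive_rev <- naive_rev[naive_rev >= 0]
      expect_setequal(got$start[got$strand == "+"], naive_fwd)
      expect_setequal(got$start[got$strand == "-"], naive_rev)
    }
  })
})

test_that("planted duplicates are found, over-distance and bad-PAM copies are not", {
  fx <- make_genome_fixture(fixture_spec(
    rng_seed = 8,
    planted_offtargets = list(
      list(site = 1, mismatches = 0),            # perfect copy, TGG PAM
      list(site = 2, mismatches = 2),            # 2-mm copy
      list(site = 3, mismatches = 0, pam = "ATT"),  # disallowed PAM
      list(site = 4, mismatches = 4)             # beyond the budget
    ),
    planted_pam_sites = 2
  ))
  g <- fx$genome
  idx <- build_seed_index(g)
  sites <- scan_targets(g, "chr1")
  policy <- search_policy(max_mismatches = 3, trim_3prime = 4)

  site_row <- function(i) {
    ts <- fx$truth_sites[i, ]
    sites[sites$proto_start == ts$proto_start & sites$strand == ts$strand, ]
  }
  h1 <- find_offtargets(site_row(1), idx, g, policy)
  expect_equal(sum(h1$is_on_target), 1)
  off1 <- h1[!h1$is_on_target, ]
  expect_equal(nrow(off1), 1)
  expect_equal(off1$mismatch_count, 0L)
  expect_equal(off1$start, fx$truth_offtargets$proto_start[1])
  expect_equal(off1$pam_observed, "TGG")

  h2 <- find_offtargets(site_row(2), idx, g, policy)
  off2 <- h2[!h2$is_on_target, ]
  expect_equal(off2$mismatch_count, 2L)
  expect_equal(off2$homologous_nt, 14L)

  h3 <- find_offtargets(site_row(3), idx, g, policy)
  expect_equal(nrow(h3[!h3$is_on_target, ]), 0)  # PAM mismatch disqualifies

  h4 <- find_offtargets(site_row(4), idx, g, policy)
  expect_equal(nrow(h4[!h4$is_on_target, ]), 0)  # 4 mismatches > budget
})

test_that("the search equals the exhaustive Hamming oracle across policies", {
  pams_ngg <- iupac_expand("NGG")
  pams_ngg_nag <- c(pams_ngg, iupac_expand("NAG"))
  policies <- list(
    list(mm = 0, ig = 0, tr = 0, pams = pams_ngg),
    list(mm = 1, ig = 0, tr = 4, pams = pams_ngg_nag),
    list(mm = 2, ig = 2, tr = 0, pams = pams_ngg),
    list(mm = 3, ig = 0, tr = 4, pams = pams_ngg_nag),
    list(mm = 3, ig = 4, tr = 0, pams = pams_ngg)
  )
  key <- function(d) sort(paste(d$chrom, d$start, d$strand, d$mismatch_count))
  withr::with_seed(99, {
    for (rep in 1:4) {
      g <- random_genome(20000, n_chroms = 2)
      idx <- build_seed_index(g)
      sites <- scan_targets(g, "chr1", 0, 3000)
      sites <- sites[sample.int(nrow(sites), 6), ]
      for (pol in policies) {
        sp <- search_policy(max_mismatches = pol$mm, ignore_5prime = pol$ig,
                            trim_3prime = pol$tr, allowed_pams = pol$pams,
                            max_hits_reported = 10000)
        for (i in seq_len(nrow(sites))) {
          got <- find_offtargets(sites[i, ], idx, g, sp)
          want <- oracle_offtargets(g, sites$protospacer[i], pol$mm,
                                    pol$ig, pol$tr, pol$pams)
          expect_identical(key(got), key(want))
        }
      }
    }
  })
})

test_that("low sensitivity restricts to one mismatch; raising budgets never loses hits", {
  fx <- make_genome_fixture(fixture_spec(
    rng_seed = 12,
    planted_offtargets = list(list(site = 1, mismatches = 2),
                              list(site = 1, mismatches = 0))))
  g <- fx$genome; idx <- build_seed_index(g)
  sites <- scan_targets(g, "chr1")
  s1 <- sites[sites$proto_start == fx$truth_sites$proto_start[1] &
                sites$strand == "+", ]
  low <- find_offtargets(s1, idx, g,
                         search_policy(max_mismatches = 3, trim_3prime = 4,
                                       sensitivity = "low"))
  expect_true(all(low$mismatch_count <= 1))
  keyset <- function(h) paste(h$chrom, h$start, h$strand)
  for (mm in 0:2) {
    a <- find_offtargets(s1, idx, g,
                         search_policy(max_mismatches = mm, trim_3prime = 4))
    b <- find_offtargets(s1, idx, g,
                         search_policy(max_mismatches = mm + 1, trim_3prime = 4))
    expect_true(all(keyset(a) %in% keyset(b)))
  }
})

test_that("hit cap truncates the sorted tail only", {
  proto <- "ACGTTGCAACGTACGTACGA"
  copies <- paste0(proto, c("TGG", "CGG", "GGG"))
  g <- genome_assembly(c(chr1 = paste0(
    proto, "AGG", strrep("A", 30), paste0(copies, strrep("C", 10), collapse = ""))))
  idx <- build_seed_index(g)
  sites <- scan_targets(g, "chr1", 0, 23)
  all_hits <- find_offtargets(sites, idx, g,
                              search_policy(max_hits_reported = 30))
  capped <- find_offtargets(sites, idx, g,
                            search_policy(max_hits_reported = 2))
  off_all <- all_hits[!all_hits$is_on_target, ]
  off_cap <- capped[!capped$is_on_target, ]
  expect_equal(nrow(off_all), 3)
  expect_equal(nrow(off_cap), 2)
  expect_equal(off_cap$start, off_all$start[1:2])
  expect_equal(sum(capped$is_on_target), 1)  # on-target never truncated
})

test_that("a second identical genomic copy is a genuine off-target (coordinate identity)", {
  proto <- "ACGTTGCAACGTACGTACGA"
  g <- genome_assembly(c(chr1 = paste0(proto, "AGG", strrep("T", 20),
                                       proto, "AGG")))
  idx <- build_seed_index(g)
  sites <- scan_targets(g, "chr1")
  first <- sites[sites$proto_start == 0 & sites$strand == "+", ]
  h <- find_offtargets(first, idx, g, search_policy())
  expect_equal(sum(h$is_on_target), 1)
  expect_equal(h$start[h$is_on_target], 0L)
  expect_equal(sum(!h$is_on_target & h$mismatch_count == 0), 1)
})

test_that("too-short queries raise an informative error", {
  g <- random_genome(200, seed = 41)
  idx <- build_seed_index(g, k = 4)
  site <- list(chrom = "chr1", strand = "+", proto_start = 0L,
               protospacer = "ACGTACGTACGTACGTACGT")
  expect_error(
    find_offtargets(site, idx, g,
                    search_policy(max_mismatches = 3, ignore_5prime = 4,
                                  trim_3prime = 4)),
    "too short")
})

test_that("specificity score reproduces the printed arithmetic and stays in range", {
  hit <- function(h, chrom = "chr1", start = 1L) {
    tibble::tibble(chrom = chrom, start = start, strand = "+",
                   mismatch_count = 0L, homologous_nt = h,
                   pam_observed = "TGG", is_on_target = FALSE)
  }
  none <- hit(20)[0, ]
  expect_equal(specificity_score(none), 100)
  expect_equal(specificity_score(hit(20)), 80)
  expect_equal(specificity_score(dplyr::bind_rows(hit(20, start = 1L),
                                                  hit(20, start = 50L))), 70)
  expect_equal(specificity_score(hit(16)), 84)
  # floor at zero
  many <- dplyr::bind_rows(lapply(1:400, function(i) hit(20, start = i * 30L)))
  expect_equal(specificity_score(many), 0)
  # monotone: more hits never raise the score; more homology never raises it
  withr::with_seed(7, {
    for (r in 1:20) {
      n <- sample(1:8, 1)
      hn <- sample(5:20, n, replace = TRUE)
      hits <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
        h <- hit(hn[i], start = i * 25L); h$homologous_nt <- hn[i]; h
      }))
      s_all <- specificity_score(hits)
      expect_gte(s_all, 0); expect_lte(s_all, 100)
      expect_lte(s_all, specificity_score(hits[-1, , drop = FALSE]))
      bumped <- hits
      bumped$homologous_nt[1] <- min(20L, bumped$homologous_nt[1] + 1L)
      expect_lte(specificity_score(bumped), s_all)
    }
  })
  # the on-target row never penalizes
  on <- hit(20); on$is_on_target <- TRUE
  expect_equal(specificity_score(on), 100)
})

test_that("SAM dump carries one line per hit with the NM tag", {
  fx <- make_genome_fixture(fixture_spec(
    rng_seed = 14, planted_offtargets = list(list(site = 1, mismatches = 1))))
  g <- fx$genome; idx <- build_seed_index(g)
  sites <- scan_targets(g, "chr1")
  s1 <- sites[sites$proto_start == fx$truth_sites$proto_start[1] &
                sites$strand == "+", ]
  hits <- find_offtargets_all(s1, idx, g, search_policy(trim_3prime = 4))
  sam <- withr::local_tempfile(fileext = ".sam")
  write_offtarget_sam(hits[!hits$is_on_target, ], g, sam, query_length = 16)
  lines <- readLines(sam)
  body <- lines[!startsWith(lines, "@")]
  expect_equal(length(body), sum(!hits$is_on_target))
  expect_true(all(grepl("NM:i:1", body)))
  expect_true(any(startsWith(lines, "@SQ")))
})
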