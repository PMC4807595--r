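test_that("a lone NGG emits one plus-strand site of 23 nt including PAM", {
  proto <- "ACGTACGTACGTACGTACGA"
  g <- genome_assembly(c(chr1 = paste0(proto, "AGG")))
  sites <- scan_targets(g, "chr1")
  expect_equal(nrow(sites), 1)
  expect_equal(sites$strand, "+")
  expect_equal(sites$end - sites$start, 23L)
  expect_equal(sites$protospacer, proto)
  expect_equal(sites$pam, "AGG")
})

test_that("a leading CCN emits one minus-strand site with reverse-complemented protospacer", {
  tail20 <- "ACGTACGTACGTACGTACGA"
  g <- genome_assembly(c(chr1 = paste0("CCT", tail20)))
  sites <- scan_targets(g, "chr1")
  minus <- sites[sites$strand == "-", ]
  expect_equal(nrow(minus), 1)
  expect_equal(minus$protospacer, revcomp(tail20))
  expect_equal(minus$pam, "AGG")  # revcomp of CCT
  expect_equal(minus$end - minus$start, 23L)
})

test_that("poly-T protospacers are excluded by default and kept when disabled", {
  proto <- "ACGTACGTACTTTTTACGTA"
  g <- genome_assembly(c(chr1 = paste0(proto, "AGG")))
  expect_equal(nrow(scan_targets(g, "chr1")), 0)
  kept <- scan_targets(g, "chr1", exclude_polyT = FALSE)
  expect_equal(kept$protospacer, proto)
})

test_that("protospacers containing N are never emitted", {
  g <- genome_assembly(c(chr1 = paste0("ACGTACGTACNGTACGTACG", "AGG")))
  expect_equal(nrow(scan_targets(g, "chr1")), 0)
})

test_that("scanning a genome and its reverse complement give mirror-image site sets", {
  g <- random_genome(600, seed = 11)
  L <- g$lengths[["chr1"]]
  grc <- genome_assembly(c(chr1 = revcomp(g$seq[["chr1"]])))
  a <- scan_targets(g, "chr1")
  b <- scan_targets(grc, "chr1")
  # reflect b back into a's coordinates
  b_ref <- tibble::tibble(
    start = L - b$end, end = L - b$start,
    strand = ifelse(b$strand == "+", "-", "+"),
    protospacer = b$protospacer, pam = b$pam)
  key <- function(x) paste(x$start, x$end, x$strand, x$protospacer, x$pam)
  expect_setequal(key(a), key(b_ref))
})

test_that("every planted fixture site is recovered by the scan", {
  fx <- make_genome_fixture(fixture_spec(rng_seed = 2, planted_pam_sites = 3))
  sites <- scan_targets(fx$genome, "chr1")
  key <- paste(sites$proto_start, sites$strand, sites$protospacer)
  truth <- paste(fx$truth_sites$proto_start, fx$truth_sites$strand,
                 fx$truth_sites$protospacer)
  expect_true(all(truth %in% key))
})

test_that("scan on a PAM-free sequence yields exactly zero sites", {
  # 60 nt with no G at all: no NGG on +, no CCN on -
  g <- genome_assembly(c(chr1 = strrep("ACT", 20)))
  expect_equal(nrow(scan_targets(g, "chr1")), 0)
})

test_that("5prime-side PAM geometry places the protospacer after the PAM", {
  proto <- "ACGTACGTACGTACGTACGA"
  g <- genome_assembly(c(chr1 = paste0("TTTA", proto)))
  sites <- scan_targets(g, "chr1", pam = pam_spec("TTTN", side = "5prime"))
  plus <- sites[sites$strand == "+", ]
  expect_equal(plus$protospacer, proto)
  expect_equal(plus$start, 0L)
  expect_equal(plus$end, 24L)
  expect_true(is.na(plus$context30))
})

test_that("the 30-nt context embeds flank/protospacer/PAM at documented offsets on both strands", {
  g <- random_genome(800, seed = 13)
  sites <- scan_targets(g, "chr1")
  has_ctx <- sites[!is.na(sites$context30), ]
  expect_gt(nrow(has_ctx), 0)
  expect_true(all(nchar(has_ctx$context30) == 30))
  expect_true(all(substr(has_ctx$context30, 5, 24) == has_ctx$protospacer))
  expect_true(all(substr(has_ctx$context30, 25, 27) == has_ctx$pam))
})

test_that("region filtering keeps only feature-overlapping sites, one-base overlap included", {
  proto <- "ACGTACGTACGTACGTACGA"
  g <- genome_assembly(c(chr1 = paste0(strrep("A", 50), proto, "AGG",
                                       strrep("A", 50))))
  sites <- scan_targets(g, "chr1")  # protospacer at [50, 70)
  stopifnot(nrow(sites) == 1)
  tree_of <- function(cds_start, cds_end) {
    annotation_tree(tibble::tibble(
      chrom = "chr1", start = as.integer(cds_start), end = as.integer(cds_end),
      strand = "+", feature_type = "cds", gene_id = "g",
      transcript_id = "t", exon_number = 1L))
  }
  filt <- region_filter(cds_only = TRUE)
  # intron-only tree: site removed
  expect_equal(nrow(filter_by_region(sites, tree_of(0, 40), filt)), 0)
  # one-base overlap at each edge: kept (nonempty intersection)
  expect_equal(nrow(filter_by_region(sites, tree_of(69, 90), filt)), 1)
  expect_equal(nrow(filter_by_region(sites, tree_of(20, 51), filt)), 1)
  # touching but half-open disjoint: removed
  expect_equal(nrow(filter_by_region(sites, tree_of(70, 90), filt)), 0)
})

test_that("TSS windows anchor strand-aware and site counts shrink monotonically under flags", {
  fx <- make_genome_fixture(fixture_spec(rng_seed = 4))
  tree <- annotation_tree(fx$features)
  sites <- scan_targets(fx$genome, "chr1")

  n_all <- nrow(sites)
  n_exon <- nrow(filter_by_region(sites, tree, region_filter(exon_only = TRUE)))
  n_exon_cds <- nrow(filter_by_region(sites, tree,
                                      region_filter(exon_only = TRUE,
                                                    cds_only = TRUE)))
  expect_lte(n_exon, n_all)
  expect_lte(n_exon_cds, n_exon)

  # minus-strand transcript: window [-50, +300) extends leftward from the
  # transcript's highest coordinate
  tx <- fx$features[fx$features$feature_type == "transcript" &
                      fx$features$strand == "-", ][1, ]
  tss <- tx$end - 1L
  got <- filter_by_region(sites, tree, region_filter(tss_window = c(-50, 300)))
  want_lo <- tss - 300 + 1   # half-open strand-aware window in + coords
  want_hi <- tss + 50 + 1
  in_minus_win <- got[got$proto_start < want_hi & got$proto_end > want_lo, ]
  # every site selected near this transcript must intersect the window
  near <- got[got$proto_end > tx$start - 400 & got$proto_start < tx$end + 400, ]
  if (nrow(near) > 0) {
    expect_true(all(near$proto_start < want_hi & near$proto_end > want_lo |
                      near$proto_end <= tx$start | near$proto_start >= tx$end + 400))
  }
  # and the plus-strand transcript window covers sites right of its TSS
  txp <- fx$features[fx$features$feature_type == "transcript" &
                       fx$features$strand == "+", ][1, ]
  expect_true(any(got$proto_start >= txp$start - 50 &
                    got$proto_start < txp$start + 300))
})

test_that("region scan attributes sites to the scanned gene; shared sites duplicate per gene", {
  g <- random_genome(400, seed = 21)
  regions <- tibble::tibble(chrom = "chr1",
                            start = c(0L, 100L), end = c(250L, 400L),
                            gene_id = c("gA", "gB"))
  sites <- scan_regions(g, regions)
  both <- sites |>
    dplyr::count(chrom, proto_start, strand) |>
    dplyr::filter(n == 2)
  # any site fully inside the shared region [100,250) appears for both genes
  shared <- sites[sites$start >= 100 & sites$end <= 250, ]
  if (nrow(shared) > 0) {
    expect_setequal(unique(shared$gene_id), c("gA", "gB"))
    expect_gt(nrow(both), 0)
  }
})
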