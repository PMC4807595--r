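#' Specification of a deterministic toy-genome fixture
#'
#' The generator plants protospacer+PAM sites inside gene exons and optional
#' mismatched copies (off-targets) elsewhere, on a random background that is
#' rejected and regenerated if it accidentally duplicates a planted
#' protospacer — so planted truth counts are exact. Everything is a pure
#' function of `rng_seed`.
#'
#' @param rng_seed Integer seed.
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Length of each chromosome (nt).
#' @param genes List of per-gene descriptions: each a list with `n_exons`
#'   (int), `strand` (`"+"`/`"-"`), and optional `exon_width`, `intron_width`.
#'   Default: two genes of 3 exons, one per strand.
#' @param planted_pam_sites Guaranteed NGG protospacers planted per gene
#'   (default 2).
#' @param planted_offtargets List of off-target plants: each a list with
#'   `site` (index into the planted-site truth table), `mismatches` (int),
#'   and optional `pam` (default `"TGG"`). Positions are chosen in free
#'   intergenic space.
#' @param cpg_islands Number of CpG-island features to annotate over the
#'   first exon of each of this many genes (default 0).
#' @param mismatch_positions Where planted mismatches go, as 1-based
#'   protospacer positions to draw from (default 1:16, the region evaluated
#'   under the published library policy of 4-nt 3' trimming).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(rng_seed = 1L, n_chroms = 1L, chrom_length = 5000L,
                         genes = NULL, planted_pam_sites = 2L,
                         planted_offtargets = list(), cpg_islands = 0L,
                         mismatch_positions = 1:16) {
  if (is.null(genes)) {
    genes <- list(list(n_exons = 3L, strand = "+"),
                  list(n_exons = 3L, strand = "-"))
  }
  structure(list(
    rng_seed = assert_count(rng_seed, "rng_seed", 0L),
    n_chroms = assert_count(n_chroms, "n_chroms", 1L),
    chrom_length = assert_count(chrom_length, "chrom_length", 500L),
    genes = genes,
    planted_pam_sites = assert_count(planted_pam_sites, "planted_pam_sites", 0L),
    planted_offtargets = planted_offtargets,
    cpg_islands = assert_count(cpg_islands, "cpg_islands", 0L),
    mismatch_positions = mismatch_positions
  ), class = "fixture_spec")
}

# count genomic windows within `maxmm` mismatches of `proto` on both strands
# (simple vectorized scan; used only to certify planted truth)
count_near_matches <- function(genome, proto, maxmm) {
  total <- 0L
  for (q in c(proto, revcomp(proto))) {
    qi <- utf8ToInt(q)
    m <- length(qi)
    for (chrom in names(genome$seq)) {
      gi <- utf8ToInt(genome$seq[[chrom]])
      L <- length(gi)
      if (L < m) next
      n <- L - m + 1L
      mm <- integer(n)
      for (j in seq_len(m)) mm <- mm + (gi[j:(j + n - 1L)] != qi[j])
      total <- total + sum(mm <= maxmm)
    }
  }
  total
}

#' Generate a toy genome with planted sites, annotations, and truth tables
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional directory: when given, writes `genome.fa`,
#'   `annotation.gff3`, `truth_sites.tsv`, `truth_offtargets.tsv`.
#' @param max_attempts Background regeneration attempts before giving up.
#' @return List: `genome` (genome_assembly), `features` (annotation tibble),
#'   `truth_sites`, `truth_offtargets` (tibbles), `paths` (if written).
#' @export
make_genome_fixture <- function(spec, dir = NULL, max_attempts = 25L) {
  stopifnot(inherits(spec, "fixture_spec"))
  for (attempt in seq_len(max_attempts)) {
    res <- withr::with_seed(spec$rng_seed + (attempt - 1L) * 100003L,
                            build_fixture_once(spec))
    if (!is.null(res)) break
    res <- NULL
  }
  if (is.null(res)) stop("could not build a collision-free fixture genome")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(genome = file.path(dir, "genome.fa"),
               annotation = file.path(dir, "annotation.gff3"),
               truth_sites = file.path(dir, "truth_sites.tsv"),
               truth_offtargets = file.path(dir, "truth_offtargets.tsv"))
    write_genome(res$genome, paths[["genome"]])
    write_fixture_gff(res$features, paths[["annotation"]])
    utils::write.table(res$truth_sites, paths[["truth_sites"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(res$truth_offtargets, paths[["truth_offtargets"]],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    res$paths <- paths
  }
  res
}

build_fixture_once <- function(spec) {
  L <- spec$chrom_length
  chroms <- paste0("chr", seq_len(spec$n_chroms))
  seqs <- stats::setNames(random_dna(spec$n_chroms, L), chroms)

  feats <- list(); truth_sites <- list(); planted <- character()
  cursor <- stats::setNames(rep(200L, spec$n_chroms), chroms)

  for (gi in seq_along(spec$genes)) {
    g <- spec$genes[[gi]]
    chrom <- chroms[((gi - 1L) %% spec$n_chroms) + 1L]
    exon_w <- g$exon_width %||% 150L
    intron_w <- g$intron_width %||% 100L
    n_ex <- g$n_exons
    gene_id <- sprintf("gene%02d", gi)
    tx_id <- paste0(gene_id, ".t1")
    gstart <- cursor[[chrom]]
    gend <- gstart + n_ex * exon_w + (n_ex - 1L) * intron_w
    if (gend + 200L > L) return(NULL)  # spec too large for the chromosome
    cursor[[chrom]] <- gend + 400L

    ex_starts <- gstart + (seq_len(n_ex) - 1L) * (exon_w + intron_w)
    ex_ends <- ex_starts + exon_w
    # strand-aware exon numbering: exon 1 is 5'-most
    exno <- if (identical(g$strand, "-")) rev(seq_len(n_ex)) else seq_len(n_ex)

    feats[[length(feats) + 1L]] <- tibble::tibble(
      chrom = chrom,
      start = c(gstart, gstart, ex_starts, ex_starts),
      end = c(gend, gend, ex_ends, ex_ends),
      strand = g$strand,
      feature_type = c("gene", "transcript", rep("exon", n_ex),
                       rep("cds", n_ex)),
      gene_id = gene_id,
      transcript_id = c(NA, tx_id, rep(tx_id, 2L * n_ex)),
      exon_number = c(NA_integer_, NA_integer_, exno, exno)
    )

    # plant NGG protospacers inside exons (plus strand, non-overlapping)
    n_plant <- spec$planted_pam_sites
    for (p in seq_len(n_plant)) {
      ex <- ((p - 1L) %% n_ex) + 1L
      pos <- ex_starts[ex] + 10L + ((p - 1L) %/% n_ex) * 40L  # 0-based
      proto <- plant_protospacer()
      substr(seqs[[chrom]], pos + 1L, pos + 23L) <- paste0(proto, "AGG")
      planted <- c(planted, proto)
      truth_sites[[length(truth_sites) + 1L]] <- tibble::tibble(
        site_id = length(truth_sites) + 1L, chrom = chrom,
        proto_start = pos, strand = "+", protospacer = proto, pam = "AGG",
        gene_id = gene_id, exon_number = exno[ex])
    }
  }
  truth_sites <- dplyr::bind_rows(truth_sites)
  feats <- dplyr::bind_rows(feats)

  # CpG-island features over the first exons of the first `cpg_islands` genes
  if (spec$cpg_islands > 0) {
    first_ex <- feats |>
      dplyr::filter(.data$feature_type == "exon", .data$exon_number == 1L) |>
      dplyr::distinct(.data$gene_id, .keep_all = TRUE) |>
      utils::head(spec$cpg_islands)
    feats <- dplyr::bind_rows(feats, tibble::tibble(
      chrom = first_ex$chrom, start = first_ex$start, end = first_ex$end,
      strand = "+", feature_type = "cpg_island", gene_id = NA_character_,
      transcript_id = NA_character_, exon_number = NA_integer_))
  }

  # plant off-target copies in intergenic space near the chromosome tails
  truth_ot <- list()
  ot_cursor <- stats::setNames(spec$chrom_length - 300L, chroms[1])
  for (chrom in chroms) ot_cursor[[chrom]] <- spec$chrom_length - 300L
  for (oi in seq_along(spec$planted_offtargets)) {
    ot <- spec$planted_offtargets[[oi]]
    src <- truth_sites[ot$site, ]
    chrom <- ot$chrom %||% src$chrom
    pos <- ot$pos %||% {
      p <- ot_cursor[[chrom]]
      ot_cursor[[chrom]] <- ot_cursor[[chrom]] - 40L
      p
    }
    if (pos < 0 || pos + 23L > L) return(NULL)
    proto <- src$protospacer
    d <- ot$mismatches %||% 0L
    if (d > 0) {
      mut_at <- sample(spec$mismatch_positions, d)
      ch <- strsplit(proto, "")[[1]]
      for (mp in mut_at) {
        ch[mp] <- sample(setdiff(c("A", "C", "G", "T"), ch[mp]), 1)
      }
      proto <- paste0(ch, collapse = "")
    }
    pam <- ot$pam %||% "TGG"
    substr(seqs[[chrom]], pos + 1L, pos + 23L) <- paste0(proto, pam)
    truth_ot[[length(truth_ot) + 1L]] <- tibble::tibble(
      site_id = ot$site, chrom = chrom, proto_start = pos, strand = "+",
      sequence = proto, pam = pam, mismatches = as.integer(d))
  }
  truth_ot <- if (length(truth_ot)) dplyr::bind_rows(truth_ot) else
    tibble::tibble(site_id = integer(), chrom = character(),
                   proto_start = integer(), strand = character(),
                   sequence = character(), pam = character(),
                   mismatches = integer())

  genome <- genome_assembly(seqs)

  # certify planted truth: each planted protospacer must occur exactly once
  # at distance 0 plus its planted mismatched copies, nothing accidental
  for (i in seq_len(nrow(truth_sites))) {
    proto <- truth_sites$protospacer[i]
    exact_expected <- 1L + sum(truth_ot$site_id == i & truth_ot$mismatches == 0L)
    if (count_near_matches(genome, proto, 0L) != exact_expected) return(NULL)
    d_planted <- truth_ot$mismatches[truth_ot$site_id == i]
    maxd <- max(c(3L, d_planted))
    near_expected <- 1L + sum(d_planted <= maxd)
    if (count_near_matches(genome, proto, maxd) != near_expected) return(NULL)
  }
  list(genome = genome, features = feats, truth_sites = truth_sites,
       truth_offtargets = truth_ot)
}

# a random protospacer safe for planting: no TTTTT, no N, doesn't start
# or end in a way that creates accidental PAMs is not required (scan finds
# all sites anyway); truth only needs the planted one present
plant_protospacer <- function() {
  repeat {
    p <- random_dna(1L, 20L)
    if (!grepl("TTTTT", p, fixed = TRUE)) return(p)
  }
}

write_fixture_gff <- function(features, path) {
  type_out <- features$feature_type
  type_out[type_out == "cds"] <- "CDS"
  attrs <- sprintf("gene_id=%s;transcript_id=%s;exon_number=%s",
                   ifelse(is.na(features$gene_id), ".", features$gene_id),
                   ifelse(is.na(features$transcript_id), ".",
                          features$transcript_id),
                   ifelse(is.na(features$exon_number), ".",
                          features$exon_number))
  # omit placeholder attributes
  attrs <- gsub(";?[a-z_]+=\\.(;|$)", "\\1", attrs)
  attrs <- sub(";$", "", attrs)
  attrs[!nzchar(attrs)] <- "."
  lines <- sprintf("%s\tguidelib_fixture\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   features$chrom, type_out, features$start + 1L,
                   features$end, features$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Simulate pooled-screen reads with planted effects
#'
#' Builds per-sample guide abundances (multinomial draws over lognormal base
#' weights, with per-gene treated-arm effect multipliers) and writes FASTQ
#' reads of the form `flank + ACCG + protospacer + TTT + AGAGC + flank`.
#' Guides of genes absent from `effects` and all non-targeting controls have
#' effect 1 (no change).
#'
#' @param library Tibble with `design_id`, `gene_id`, `protospacer`
#'   (non-targeting controls carry `gene_id = NA`).
#' @param effects Named numeric vector: treated/control fold change per
#'   gene_id (e.g. `c(geneA = 4)`).
#' @param reads_per_guide Expected sequencing depth per guide per sample
#'   (default 500).
#' @param n_replicates Replicates per arm (default 2).
#' @param rng_seed Integer seed (default 7).
#' @param dir Directory for FASTQ files; `NULL` skips writing and returns
#'   counts only.
#' @return List: `counts` (wide tibble, samples `treated1..`, `control1..`),
#'   `truth` (per-gene expected log2 effects), `fastqs` (named paths, if
#'   written), `samples` (list with `treated`, `control` names).
#' @export
make_screen_fixture <- function(library, effects = c(), reads_per_guide = 500L,
                                n_replicates = 2L, rng_seed = 7L, dir = NULL) {
  stopifnot(all(c("design_id", "gene_id", "protospacer") %in% names(library)))
  n <- nrow(library)
  reads_total <- n * assert_count(reads_per_guide, "reads_per_guide", 1L)
  treated_names <- paste0("treated", seq_len(n_replicates))
  control_names <- paste0("control", seq_len(n_replicates))
  res <- withr::with_seed(rng_seed, {
    base_w <- stats::rlnorm(n, meanlog = 0, sdlog = 0.25)
    eff <- rep(1, n)
    if (length(effects) > 0) {
      hit <- library$gene_id %in% names(effects)
      eff[hit] <- effects[library$gene_id[hit]]
    }
    counts <- tibble::tibble(design_id = library$design_id)
    for (s in control_names) {
      counts[[s]] <- as.integer(stats::rmultinom(1, reads_total,
                                                 base_w / sum(base_w)))
    }
    tw <- base_w * eff
    for (s in treated_names) {
      counts[[s]] <- as.integer(stats::rmultinom(1, reads_total, tw / sum(tw)))
    }
    counts
  })
  truth <- tibble::tibble(
    gene_id = names(effects) %||% character(),
    true_log2_effect = if (length(effects)) log2(unname(effects)) else numeric()
  )
  out <- list(counts = res, truth = truth,
              samples = list(treated = treated_names, control = control_names))
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- character()
    for (s in c(treated_names, control_names)) {
      path <- file.path(dir, paste0(s, ".fastq"))
      write_sample_fastq(library$protospacer, res[[s]], path,
                         seed = rng_seed + match(s, c(treated_names,
                                                      control_names)))
      paths[[s]] <- path
    }
    out$fastqs <- paths
  }
  out
}

# reads in deterministic order with fixed random flanks per sample
write_sample_fastq <- function(protospacers, counts, path, seed) {
  total <- sum(counts)
  withr::with_seed(seed, {
    flank5 <- random_dna(total, 6L)
    flank3 <- random_dna(total, 6L)
  })
  inserts <- rep(protospacers, counts)
  reads <- paste0(flank5, "ACCG", inserts, "TTT", "AGAGC", flank3)
  qual <- strrep("I", nchar(reads))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0("@read", seq_len(total)), reads,
                             "+", qual)), con)
  invisible(path)
}
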