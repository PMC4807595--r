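#' Describe a PAM requirement
#'
#' @param pattern IUPAC pattern of the PAM, e.g. `"NGG"` (SpCas9) or
#'   `"TTTN"` (Cpf1-style).
#' @param side `"3prime"` if the PAM follows the protospacer (Cas9),
#'   `"5prime"` if it precedes it (Cpf1-style).
#' @param protospacer_length Protospacer length in nt (default 20).
#' @return A `pam_spec` list.
#' @export
pam_spec <- function(pattern = "NGG", side = c("3prime", "5prime"),
                     protospacer_length = 20L) {
  side <- match.arg(side)
  pattern <- toupper(pattern)
  bad <- setdiff(strsplit(pattern, "")[[1]], names(IUPAC_CLASSES))
  if (!nzchar(pattern) || length(bad) > 0) {
    stop("PAM pattern must be a nonempty IUPAC string")
  }
  protospacer_length <- assert_count(protospacer_length, "protospacer_length", 1L)
  structure(list(pattern = pattern, side = side,
                 protospacer_length = protospacer_length),
            class = "pam_spec")
}

# all start positions (0-based) of IUPAC `pattern` in `seqchar`,
# overlapping matches included
match_pam_positions <- function(seqchar, pattern) {
  subject <- Biostrings::DNAString(seqchar)
  m <- Biostrings::matchPattern(pattern, subject, fixed = FALSE)
  Biostrings::start(m) - 1L
}

#' Scan a region for candidate protospacer + PAM sites
#'
#' Enumerates, on both strands, every protospacer whose adjacent PAM matches
#' the IUPAC pattern and whose full protospacer lies inside the chromosome.
#' Minus-strand sites report the reverse-complemented, 5'->3' protospacer and
#' PAM. Protospacers containing `N` are excluded; protospacers containing the
#' RNA-polymerase terminator motif `TTTTT` are excluded when
#' `exclude_polyT = TRUE`. Each site carries, when the chromosome permits,
#' a 30-nt strand-oriented context window spanning PAM-24 .. PAM+6 (4 nt
#' 5' flank, 20 nt protospacer, 3 nt PAM, 3 nt 3' flank for the default
#' Cas9 geometry) used by context-dependent on-target scores.
#'
#' @param genome A `genome_assembly`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open region to scan (defaults: whole
#'   chromosome).
#' @param pam A [pam_spec()].
#' @param exclude_polyT Drop protospacers containing `TTTTT` (default TRUE).
#' @param gene_id Identifier recorded on every emitted site (the gene whose
#'   region is being scanned), default `NA`.
#' @return Tibble of candidate sites: `chrom`, `start`, `end` (full
#'   protospacer+PAM span), `strand`, `proto_start`, `proto_end`
#'   (protospacer span), `protospacer`, `pam`, `context30`, `gene_id`.
#' @export
scan_targets <- function(genome, chrom, start = 0L, end = NULL,
                         pam = pam_spec("NGG"), exclude_polyT = TRUE,
                         gene_id = NA_character_) {
  stopifnot(inherits(genome, "genome_assembly"), inherits(pam, "pam_spec"))
  if (!chrom %in% names(genome$seq)) stop("unknown chromosome: ", chrom)
  clen <- genome$lengths[[chrom]]
  if (is.null(end)) end <- clen
  if (start < 0 || end > clen || start >= end) {
    stop(sprintf("region [%s,%s) out of bounds for %s (length %d)",
                 start, end, chrom, clen))
  }
  plen <- pam$protospacer_length
  pamlen <- nchar(pam$pattern)
  pside <- pam$side
  region <- genome_seq(genome, chrom, start, end)

  # PAM occurrences: pattern on + strand, its reverse complement on the +
  # strand text marks minus-strand PAMs
  pos_fwd <- match_pam_positions(region, pam$pattern) + start
  pos_rev <- match_pam_positions(region, revcomp(pam$pattern)) + start

  chromseq <- genome$seq[[chrom]]
  sub0 <- function(s, from, to) substring(s, from + 1L, to)  # 0-based half-open

  rows <- list()
  if (length(pos_fwd) > 0) {
    if (pam$side == "3prime") {
      ps <- pos_fwd - plen; pe <- pos_fwd
      site_s <- ps; site_e <- pos_fwd + pamlen
    } else {
      ps <- pos_fwd + pamlen; pe <- ps + plen
      site_s <- pos_fwd; site_e <- pe
    }
    keep <- ps >= 0 & site_e <= clen
    if (any(keep)) {
      ps <- ps[keep]; pe <- pe[keep]
      site_s <- site_s[keep]; site_e <- site_e[keep]
      pam_s <- pos_fwd[keep]
      rows$fwd <- tibble::tibble(
        chrom = chrom, start = site_s, end = site_e, strand = "+",
        proto_start = ps, proto_end = pe,
        protospacer = sub0(chromseq, ps, pe),
        pam = sub0(chromseq, pam_s, pam_s + pamlen),
        context30 = context30_plus(chromseq, pam_s, pside, clen)
      )
    }
  }
  if (length(pos_rev) > 0) {
    # rc(pattern) match at q..q+pamlen on + text; on the minus strand the
    # protospacer lies 3' of that PAM for side == "3prime"
    q <- pos_rev
    if (pam$side == "3prime") {
      ps <- q + pamlen; pe <- ps + plen        # + coords of protospacer
      site_s <- q; site_e <- pe
    } else {
      ps <- q - plen; pe <- q
      site_s <- ps; site_e <- q + pamlen
    }
    keep <- ps >= 0 & site_e <= clen & site_s >= 0 & pe <= clen
    if (any(keep)) {
      ps <- ps[keep]; pe <- pe[keep]
      site_s <- site_s[keep]; site_e <- site_e[keep]
      q <- q[keep]
      rows$rev <- tibble::tibble(
        chrom = chrom, start = site_s, end = site_e, strand = "-",
        proto_start = ps, proto_end = pe,
        protospacer = revcomp(sub0(chromseq, ps, pe)),
        pam = revcomp(sub0(chromseq, q, q + pamlen)),
        context30 = context30_minus(chromseq, q, pamlen, pside, clen)
      )
    }
  }
  sites <- dplyr::bind_rows(rows)
  if (nrow(sites) == 0L) return(empty_sites(gene_id))
  sites$gene_id <- gene_id
  sites <- dplyr::filter(sites, !grepl("N", .data$protospacer, fixed = TRUE))
  if (exclude_polyT) {
    sites <- dplyr::filter(sites, !grepl("TTTTT", .data$protospacer, fixed = TRUE))
  }
  dplyr::arrange(sites, .data$proto_start, .data$strand)
}

# strand-oriented 30-mer context for a plus-strand site, NA near contig edges
context30_plus <- function(chromseq, pam_start, side, clen) {
  if (side != "3prime") return(rep(NA_character_, length(pam_start)))
  s <- pam_start - 24L
  e <- pam_start + 6L
  ok <- s >= 0 & e <= clen
  out <- rep(NA_character_, length(pam_start))
  out[ok] <- substr(rep(chromseq, sum(ok)), s[ok] + 1L, e[ok])
  out
}

context30_minus <- function(chromseq, q, pamlen, side, clen) {
  if (side != "3prime") return(rep(NA_character_, length(q)))
  s <- q + pamlen - 6L
  e <- q + pamlen + 24L
  ok <- s >= 0 & e <= clen
  out <- rep(NA_character_, length(q))
  out[ok] <- revcomp(substr(rep(chromseq, sum(ok)), s[ok] + 1L, e[ok]))
  out
}

empty_sites <- function(gene_id = character()) {
  tibble::tibble(chrom = character(), start = integer(), end = integer(),
                 strand = character(), proto_start = integer(),
                 proto_end = integer(), protospacer = character(),
                 pam = character(), context30 = character(),
                 gene_id = character())
}

#' Scan several gene regions in one call
#'
#' Tidy wrapper around [scan_targets()]: one row per region in, candidate
#' sites for all regions out. A site reachable from two genes' regions is
#' reported once per gene (distinct `gene_id`).
#'
#' @param genome A `genome_assembly`.
#' @param regions Tibble with columns `chrom`, `start`, `end` and optionally
#'   `gene_id`.
#' @inheritParams scan_targets
#' @return Tibble of candidate sites (see [scan_targets()]).
#' @export
scan_regions <- function(genome, regions, pam = pam_spec("NGG"),
                         exclude_polyT = TRUE) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  if (!"gene_id" %in% names(regions)) {
    regions$gene_id <- paste0("region_", seq_len(nrow(regions)))
  }
  purrr::pmap_dfr(
    regions[, c("chrom", "start", "end", "gene_id")],
    function(chrom, start, end, gene_id) {
      scan_targets(genome, chrom, start, end, pam = pam,
                   exclude_polyT = exclude_polyT, gene_id = gene_id)
    }
  )
}

#' Region filter for candidate sites
#'
#' @param cds_only Require overlap with a coding sequence.
#' @param exon_only Require overlap with an exon.
#' @param start_codon,stop_codon Require overlap with the named codon feature.
#' @param tss_window Require overlap with a window around a transcription
#'   start site (for CRISPRi/CRISPRa); `NULL` (off) or length-2 numeric
#'   `c(lower, upper)` of signed strand-aware offsets, half-open
#'   `[TSS+lower, TSS+upper)`.
#' @return A `region_filter` list.
#' @export
region_filter <- function(cds_only = FALSE, exon_only = FALSE,
                          start_codon = FALSE, stop_codon = FALSE,
                          tss_window = NULL) {
  if (!is.null(tss_window)) {
    stopifnot(is.numeric(tss_window), length(tss_window) == 2L,
              tss_window[1] < tss_window[2])
  }
  flags <- c(cds_only = cds_only, exon_only = exon_only,
             start_codon = start_codon, stop_codon = stop_codon,
             tss_window = !is.null(tss_window))
  if (!any(flags)) stop("region_filter: at least one mode must be active")
  structure(list(cds_only = cds_only, exon_only = exon_only,
                 start_codon = start_codon, stop_codon = stop_codon,
                 tss_window = tss_window),
            class = "region_filter")
}

#' Keep candidate sites overlapping required feature classes
#'
#' A site is kept iff its protospacer interval has a nonempty intersection
#' with at least one qualifying feature for every active filter mode. The
#' TSS window is strand-aware: on a minus-strand transcript it anchors at the
#' transcript's highest coordinate and extends leftward.
#'
#' @param sites Candidate-site tibble from [scan_targets()].
#' @param tree An [annotation_tree()].
#' @param filter A [region_filter()].
#' @return The filtered site tibble.
#' @export
filter_by_region <- function(sites, tree, filter) {
  stopifnot(inherits(tree, "annotation_tree"), inherits(filter, "region_filter"))
  if (nrow(sites) == 0L) return(sites)
  keep <- rep(TRUE, nrow(sites))

  overlap_any <- function(feat_idx) {
    if (length(feat_idx) == 0L) return(rep(FALSE, nrow(sites)))
    sub <- tree$features[feat_idx, , drop = FALSE]
    subtree <- annotation_tree(sub)
    pairs <- query_overlaps_many(subtree, sites$chrom, sites$proto_start,
                                 sites$proto_end)
    seq_len(nrow(sites)) %in% pairs$query
  }

  types <- tree$features$feature_type
  if (filter$cds_only) keep <- keep & overlap_any(which(types == "cds"))
  if (filter$exon_only) keep <- keep & overlap_any(which(types == "exon"))
  if (filter$start_codon) keep <- keep & overlap_any(which(types == "start_codon"))
  if (filter$stop_codon) keep <- keep & overlap_any(which(types == "stop_codon"))
  if (!is.null(filter$tss_window)) {
    tx <- dplyr::filter(tree$features, .data$feature_type == "transcript")
    if (nrow(tx) == 0L) {
      keep <- keep & FALSE
    } else {
      lo <- filter$tss_window[1]; up <- filter$tss_window[2]
      win <- dplyr::mutate(
        tx,
        tss = ifelse(.data$strand == "-", .data$end - 1L, .data$start),
        wstart = ifelse(.data$strand == "-", .data$tss - up + 1L, .data$tss + lo),
        wend = ifelse(.data$strand == "-", .data$tss - lo + 1L, .data$tss + up)
      )
      win <- dplyr::filter(win, .data$wend > .data$wstart)
      wtree <- annotation_tree(tibble::tibble(
        chrom = win$chrom, start = as.integer(win$wstart),
        end = as.integer(win$wend), strand = win$strand,
        feature_type = "tss_window", gene_id = win$gene_id,
        transcript_id = win$transcript_id, exon_number = NA_integer_
      ))
      pairs <- query_overlaps_many(wtree, sites$chrom, sites$proto_start,
                                   sites$proto_end)
      keep <- keep & (seq_len(nrow(sites)) %in% pairs$query)
    }
  }
  sites[keep, , drop = FALSE]
}
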