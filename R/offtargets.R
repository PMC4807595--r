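#' Off-target search policy
#'
#' Controls the mismatch-tolerant genome search that replaces an external
#' short-read aligner. The protospacer is trimmed by `trim_3prime` bases at
#' its 3' end and masked by `ignore_5prime` bases at its 5' end before
#' mapping; the remaining query must match with at most `max_mismatches`
#' mismatches and be adjacent to one of `allowed_pams` with zero PAM
#' mismatches.
#'
#' @param max_mismatches Maximum mismatches in the evaluated query
#'   (default 3; `sensitivity = "low"` caps this at 1).
#' @param ignore_5prime Number of 5' protospacer bases excluded from the
#'   homology evaluation (default 0).
#' @param trim_3prime Number of 3' protospacer bases removed before mapping
#'   (default 0; the published human library run used 4).
#' @param allowed_pams Character vector of concrete PAM strings a hit must be
#'   followed by. Default: all NGG and NAG trinucleotides.
#' @param max_hits_reported Cap on reported off-targets, best (most
#'   homologous) first (default 30).
#' @param sensitivity `"high"` (use `max_mismatches`) or `"low"` (at most 1
#'   mismatch).
#' @return A `search_policy` list.
#' @export
search_policy <- function(max_mismatches = 3L, ignore_5prime = 0L,
                          trim_3prime = 0L,
                          allowed_pams = c(iupac_expand("NGG"),
                                           iupac_expand("NAG")),
                          max_hits_reported = 30L,
                          sensitivity = c("high", "low")) {
  sensitivity <- match.arg(sensitivity)
  max_mismatches <- assert_count(max_mismatches, "max_mismatches", 0L)
  ignore_5prime <- assert_count(ignore_5prime, "ignore_5prime", 0L)
  trim_3prime <- assert_count(trim_3prime, "trim_3prime", 0L)
  max_hits_reported <- assert_count(max_hits_reported, "max_hits_reported", 1L)
  if (!is.null(allowed_pams)) {
    allowed_pams <- toupper(allowed_pams)
    if (length(allowed_pams) == 0 || any(grepl("[^ACGT]", allowed_pams))) {
      stop("allowed_pams must be concrete ACGT strings (see iupac_expand())")
    }
  }
  structure(list(max_mismatches = max_mismatches,
                 ignore_5prime = ignore_5prime,
                 trim_3prime = trim_3prime,
                 allowed_pams = allowed_pams,
                 max_hits_reported = max_hits_reported,
                 sensitivity = sensitivity),
            class = "search_policy")
}

#' Build an exact k-mer seed index over a genome
#'
#' Indexes every k-mer of the forward strand of each chromosome; minus-strand
#' occurrences are retrieved by looking up the reverse complement of a query.
#' The index backs the pigeonhole seed-and-verify off-target search.
#'
#' @param genome A `genome_assembly`.
#' @param k Seed length, 4..16 (default 4; must not exceed the shortest
#'   pigeonhole chunk of any query you intend to search).
#' @return A `seed_index` object.
#' @export
build_seed_index <- function(genome, k = 4L) {
  stopifnot(inherits(genome, "genome_assembly"))
  k <- assert_count(k, "k", 4L)
  if (k > 16L) stop("k must be <= 16")
  chroms <- names(genome$seq)
  per_chrom <- lapply(chroms, function(chrom) {
    s <- genome$seq[[chrom]]
    L <- nchar(s)
    if (L < k) return(list(env = new.env(parent = emptyenv()),
                           ints = utf8ToInt(s), length = L))
    starts <- seq_len(L - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    env <- list2env(split(starts - 1L, kmers), parent = emptyenv())  # 0-based
    list(env = env, ints = utf8ToInt(s), length = L)
  })
  names(per_chrom) <- chroms
  structure(list(k = k, chroms = per_chrom), class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  cat("<seed_index> k=", x$k, ", ", length(x$chroms), " chromosome(s)\n",
      sep = "")
  invisible(x)
}

#' Look up all genomic occurrences of a k-mer
#'
#' Returns forward-strand start positions of `kmer` and, as minus-strand
#' entries, forward-strand start positions of its reverse complement.
#'
#' @param index A `seed_index`.
#' @param kmer ACGT string of length `index$k`.
#' @return Tibble with `chrom`, `start` (0-based, on the forward strand) and
#'   `strand`.
#' @export
lookup_kmer <- function(index, kmer) {
  stopifnot(inherits(index, "seed_index"), nchar(kmer) == index$k)
  rc <- revcomp(kmer)
  rows <- list()
  for (chrom in names(index$chroms)) {
    env <- index$chroms[[chrom]]$env
    fwd <- env[[kmer]] %||% integer()
    rev <- env[[rc]] %||% integer()
    if (length(fwd)) rows[[paste0(chrom, "+")]] <-
      tibble::tibble(chrom = chrom, start = fwd, strand = "+")
    if (length(rev)) rows[[paste0(chrom, "-")]] <-
      tibble::tibble(chrom = chrom, start = rev, strand = "-")
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          strand = character()))
  }
  dplyr::bind_rows(rows)
}

# contiguous pigeonhole chunks: mm+1 chunks covering 1..m, lengths as equal
# as possible. A window with <= mm mismatches leaves at least one chunk
# mismatch-free, so looking up each chunk's k-prefix finds every true hit.
pigeonhole_chunks <- function(m, mm) {
  n <- mm + 1L
  sizes <- rep(m %/% n, n)
  extra <- m %% n
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  starts <- cumsum(c(1L, sizes[-n]))
  tibble::tibble(start = starts, size = sizes)
}

# mismatch counts of `qints` against windows of chromosome int vector at
# 0-based starts `pos` (all windows assumed in bounds)
window_mismatches <- function(ints, pos, qints) {
  m <- length(qints)
  idx <- outer(seq_len(m), pos, FUN = "+")  # pos is 0-based: row j -> pos+j
  colSums(matrix(ints[idx], nrow = m) != qints)
}

# core engine: all loci where `query` (plain ACGT) matches the genome with
# <= mm mismatches on either strand. Returns 0-based query-window starts on
# the forward strand plus the strand of the protospacer-equivalent locus.
seed_search <- function(index, query, mm) {
  k <- index$k
  m <- nchar(query)
  chunks <- pigeonhole_chunks(m, mm)
  if (min(chunks$size) < k) {
    stop(sprintf(
      "query too short for pigeonhole search: %d nt over %d chunks gives a chunk of %d < seed length %d",
      m, mm + 1L, min(chunks$size), k))
  }
  queries <- c(`+` = query, `-` = rc1(query))
  chrom_v <- character(); start_v <- integer()
  strand_v <- character(); mm_v <- integer()
  for (strand in names(queries)) {
    q <- queries[[strand]]
    qints <- utf8ToInt(q)
    seeds <- substring(q, chunks$start, chunks$start + k - 1L)
    offsets <- chunks$start - 1L  # 0-based offset of each chunk in the query
    for (chrom in names(index$chroms)) {
      ci <- index$chroms[[chrom]]
      L <- ci$length
      cand <- integer()
      for (j in seq_along(seeds)) {
        hits <- ci$env[[seeds[j]]]
        if (!is.null(hits)) cand <- c(cand, hits - offsets[j])
      }
      cand <- unique(cand)
      cand <- cand[cand >= 0 & cand + m <= L]
      if (length(cand) == 0L) next
      mmc <- window_mismatches(ci$ints, cand, qints)
      ok <- mmc <= mm
      if (any(ok)) {
        chrom_v <- c(chrom_v, rep(chrom, sum(ok)))
        start_v <- c(start_v, cand[ok])
        strand_v <- c(strand_v, rep(strand, sum(ok)))
        mm_v <- c(mm_v, as.integer(mmc[ok]))
      }
    }
  }
  tibble::tibble(chrom = chrom_v, win_start = start_v, strand = strand_v,
                 mismatch_count = mm_v)
}

# boolean fast path: does `query` align anywhere under `mm` mismatches?
# Same pigeonhole guarantee as seed_search, early exit, no allocation of
# result containers (used by the non-targeting rejection sampler).
seed_search_any <- function(index, query, query_rc, mm) {
  k <- index$k
  m <- nchar(query)
  chunks <- pigeonhole_chunks(m, mm)
  if (min(chunks$size) < k) {
    stop("query too short for pigeonhole search at seed length ", k)
  }
  starts <- chunks$start
  for (q in c(query, query_rc)) {
    qints <- utf8ToInt(q)
    seeds <- substring(q, starts, starts + k - 1L)
    for (chrom in names(index$chroms)) {
      ci <- index$chroms[[chrom]]
      L <- ci$length
      cand <- integer()
      for (j in seq_along(seeds)) {
        hits <- ci$env[[seeds[j]]]
        if (!is.null(hits)) cand <- c(cand, hits - starts[j] + 1L)
      }
      if (length(cand) == 0L) next
      cand <- unique(cand)
      cand <- cand[cand >= 0 & cand + m <= L]
      if (length(cand) == 0L) next
      if (any(window_mismatches(ci$ints, cand, qints) <= mm)) return(TRUE)
    }
  }
  FALSE
}

#' Find genome-wide off-targets of a candidate site
#'
#' Pigeonhole seed-and-verify search: the evaluated query (protospacer minus
#' `trim_3prime` 3' bases and `ignore_5prime` 5' bases) is split into
#' `max_mismatches + 1` contiguous chunks; any true hit leaves one chunk
#' exact, so exact seed lookups followed by full-window verification
#' enumerate every locus within the mismatch budget — the result is
#' set-identical to an exhaustive scan. Hits must be adjacent to one of the
#' policy's PAMs with zero PAM mismatches; `N` bases in the genome mismatch
#' everything. The candidate's own locus (coordinate identity) is returned
#' flagged `is_on_target = TRUE` and does not count against
#' `max_hits_reported`; off-targets are sorted by `homologous_nt` descending
#' and truncated to `max_hits_reported`.
#'
#' @param site One row of a candidate-site tibble (see [scan_targets()]), or
#'   a list with `chrom`, `strand`, `proto_start`, `protospacer`.
#' @param index A [build_seed_index()] over the same genome.
#' @param genome The `genome_assembly` the index was built from.
#' @param policy A [search_policy()].
#' @return Tibble of hits: `chrom`, `start` (0-based start of the full
#'   protospacer-equivalent window on the forward strand), `strand`,
#'   `mismatch_count`, `homologous_nt`, `pam_observed`, `is_on_target`.
#' @export
find_offtargets <- function(site, index, genome, policy = search_policy()) {
  stopifnot(inherits(index, "seed_index"), inherits(genome, "genome_assembly"),
            inherits(policy, "search_policy"))
  if (is.data.frame(site)) {
    stopifnot(nrow(site) == 1L)
    site <- as.list(site)
  }
  proto <- toupper(site$protospacer)
  P <- nchar(proto)
  ig <- policy$ignore_5prime
  tr <- policy$trim_3prime
  mm <- if (policy$sensitivity == "low") min(policy$max_mismatches, 1L)
        else policy$max_mismatches
  if (P - ig - tr < (mm + 1L) * index$k) {
    stop("protospacer too short for the requested masking/trimming and seed length")
  }
  query <- substr(proto, ig + 1L, P - tr)
  m <- nchar(query)
  pamlen <- if (!is.null(policy$allowed_pams)) nchar(policy$allowed_pams[1]) else 0L

  raw <- seed_search(index, query, mm)
  if (nrow(raw) == 0L) return(empty_hits())

  # map the evaluated-query window back to the full protospacer-equivalent
  # window and check the PAM that a Cas9 at that locus would see
  keep <- logical(nrow(raw))
  ps_start <- integer(nrow(raw))
  pam_obs <- character(nrow(raw))
  for (i in seq_len(nrow(raw))) {
    chrom <- raw$chrom[i]
    L <- genome$lengths[[chrom]]
    w <- raw$win_start[i]
    if (raw$strand[i] == "+") {
      ps <- w - ig
      pam_at <- ps + P
      in_bounds <- ps >= 0 && pam_at + pamlen <= L
      pam_seq <- if (in_bounds && pamlen > 0)
        genome_seq(genome, chrom, pam_at, pam_at + pamlen) else ""
    } else {
      # rc(query) matched at w on the + text; protospacer-equivalent window
      # on the minus strand spans [w - tr, w + m + ig) in + coordinates
      ps <- w - tr
      pam_at <- ps - pamlen
      in_bounds <- pam_at >= 0 && ps + P <= L
      pam_seq <- if (in_bounds && pamlen > 0)
        revcomp(genome_seq(genome, chrom, pam_at, pam_at + pamlen)) else ""
    }
    pam_ok <- is.null(policy$allowed_pams) ||
      (nzchar(pam_seq) && pam_seq %in% policy$allowed_pams)
    keep[i] <- in_bounds && pam_ok
    ps_start[i] <- ps
    pam_obs[i] <- pam_seq
  }
  hits <- raw[keep, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty_hits())
  hits$start <- ps_start[keep]
  hits$pam_observed <- pam_obs[keep]
  hits$homologous_nt <- m - hits$mismatch_count
  hits$is_on_target <- hits$chrom == site$chrom &
    hits$strand == site$strand & hits$start == site$proto_start
  hits <- dplyr::arrange(hits, dplyr::desc(.data$homologous_nt),
                         .data$chrom, .data$start, .data$strand)
  off <- dplyr::filter(hits, !.data$is_on_target)
  if (nrow(off) > policy$max_hits_reported) {
    off <- off[seq_len(policy$max_hits_reported), , drop = FALSE]
  }
  on <- dplyr::filter(hits, .data$is_on_target)
  out <- dplyr::bind_rows(on, off)
  out[, c("chrom", "start", "strand", "mismatch_count", "homologous_nt",
          "pam_observed", "is_on_target")]
}

empty_hits <- function() {
  tibble::tibble(chrom = character(), start = integer(), strand = character(),
                 mismatch_count = integer(), homologous_nt = integer(),
                 pam_observed = character(), is_on_target = logical())
}

#' Off-target search for many sites
#'
#' @param sites Candidate-site tibble (see [scan_targets()]).
#' @inheritParams find_offtargets
#' @return Tibble of hits with a `site_id` column (row index into `sites`).
#' @export
find_offtargets_all <- function(sites, index, genome, policy = search_policy()) {
  if (nrow(sites) == 0L) {
    return(dplyr::mutate(empty_hits(), site_id = integer(), .before = 1))
  }
  purrr::map_dfr(seq_len(nrow(sites)), function(i) {
    h <- find_offtargets(sites[i, ], index, genome, policy)
    if (nrow(h) == 0L) return(dplyr::mutate(h, site_id = integer(), .before = 1))
    dplyr::mutate(h, site_id = i, .before = 1)
  })
}

#' Specificity score of a design from its off-target hits
#'
#' Starts at 100; each off-target, ranked by descending homologous
#' nucleotides (rank i = 1, 2, ...), subtracts `homologous_nt / i`, so a
#' perfectly matching first 20-nt off-target subtracts 20 and a perfectly
#' matching second subtracts a further 10. The score is floored at 0. The
#' on-target hit must be excluded (rows flagged `is_on_target` are dropped
#' here defensively).
#'
#' @param hits Hit tibble for one design (see [find_offtargets()]).
#' @return Numeric score in `[0, 100]`.
#' @export
specificity_score <- function(hits) {
  if (nrow(hits) == 0L) return(100)
  off <- hits[!hits$is_on_target, , drop = FALSE]
  if (nrow(off) == 0L) return(100)
  off <- dplyr::arrange(off, dplyr::desc(.data$homologous_nt),
                        .data$chrom, .data$start, .data$strand)
  penalty <- sum(off$homologous_nt / seq_len(nrow(off)))
  max(0, 100 - penalty)
}

#' Write off-target hits as SAM
#'
#' One alignment line per hit against the forward strand of the reference;
#' the `NM` tag carries the mismatch count. Useful for inspecting hits in
#' standard genome tooling.
#'
#' @param hits Hit tibble with a `site_id` column (see
#'   [find_offtargets_all()]); `query_length` nt are reported as matched.
#' @param genome The `genome_assembly` searched (for `@SQ` headers).
#' @param path Output SAM path.
#' @param query_length Evaluated query length (CIGAR `<n>M`).
#' @return `path`, invisibly.
#' @export
write_offtarget_sam <- function(hits, genome, path, query_length) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (chrom in names(genome$seq)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", chrom, genome$lengths[[chrom]]), con)
  }
  if (nrow(hits) > 0) {
    flag <- ifelse(hits$strand == "-", 16L, 0L)
    qname <- if ("site_id" %in% names(hits)) paste0("site", hits$site_id)
             else paste0("hit", seq_len(nrow(hits)))
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t*\t*\tNM:i:%d",
                       qname, flag, hits$chrom, hits$start + 1L,
                       query_length, hits$mismatch_count), con)
  }
  invisible(path)
}
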