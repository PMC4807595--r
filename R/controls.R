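#' Non-targeting control generation policy
#'
#' Defaults mirror the published control-design procedure: 20,000 random
#' 20-mers, mapped back to the genome with loose parameters (ignore the
#' first four 5' nucleotides, allow three further mismatches, no PAM
#' requirement, both strands); candidates that align anywhere, contain a
#' polymerase-hostile motif (`TTTTT`, `GGGGG`) or a BbsI cloning site
#' (`GAAGAC`, `GTCTTC`) are rejected.
#'
#' @param rng_seed Integer seed; recorded in the output provenance
#'   (mandatory, there is no default seed).
#' @param n_candidates Random oligos to draw (default 20000).
#' @param oligo_length Oligo length in nt (default 20).
#' @param loose_ignore_5prime 5' bases ignored in the alignment check
#'   (default 4).
#' @param loose_max_mismatches Mismatch budget of the alignment check
#'   (default 3).
#' @param forbidden_motifs Motifs that disqualify a candidate outright.
#' @param forbidden_sites Restriction sites that disqualify a candidate.
#' @return A `control_policy` list.
#' @export
control_policy <- function(rng_seed, n_candidates = 20000L,
                           oligo_length = 20L, loose_ignore_5prime = 4L,
                           loose_max_mismatches = 3L,
                           forbidden_motifs = c("TTTTT", "GGGGG"),
                           forbidden_sites = c("GAAGAC", "GTCTTC")) {
  if (missing(rng_seed)) stop("control_policy: rng_seed is required")
  rng_seed <- assert_count(rng_seed, "rng_seed", 0L)
  structure(list(
    rng_seed = rng_seed,
    n_candidates = assert_count(n_candidates, "n_candidates", 1L),
    oligo_length = assert_count(oligo_length, "oligo_length", 1L),
    loose_ignore_5prime = assert_count(loose_ignore_5prime,
                                       "loose_ignore_5prime", 0L),
    loose_max_mismatches = assert_count(loose_max_mismatches,
                                        "loose_max_mismatches", 0L),
    forbidden_motifs = toupper(forbidden_motifs),
    forbidden_sites = toupper(forbidden_sites)
  ), class = "control_policy")
}

#' Generate random non-targeting control sgRNAs
#'
#' Rejection sampling against the genome: draws `n_candidates` uniform
#' random oligos from the seeded generator, drops any containing a forbidden
#' motif or restriction site, then drops any that aligns anywhere in the
#' genome (either strand) under the loose policy. Survivors are returned in
#' generation order.
#'
#' @param genome A `genome_assembly`.
#' @param index A [build_seed_index()] over the same genome (pass `NULL`
#'   for an assembly with no indexable sequence).
#' @param policy A [control_policy()].
#' @return Tibble with column `sequence`; attributes `seed`, `policy`,
#'   `n_candidates`, `n_motif_rejected`, `n_aligned_rejected`.
#' @export
generate_nontargeting <- function(genome, index, policy) {
  stopifnot(inherits(policy, "control_policy"))
  cand <- withr::with_seed(policy$rng_seed,
                           random_dna(policy$n_candidates, policy$oligo_length))
  bad_motif <- rep(FALSE, length(cand))
  for (mot in c(policy$forbidden_motifs, policy$forbidden_sites)) {
    bad_motif <- bad_motif | grepl(mot, cand, fixed = TRUE)
  }
  surv <- cand[!bad_motif]
  n_aligned <- 0L
  if (!is.null(index) && length(surv) > 0) {
    stopifnot(inherits(index, "seed_index"))
    queries <- substr(surv, policy$loose_ignore_5prime + 1L, nchar(surv))
    queries_rc <- revcomp(queries)  # one vectorized pass
    aligned <- vapply(seq_along(queries), function(i) {
      seed_search_any(index, queries[i], queries_rc[i],
                      policy$loose_max_mismatches)
    }, logical(1))
    n_aligned <- sum(aligned)
    surv <- surv[!aligned]
  }
  if (length(surv) == 0L) {
    message("generate_nontargeting: no candidate survived the filters")
  }
  out <- tibble::tibble(sequence = surv)
  attr(out, "seed") <- policy$rng_seed
  attr(out, "policy") <- policy
  attr(out, "n_candidates") <- policy$n_candidates
  attr(out, "n_motif_rejected") <- sum(bad_motif)
  attr(out, "n_aligned_rejected") <- n_aligned
  out
}

#' Write non-targeting controls as FASTA with provenance header
#'
#' @param controls Output of [generate_nontargeting()].
#' @param path Output FASTA path.
#' @param prefix Record-name prefix (default `"nontargeting"`).
#' @return `path`, invisibly.
#' @export
write_controls_fasta <- function(controls, path, prefix = "nontargeting") {
  pol <- attr(controls, "policy")
  hdr <- c(
    sprintf(";provenance seed=%d n_candidates=%d oligo_length=%d",
            attr(controls, "seed"), attr(controls, "n_candidates"),
            pol$oligo_length),
    sprintf(";provenance loose_ignore_5prime=%d loose_max_mismatches=%d",
            pol$loose_ignore_5prime, pol$loose_max_mismatches),
    sprintf(";provenance forbidden=%s",
            paste(c(pol$forbidden_motifs, pol$forbidden_sites), collapse = ","))
  )
  ids <- sprintf("%s_%05d", prefix, seq_len(nrow(controls)))
  writeLines(c(hdr, as.vector(rbind(paste0(">", ids), controls$sequence))),
             path)
  invisible(path)
}
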