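#' Annotation score of candidate sites
#'
#' For each site, every annotation feature overlapping the protospacer
#' interval contributes: exon or CDS, `+5 / exon_number` (each overlapping
#' feature separately, so early exons score higher); transcript, `+1`;
#' start or stop codon, `+1`; CpG island, `-1`; gene features contribute 0.
#' A site overlapping nothing scores 0.
#'
#' @param sites Candidate-site tibble (see [scan_targets()]); needs `chrom`,
#'   `proto_start`, `proto_end`.
#' @param tree An [annotation_tree()].
#' @return Numeric vector of annotation scores, one per site row.
#' @export
annotation_score <- function(sites, tree) {
  stopifnot(inherits(tree, "annotation_tree"))
  if (nrow(sites) == 0L) return(numeric())
  pairs <- query_overlaps_many(tree, sites$chrom, sites$proto_start,
                               sites$proto_end)
  scores <- numeric(nrow(sites))
  if (nrow(pairs) == 0L) return(scores)
  feat <- tree$features[pairs$feature, , drop = FALSE]
  exno <- feat$exon_number
  contrib <- dplyr::case_when(
    feat$feature_type %in% c("exon", "cds") ~ 5 / ifelse(is.na(exno), 1, exno),
    feat$feature_type == "transcript" ~ 1,
    feat$feature_type %in% c("start_codon", "stop_codon") ~ 1,
    feat$feature_type == "cpg_island" ~ -1,
    TRUE ~ 0
  )
  agg <- tapply(contrib, pairs$query, sum)
  scores[as.integer(names(agg))] <- as.numeric(agg)
  scores
}

# linear term of the Rule Set 1 logistic model, vectorized over 30-mers
rule_set1_linear <- function(context30) {
  rs <- rule_set1_weights()
  chars <- strsplit(context30, "", fixed = TRUE)
  vapply(chars, function(ch) {
    proto <- ch[5:24]
    gc <- sum(proto %in% c("G", "C"))
    lt <- rs$intercept +
      if (gc < 10) (10 - gc) * rs$gc_low else (gc - 10) * rs$gc_high
    w <- rs$weights
    obs <- substring(paste0(ch, collapse = ""), w$pos,
                     w$pos + nchar(w$seq) - 1L)
    lt + sum(w$weight[obs == w$seq])
  }, numeric(1))
}

#' Doench 2014 (Rule Set 1) on-target score
#'
#' Logistic score over a 30-mer context (4 nt 5' flank, 20 nt protospacer,
#' NGG PAM at positions 25-27, 3 nt 3' flank):
#' `1 / (1 + exp(-(intercept + GC terms + position weights)))`, using the
#' packaged coefficient table ([rule_set1_weights()]). Strictly inside (0,1).
#'
#' @param context30 Character vector of 30-nt ACGT strings (`NA` allowed;
#'   returns `NA` for those entries).
#' @return Numeric vector of scores in (0, 1).
#' @export
doench_score <- function(context30) {
  out <- rep(NA_real_, length(context30))
  ok <- !is.na(context30)
  if (!any(ok)) return(out)
  x <- toupper(context30[ok])
  if (any(nchar(x) != 30L)) stop("doench_score: every context must be 30 nt")
  if (any(grepl("[^ACGT]", x))) stop("doench_score: contexts must be ACGT only")
  out[ok] <- 1 / (1 + exp(-rule_set1_linear(x)))
  out
}

#' Position-weight linear on-target score
#'
#' Sum of the packaged position-by-base weights ([xu_weights()]) over a
#' 30-mer context. Purely additive: changing one base changes the score by
#' exactly the weight difference at that position.
#'
#' @param context Character vector of 30-nt ACGT strings (`NA` allowed).
#' @return Numeric vector of scores.
#' @export
xu_score <- function(context) {
  w <- xu_weights()
  out <- rep(NA_real_, length(context))
  ok <- !is.na(context)
  if (!any(ok)) return(out)
  x <- toupper(context[ok])
  if (any(nchar(x) != nrow(w))) {
    stop("xu_score: every context must be ", nrow(w), " nt")
  }
  if (any(grepl("[^ACGT]", x))) stop("xu_score: contexts must be ACGT only")
  out[ok] <- vapply(strsplit(x, "", fixed = TRUE), function(ch) {
    sum(w[cbind(seq_along(ch), match(ch, colnames(w)))])
  }, numeric(1))
  out
}

#' Apply a user-supplied custom on-target score
#'
#' The plug-in contract: a pure function of one 30-nt string returning a
#' single number in `[0, 1]`. Outputs outside that range, or non-numeric
#' outputs, abort with the offending value.
#'
#' @param context30 Character vector of 30-nt strings (`NA` allowed).
#' @param fn The scoring function.
#' @return Numeric vector of scores in `[0, 1]` (`NA` where context absent).
#' @export
custom_score <- function(context30, fn) {
  stopifnot(is.function(fn))
  out <- rep(NA_real_, length(context30))
  for (i in seq_along(context30)) {
    if (is.na(context30[i])) next
    if (nchar(context30[i]) != 30L) {
      stop("custom score input must be exactly 30 nt")
    }
    v <- fn(context30[i])
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop("custom score returned an out-of-contract value: ",
           paste(format(v), collapse = ", "), " (must be one number in [0,1])")
    }
    out[i] <- as.numeric(v)
  }
  out
}

#' Score a set of candidate sites
#'
#' Convenience wrapper: runs the off-target search, then attaches
#' `specificity_score`, `annotation_score`, the requested on-target score(s)
#' and the off-target count to the site tibble.
#'
#' @param sites Candidate-site tibble.
#' @param tree An [annotation_tree()].
#' @param index A [build_seed_index()] over `genome`.
#' @param genome The `genome_assembly`.
#' @param policy A [search_policy()].
#' @param on_target One of `"doench"`, `"xu"`, `"none"`.
#' @param custom_fn Optional custom score plug-in (see [custom_score()]).
#' @return `sites` with score columns (`annotation_score`,
#'   `specificity_score`, `offtarget_count`, and `doench`/`xu`/`custom` as
#'   requested).
#' @export
score_sites <- function(sites, tree, index, genome,
                        policy = search_policy(),
                        on_target = c("doench", "xu", "none"),
                        custom_fn = NULL) {
  on_target <- match.arg(on_target)
  if (nrow(sites) == 0L) {
    sites$annotation_score <- numeric()
    sites$specificity_score <- numeric()
    sites$offtarget_count <- integer()
    if (on_target != "none") sites[[on_target]] <- numeric()
    return(sites)
  }
  sites$annotation_score <- annotation_score(sites, tree)
  hits <- find_offtargets_all(sites, index, genome, policy)
  spec <- vapply(seq_len(nrow(sites)), function(i) {
    specificity_score(hits[hits$site_id == i, , drop = FALSE])
  }, numeric(1))
  noff <- vapply(seq_len(nrow(sites)), function(i) {
    sum(hits$site_id == i & !hits$is_on_target)
  }, integer(1))
  sites$specificity_score <- spec
  sites$offtarget_count <- noff
  if (on_target == "doench") sites$doench <- doench_score(sites$context30)
  if (on_target == "xu") sites$xu <- xu_score(sites$context30)
  if (!is.null(custom_fn)) sites$custom <- custom_score(sites$context30, custom_fn)
  sites
}

#' Rank designs hierarchically
#'
#' Stable lexicographic sort, each key descending; the default order is
#' annotation score, then specificity, then the efficacy (on-target) score.
#' Remaining ties break by genomic coordinate (`chrom`, `proto_start`,
#' `strand`), so output order is fully deterministic. `NA` score values sort
#' last within their key.
#'
#' @param designs Scored design tibble (see [score_sites()]).
#' @param order Character vector of score column names, highest priority
#'   first.
#' @return `designs`, reordered.
#' @export
rank_designs <- function(designs,
                         order = c("annotation_score", "specificity_score",
                                   "doench")) {
  missing <- setdiff(order, names(designs))
  if (length(missing) > 0) {
    stop("rank_designs: score column(s) absent: ",
         paste(missing, collapse = ", "))
  }
  keys <- c(lapply(order, function(k) -rank_na_last(designs[[k]])),
            list(designs$chrom, designs$proto_start, designs$strand))
  designs[do.call(base::order, keys), , drop = FALSE]
}

# numeric utility: higher value -> higher rank, NA -> -Inf (sorts last
# under the descending order used above)
rank_na_last <- function(x) {
  x <- as.numeric(x)
  x[is.na(x)] <- -Inf
  x
}
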