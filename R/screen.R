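GUIDE_READ_PATTERN <- "ACCG(.{20})T{2,4}AGAGC"

#' Count guides in one FASTQ sample
#'
#' Each read is searched for the expression-cassette pattern
#' `ACCG(.{20})T{2,4}AGAGC` (first occurrence); the captured 20-mer is
#' matched exactly against the library. Reads without the pattern, or whose
#' 20-mer is not in the library, increment the unmatched tally; matched plus
#' unmatched always equals the total number of reads.
#'
#' @param fastq Path to a FASTQ file (gzip accepted).
#' @param library Either a named character vector mapping protospacer ->
#'   design_id, or a tibble with columns `protospacer` and `design_id`.
#'   Protospacers must be unique 20-mers.
#' @return Tibble with `design_id` and `count` (every library design present,
#'   zeros included); attributes `unmatched` and `total_reads`.
#' @export
count_guides <- function(fastq, library) {
  if (is.data.frame(library)) {
    stopifnot(all(c("protospacer", "design_id") %in% names(library)))
    map <- stats::setNames(library$design_id, library$protospacer)
  } else {
    map <- library
  }
  if (is.null(names(map)) || anyDuplicated(names(map))) {
    stop("library protospacers must be named and unique")
  }
  if (any(nchar(names(map)) != 20L)) {
    stop("library protospacers must be 20 nt")
  }
  if (!file.exists(fastq)) stop("FASTQ not found: ", fastq)
  con <- gzfile(fastq, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  if (length(lines) %% 4 != 0) {
    stop("unreadable FASTQ (line count not a multiple of 4): ", fastq)
  }
  seqs <- lines[seq(2L, length(lines), by = 4L)]
  m <- regexpr(GUIDE_READ_PATTERN, seqs, perl = TRUE)
  cap_start <- attr(m, "capture.start")[, 1]
  has <- m != -1L
  inserts <- rep(NA_character_, length(seqs))
  inserts[has] <- substr(seqs[has], cap_start[has], cap_start[has] + 19L)
  idx <- match(inserts, names(map))
  matched <- !is.na(idx)
  counts <- tabulate(idx[matched], nbins = length(map))
  out <- tibble::tibble(design_id = unname(map), count = counts)
  attr(out, "unmatched") <- sum(!matched)
  attr(out, "total_reads") <- length(seqs)
  out
}

#' Count guides across samples into a count matrix
#'
#' @param fastqs Named character vector of FASTQ paths (names become sample
#'   columns).
#' @param library As in [count_guides()].
#' @return Wide tibble: `design_id` plus one integer column per sample;
#'   attribute `unmatched` is a named vector of per-sample unmatched tallies.
#' @export
count_screen <- function(fastqs, library) {
  stopifnot(length(fastqs) >= 1L, !is.null(names(fastqs)),
            all(nzchar(names(fastqs))))
  cols <- lapply(fastqs, count_guides, library = library)
  out <- cols[[1]]["design_id"]
  unmatched <- integer(length(fastqs))
  names(unmatched) <- names(fastqs)
  for (s in names(fastqs)) {
    out[[s]] <- cols[[s]]$count
    unmatched[[s]] <- attr(cols[[s]], "unmatched")
  }
  attr(out, "unmatched") <- unmatched
  out
}

#' Median-normalize counts and compute control-centred log2 fold changes
#'
#' Each sample column is divided by its median (a zero median is an error
#' naming the sample). The raw per-guide log2 fold change is the log2 ratio
#' of the mean normalized treated count over the mean normalized control
#' count, with a pseudocount added to both means; the centred value subtracts
#' the median raw fold change of the non-targeting controls, so the
#' non-targeting median is exactly 0 after centring.
#'
#' The pseudocount is expressed in read-count units and converted to the
#' normalized scale through each sample's median (i.e. it is equivalent to
#' adding `pseudocount` reads to every raw count), so it guards against
#' zero-count infinities without biasing fold changes at realistic depth.
#'
#' @param counts Wide count tibble (`design_id` + sample columns).
#' @param treated,control Disjoint, nonempty character vectors of sample
#'   column names.
#' @param nontargeting_ids Design ids of the non-targeting controls.
#' @param pseudocount Reads added to numerator and denominator means, on the
#'   raw-count scale (default 0.5; set 0 to disable).
#' @return Tibble: `design_id`, `mean_treated`, `mean_control`, `raw_l2fc`,
#'   `centred_l2fc`.
#' @export
normalize_and_fold_change <- function(counts, treated, control,
                                      nontargeting_ids, pseudocount = 0.5) {
  stopifnot(length(treated) >= 1, length(control) >= 1,
            length(intersect(treated, control)) == 0)
  samples <- c(treated, control)
  missing <- setdiff(samples, names(counts))
  if (length(missing) > 0) {
    stop("sample column(s) absent from counts: ", paste(missing, collapse = ", "))
  }
  if (!all(nontargeting_ids %in% counts$design_id)) {
    stop("nontargeting_ids must all be present in counts$design_id")
  }
  norm <- counts
  meds <- numeric(0)
  for (s in samples) {
    med <- stats::median(counts[[s]])
    if (med == 0) stop("sample '", s, "' has median count 0; cannot normalize")
    norm[[s]] <- counts[[s]] / med
    meds[[s]] <- med
  }
  mt <- rowMeans(as.matrix(norm[, treated, drop = FALSE]))
  mc <- rowMeans(as.matrix(norm[, control, drop = FALSE]))
  # pseudocount in count units -> normalized units, per arm
  eps_t <- pseudocount * mean(1 / meds[treated])
  eps_c <- pseudocount * mean(1 / meds[control])
  raw <- log2((mt + eps_t) / (mc + eps_c))
  is_nt <- counts$design_id %in% nontargeting_ids
  centred <- raw - stats::median(raw[is_nt])
  tibble::tibble(design_id = counts$design_id,
                 mean_treated = mt, mean_control = mc,
                 raw_l2fc = raw, centred_l2fc = centred)
}

#' Gene-level Wilcoxon rank-sum test against non-targeting controls
#'
#' Per gene, the Wilcoxon rank-sum test (normal approximation with tie
#' correction) compares the gene's guide fold changes with the non-targeting
#' set; the gene fold change is the median of its guides' values. The
#' default alternative `"greater"` tests for enrichment of the gene's guides
#' over controls; `"less"` and `"two.sided"` are available.
#'
#' @param l2fc Per-guide fold-change tibble from
#'   [normalize_and_fold_change()].
#' @param gene_map Tibble with `design_id` and `gene_id` for the targeting
#'   guides (non-targeting designs need no entry).
#' @param nontargeting_ids Design ids of the non-targeting controls
#'   (nonempty).
#' @param alternative Test sidedness (default `"greater"`).
#' @param value Fold-change column used (default `"centred_l2fc"`).
#' @return A `screen_gene_results` tibble: `gene_id`, `log2fc`, `p_value`,
#'   `n_guides`, sorted by `p_value`.
#' @export
gene_test <- function(l2fc, gene_map, nontargeting_ids,
                      alternative = c("greater", "less", "two.sided"),
                      value = "centred_l2fc") {
  alternative <- match.arg(alternative)
  if (length(nontargeting_ids) == 0) stop("empty non-targeting set")
  stopifnot(all(c("design_id", "gene_id") %in% names(gene_map)),
            value %in% names(l2fc))
  ctrl <- l2fc[[value]][l2fc$design_id %in% nontargeting_ids]
  if (length(ctrl) == 0) stop("no non-targeting design found in l2fc")
  dat <- dplyr::inner_join(l2fc, gene_map, by = "design_id")
  res <- dat |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      log2fc = stats::median(.data[[value]]),
      p_value = stats::wilcox.test(.data[[value]], ctrl,
                                   alternative = alternative,
                                   exact = FALSE)$p.value,
      n_guides = dplyr::n()
    ) |>
    dplyr::arrange(.data$p_value, .data$gene_id)
  attr(res, "alternative") <- alternative
  attr(res, "n_controls") <- length(ctrl)
  class(res) <- c("screen_gene_results", class(res))
  res
}

#' @export
print.screen_gene_results <- function(x, ...) {
  cat("Gene-level screen results (Wilcoxon rank-sum vs non-targeting, ",
      attr(x, "alternative"), "; ", attr(x, "n_controls"),
      " control guides)\n", sep = "")
  NextMethod()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy gene-level screen results
#'
#' @param x A `screen_gene_results` object from [gene_test()].
#' @param ... Unused.
#' @return A plain tibble (`gene_id`, `log2fc`, `p_value`, `n_guides`).
#' @export
tidy.screen_gene_results <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("gene_id", "log2fc", "p_value", "n_guides")])
}

#' One-row summary of gene-level screen results
#'
#' @param x A `screen_gene_results` object.
#' @param alpha Significance threshold for the `n_significant` column.
#' @param ... Unused.
#' @return One-row tibble: `n_genes`, `n_controls`, `alternative`,
#'   `n_significant`.
#' @export
glance.screen_gene_results <- function(x, alpha = 0.05, ...) {
  tibble::tibble(
    n_genes = nrow(x),
    n_controls = attr(x, "n_controls"),
    alternative = attr(x, "alternative"),
    n_significant = sum(x$p_value < alpha)
  )
}

#' Classify one gene's guides as functional / non-functional
#'
#' z-scores each value against the gene's own guides (sample standard
#' deviation); `z > 1` is `functional`, `z < -1` `non-functional`, otherwise
#' `intermediate`. Zero spread labels everything `intermediate` with a
#' warning.
#'
#' @param values Numeric fold changes of one gene's guides (length >= 2).
#' @return Tibble: `value`, `z`, `label`.
#' @export
classify_functional <- function(values) {
  stopifnot(is.numeric(values), length(values) >= 2L)
  s <- stats::sd(values)
  if (is.na(s) || s == 0) {
    warning("classify_functional: zero spread; all guides intermediate")
    z <- rep(0, length(values))
  } else {
    z <- (values - mean(values)) / s
  }
  label <- dplyr::case_when(z > 1 ~ "functional",
                            z < -1 ~ "non-functional",
                            TRUE ~ "intermediate")
  tibble::tibble(value = values, z = z, label = label)
}
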