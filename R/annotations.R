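KNOWN_FEATURE_TYPES <- c("gene", "transcript", "exon", "cds",
                         "start_codon", "stop_codon", "cpg_island")

# normalize on-disk feature type spellings to the internal vocabulary
normalize_feature_type <- function(type) {
  type <- as.character(type)
  out <- tolower(type)
  out[out == "mrna"] <- "transcript"
  out[out %in% c("cpg_island", "cpgisland", "cpg island")] <- "cpg_island"
  out
}

#' Load genome annotations from GFF3/GTF
#'
#' Coordinates on disk are 1-based closed; in memory every interval is
#' 0-based half-open. `exon_number` is taken from the attribute when present,
#' otherwise assigned in strand-aware transcript order (1 = 5'-most exon).
#' Feature types outside `feature_types` are dropped, with a message giving
#' the dropped count.
#'
#' @param gff_path Path to a GFF3 or GTF file.
#' @param feature_types Character vector of feature types to retain
#'   (lower-case; `mRNA` rows are treated as `transcript`).
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `feature_type`, `gene_id`, `transcript_id`, `exon_number`.
#' @export
read_annotations <- function(gff_path, feature_types = KNOWN_FEATURE_TYPES) {
  if (!file.exists(gff_path)) stop("annotation file not found: ", gff_path)
  gr <- rtracklayer::import(gff_path)
  mc <- S4Vectors::mcols(gr)
  get_col <- function(nm) {
    if (nm %in% colnames(mc)) as.character(mc[[nm]]) else rep(NA_character_, length(gr))
  }
  type <- normalize_feature_type(get_col("type"))
  gene_id <- get_col("gene_id")
  transcript_id <- get_col("transcript_id")
  # GFF3 dialects carry identity via ID/Parent instead of flat attributes
  id <- get_col("ID")
  parent <- get_col("Parent")
  gene_id[is.na(gene_id) & type == "gene"] <- id[is.na(gene_id) & type == "gene"]
  gene_id[is.na(gene_id) & type == "transcript"] <-
    parent[is.na(gene_id) & type == "transcript"]
  transcript_id[is.na(transcript_id) & type == "transcript"] <-
    id[is.na(transcript_id) & type == "transcript"]
  sub_tx <- is.na(transcript_id) & type %in% c("exon", "cds", "start_codon", "stop_codon")
  transcript_id[sub_tx] <- parent[sub_tx]

  exon_number <- suppressWarnings(as.integer(get_col("exon_number")))

  feat <- tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature_type = type,
    gene_id = gene_id,
    transcript_id = transcript_id,
    exon_number = exon_number
  )
  known <- feat$feature_type %in% feature_types
  n_dropped <- sum(!known)
  if (n_dropped > 0) {
    message("read_annotations: dropped ", n_dropped,
            " row(s) with feature types outside {",
            paste(feature_types, collapse = ", "), "}")
  }
  feat <- feat[known, , drop = FALSE]
  if (any(feat$end <= feat$start)) {
    bad <- which(feat$end <= feat$start)[1]
    stop("annotation row ", bad, ": end <= start after conversion")
  }
  assign_exon_numbers(feat)
}

# strand-aware 1-based exon/CDS numbering where the attribute was absent
assign_exon_numbers <- function(feat) {
  needs <- feat$feature_type %in% c("exon", "cds") & is.na(feat$exon_number)
  if (!any(needs)) return(feat)
  feat$._row <- seq_len(nrow(feat))
  fixed <- feat |>
    dplyr::filter(.data$feature_type %in% c("exon", "cds")) |>
    dplyr::group_by(.data$transcript_id, .data$feature_type) |>
    dplyr::mutate(
      ._assigned = if (all(is.na(.data$exon_number))) {
        if (dplyr::first(.data$strand) == "-") {
          rank(-.data$start, ties.method = "first")
        } else {
          rank(.data$start, ties.method = "first")
        }
      } else {
        .data$exon_number
      }
    ) |>
    dplyr::ungroup()
  feat$exon_number[fixed$._row] <- as.integer(fixed$._assigned)
  feat$._row <- NULL
  feat
}

#' Build a per-chromosome interval tree over annotation features
#'
#' Overlap queries run on an indexed interval structure (nested containment
#' lists, one per chromosome), giving the usual O(log n + k) behaviour.
#'
#' @param features Annotation tibble as returned by [read_annotations()].
#' @return An `annotation_tree` object.
#' @export
annotation_tree <- function(features) {
  required <- c("chrom", "start", "end", "strand", "feature_type")
  missing <- setdiff(required, names(features))
  if (length(missing) > 0) stop("features lack column(s): ",
                                paste(missing, collapse = ", "))
  if (!"gene_id" %in% names(features)) features$gene_id <- NA_character_
  if (!"transcript_id" %in% names(features)) features$transcript_id <- NA_character_
  if (!"exon_number" %in% names(features)) features$exon_number <- NA_integer_
  if (nrow(features) > 0 && any(features$end <= features$start)) {
    stop("invalid feature interval (end <= start)")
  }
  features <- tibble::as_tibble(features)
  gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = ifelse(features$strand %in% c("+", "-"), features$strand, "*")
  )
  structure(list(gr = gr, features = features, format_version = 1L),
            class = "annotation_tree")
}

#' @export
print.annotation_tree <- function(x, ...) {
  cat("<annotation_tree> ", nrow(x$features), " feature(s) on ",
      length(unique(x$features$chrom)), " chromosome(s)\n", sep = "")
  print(table(x$features$feature_type))
  invisible(x)
}

#' Query all features overlapping an interval
#'
#' Returns exactly the features whose interval has a nonempty intersection
#' with `[start, end)` on `chrom`. An unknown chromosome yields an empty
#' result with a warning (so batch runs survive unplaced contigs).
#'
#' @param tree An `annotation_tree`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open query interval, `start < end`.
#' @return Tibble of overlapping features (same columns as the input tibble).
#' @export
query_overlaps <- function(tree, chrom, start, end) {
  stopifnot(inherits(tree, "annotation_tree"), start < end)
  if (!chrom %in% unique(tree$features$chrom)) {
    warning("query_overlaps: unknown chromosome '", chrom, "'")
    return(tree$features[0, , drop = FALSE])
  }
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  hits <- GenomicRanges::findOverlaps(q, tree$gr, ignore.strand = TRUE)
  tree$features[S4Vectors::subjectHits(hits), , drop = FALSE]
}

# vectorized form used internally: query many intervals at once, returning
# the overlap pairs (query row index, feature row index)
query_overlaps_many <- function(tree, chrom, start, end) {
  known <- chrom %in% unique(tree$features$chrom)
  idx <- which(known)
  if (length(idx) == 0L) {
    return(tibble::tibble(query = integer(), feature = integer()))
  }
  q <- GenomicRanges::GRanges(chrom[idx],
                              IRanges::IRanges(start[idx] + 1L, end[idx]))
  hits <- GenomicRanges::findOverlaps(q, tree$gr, ignore.strand = TRUE)
  tibble::tibble(query = idx[S4Vectors::queryHits(hits)],
                 feature = S4Vectors::subjectHits(hits))
}

#' Persist / restore an annotation tree
#'
#' The on-disk cache carries a format version; loading refuses a mismatched
#' version rather than silently misreading.
#'
#' @param tree An `annotation_tree`.
#' @param path Cache file path.
#' @return `path` (save) or the restored `annotation_tree` (load).
#' @export
save_annotation_tree <- function(tree, path) {
  stopifnot(inherits(tree, "annotation_tree"))
  saveRDS(list(magic = "guidelib_annotation_tree",
               format_version = tree$format_version,
               features = tree$features),
          path)
  invisible(path)
}

#' @rdname save_annotation_tree
#' @export
load_annotation_tree <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$magic, "guidelib_annotation_tree")) {
    stop("not an annotation tree cache: ", path)
  }
  if (!identical(obj$format_version, 1L)) {
    stop("annotation tree cache version mismatch (found ",
         obj$format_version, ", expected 1)")
  }
  annotation_tree(obj$features)
}

#' Predict CpG islands (optional detector)
#'
#' Sliding-window rule: windows of at least `min_length` nt with GC fraction
#' >= `min_gc` and observed/expected CpG ratio >= `min_obs_exp`
#' (obs/exp = n(CG) * L / (n(C) * n(G))). Qualifying windows are merged.
#' Use this only when the annotation carries no `cpg_island` features.
#'
#' @param genome A `genome_assembly`.
#' @param min_length Minimum island length (default 200 nt).
#' @param min_gc Minimum GC fraction (default 0.5).
#' @param min_obs_exp Minimum observed/expected CpG ratio (default 0.6).
#' @param step Window step in nt (default 50).
#' @return Annotation tibble of `cpg_island` features (possibly empty).
#' @export
detect_cpg_islands <- function(genome, min_length = 200L, min_gc = 0.5,
                               min_obs_exp = 0.6, step = 50L) {
  stopifnot(inherits(genome, "genome_assembly"))
  out <- list()
  for (chrom in names(genome$seq)) {
    s <- genome$seq[[chrom]]
    L <- nchar(s)
    if (L < min_length) next
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    isC <- ch == "C"; isG <- ch == "G"
    isCG <- c(isC[-L] & isG[-1], FALSE)
    cumC <- cumsum(isC); cumG <- cumsum(isG); cumCG <- cumsum(isCG)
    starts <- seq(1L, L - min_length + 1L, by = step)
    ends <- starts + min_length - 1L
    nC <- cumC[ends] - c(0, cumC)[starts]
    nG <- cumG[ends] - c(0, cumG)[starts]
    nCG <- cumCG[pmin(ends, L - 1L)] - c(0, cumCG)[starts]
    gc <- (nC + nG) / min_length
    obs_exp <- ifelse(nC * nG > 0, nCG * min_length / (nC * nG), 0)
    ok <- gc >= min_gc & obs_exp >= min_obs_exp
    if (!any(ok)) next
    ir <- IRanges::reduce(IRanges::IRanges(starts[ok], ends[ok]))
    out[[chrom]] <- tibble::tibble(
      chrom = chrom,
      start = IRanges::start(ir) - 1L,
      end = IRanges::end(ir),
      strand = "+",
      feature_type = "cpg_island",
      gene_id = NA_character_,
      transcript_id = NA_character_,
      exon_number = NA_integer_
    )
  }
  if (length(out) == 0L) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), strand = character(),
                          feature_type = character(), gene_id = character(),
                          transcript_id = character(),
                          exon_number = integer()))
  }
  dplyr::bind_rows(out)
}
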