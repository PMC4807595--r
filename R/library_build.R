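#' Library build configuration
#'
#' @param adapter5,adapter3 Cloning adapter sequences flanking the final
#'   protospacer in each ordered oligo. Required: there is no universal
#'   default, they must match the cloning strategy.
#' @param guides_per_gene Designs accepted per gene, best-ranked first
#'   (default 30).
#' @param min_coverage Genes with fewer accepted designs are dropped
#'   (default: `guides_per_gene`, i.e. a gene must be fully coverable).
#' @param forbidden_sites Restriction sites that must not occur in an
#'   assembled oligo. The default list already contains both orientations of
#'   each enzyme site (BbsI GAAGAC/GTCTTC, EcoRI GAATTC/CTTAAG,
#'   MfeI CAATTG/HpaI GTTAAC, XhoI CTCGAG/SacI GAGCTC).
#' @return A `build_config` list.
#' @export
build_config <- function(adapter5, adapter3, guides_per_gene = 30L,
                         min_coverage = guides_per_gene,
                         forbidden_sites = c("GAAGAC", "GTCTTC", "GAATTC",
                                             "CTTAAG", "CAATTG", "GTTAAC",
                                             "CTCGAG", "GAGCTC")) {
  if (missing(adapter5) || missing(adapter3) ||
      !is.character(adapter5) || !is.character(adapter3) ||
      !nzchar(adapter5) || !nzchar(adapter3)) {
    stop("build_config: adapter5 and adapter3 must be set explicitly ",
         "(no silent empty adapters)")
  }
  adapter5 <- toupper(adapter5); adapter3 <- toupper(adapter3)
  guides_per_gene <- assert_count(guides_per_gene, "guides_per_gene", 1L)
  min_coverage <- assert_count(min_coverage, "min_coverage", 0L)
  forbidden_sites <- toupper(forbidden_sites)
  if (length(forbidden_sites) == 0 || any(grepl("[^ACGT]", forbidden_sites))) {
    stop("forbidden_sites must be nonempty ACGT strings")
  }
  structure(list(adapter5 = adapter5, adapter3 = adapter3,
                 guides_per_gene = guides_per_gene,
                 min_coverage = min_coverage,
                 forbidden_sites = forbidden_sites),
            class = "build_config")
}

#' Finalize a protospacer for U6 expression
#'
#' The first 5' base is replaced by guanine (U6-driven transcription starts
#' on G); length is preserved.
#'
#' @param protospacer Character vector of protospacers (length >= 2 each).
#' @return Character vector with leading `G`.
#' @export
finalize_protospacer <- function(protospacer) {
  if (length(protospacer) == 0) return(character())
  if (any(is.na(protospacer)) || any(nchar(protospacer) < 2L)) {
    stop("finalize_protospacer: protospacers must be at least 2 nt")
  }
  paste0("G", substr(protospacer, 2L, nchar(protospacer)))
}

#' Assemble the ordered oligo library from ranked designs
#'
#' Walks each gene's designs in rank order: the protospacer is finalized
#' ([finalize_protospacer()]), flanked by the adapters, and dropped if the
#' assembled oligo contains any forbidden restriction site; acceptance stops
#' at `guides_per_gene` oligos per gene. Genes ending below `min_coverage`
#' accepted oligos are removed (reported in the `dropped_genes` attribute).
#' Library-wide duplicate final protospacers collapse to the first
#' occurrence by rank (reported in the `collapsed_duplicates` attribute).
#'
#' @param designs Ranked design tibble (see [rank_designs()]); needs
#'   `gene_id`, `protospacer` and the coordinate/score columns to carry
#'   through.
#' @param config A [build_config()].
#' @return Tibble of library oligos (`design_id`, `gene_id`,
#'   `protospacer_final`, `oligo_sequence`, provenance and score columns),
#'   with attributes `dropped_genes` and `collapsed_duplicates`.
#' @export
assemble_and_filter <- function(designs, config) {
  stopifnot(inherits(config, "build_config"))
  if (!all(c("gene_id", "protospacer") %in% names(designs))) {
    stop("designs need gene_id and protospacer columns")
  }
  if (nrow(designs) == 0L) {
    out <- tibble::tibble(design_id = character(), gene_id = character(),
                          protospacer_final = character(),
                          oligo_sequence = character())
    attr(out, "dropped_genes") <- tibble::tibble(gene_id = character(),
                                                 n_accepted = integer())
    attr(out, "collapsed_duplicates") <- tibble::tibble(
      design_id = character(), duplicate_of = character())
    return(out)
  }
  designs <- dplyr::mutate(
    designs,
    protospacer_final = finalize_protospacer(.data$protospacer),
    oligo_sequence = paste0(config$adapter5, .data$protospacer_final,
                            config$adapter3)
  )
  forbidden <- rep(FALSE, nrow(designs))
  for (site in config$forbidden_sites) {
    forbidden <- forbidden | grepl(site, designs$oligo_sequence, fixed = TRUE)
  }
  kept <- designs[!forbidden, , drop = FALSE]
  # acceptance in rank order, capped per gene
  kept <- kept |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(._serial = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$._serial <= config$guides_per_gene)
  # library-wide duplicate protospacer collapse (first by rank wins)
  dup <- duplicated(kept$protospacer_final)
  collapsed <- tibble::tibble(design_id = character(),
                              duplicate_of = character())
  if (any(dup)) {
    first_of <- kept$gene_id[match(kept$protospacer_final[dup],
                                   kept$protospacer_final)]
    collapsed <- tibble::tibble(
      design_id = paste0(kept$gene_id[dup], "_dup"),
      duplicate_of = first_of)
    kept <- kept[!dup, , drop = FALSE]
    # re-serial after collapse so ids stay dense
    kept <- kept |>
      dplyr::group_by(.data$gene_id) |>
      dplyr::mutate(._serial = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  counts <- dplyr::count(kept, .data$gene_id, name = "n_accepted")
  low <- dplyr::filter(counts, .data$n_accepted < config$min_coverage)
  if (nrow(low) > 0) {
    message("assemble_and_filter: dropping ", nrow(low),
            " gene(s) below min_coverage = ", config$min_coverage, ": ",
            paste(low$gene_id, collapse = ", "))
    kept <- dplyr::filter(kept, !.data$gene_id %in% low$gene_id)
  }
  kept <- dplyr::mutate(kept,
                        design_id = sprintf("%s_%03d", .data$gene_id,
                                            .data$._serial))
  kept$._serial <- NULL
  kept <- dplyr::relocate(kept, "design_id", "gene_id", "protospacer_final",
                          "oligo_sequence")
  attr(kept, "dropped_genes") <- low
  attr(kept, "collapsed_duplicates") <- collapsed
  kept
}

#' Write library output files
#'
#' Writes, deterministically: (a) a FASTA of oligo sequences keyed by
#' `design_id`; (b) a GFF3 of the design genomic intervals with scores as
#' attributes; (c) a tab-delimited summary table; (d) a plain-text
#' dropped-genes report if any gene fell below coverage.
#'
#' @param library Oligo tibble from [assemble_and_filter()].
#' @param out_dir Output directory (created if absent).
#' @param prefix File-name prefix (default `"library"`).
#' @return Named character vector of written paths, invisibly.
#' @export
write_outputs <- function(library, out_dir, prefix = "library") {
  if (nrow(library) == 0L) stop("write_outputs: empty library")
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  paths <- c(
    fasta = file.path(out_dir, paste0(prefix, ".fasta")),
    gff = file.path(out_dir, paste0(prefix, ".gff3")),
    tsv = file.path(out_dir, paste0(prefix, ".tsv"))
  )
  writeLines(
    as.vector(rbind(paste0(">", library$design_id), library$oligo_sequence)),
    paths[["fasta"]]
  )

  score_cols <- intersect(c("annotation_score", "specificity_score", "doench",
                            "xu", "custom", "offtarget_count"),
                          names(library))
  attrs <- vapply(seq_len(nrow(library)), function(i) {
    kv <- c(sprintf("ID=%s", library$design_id[i]),
            sprintf("gene_id=%s", library$gene_id[i]),
            vapply(score_cols, function(cl) {
              sprintf("%s=%s", cl, format(library[[cl]][i], digits = 10))
            }, character(1)))
    paste(kv, collapse = ";")
  }, character(1))
  gff <- sprintf("%s\tguidelib\tsgRNA\t%d\t%d\t.\t%s\t.\t%s",
                 library$chrom, library$start + 1L, library$end,
                 library$strand, attrs)
  writeLines(c("##gff-version 3", gff), paths[["gff"]])

  tsv_cols <- intersect(c("design_id", "gene_id", "chrom", "start", "end",
                          "strand", "protospacer_final", "oligo_sequence",
                          score_cols),
                        names(library))
  utils::write.table(library[, tsv_cols], paths[["tsv"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)

  dropped <- attr(library, "dropped_genes")
  if (!is.null(dropped) && nrow(dropped) > 0) {
    paths[["dropped"]] <- file.path(out_dir, paste0(prefix, ".dropped_genes.txt"))
    writeLines(sprintf("%s\t%d", dropped$gene_id, dropped$n_accepted),
               paths[["dropped"]])
  }
  invisible(paths)
}
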