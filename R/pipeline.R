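# The documented parameter vocabulary of the flat key=value run-parameter
# file. Unknown keys are rejected loudly; every run writes the fully
# resolved set next to its outputs.
PARAM_DEFAULTS <- list(
  pam = "NGG",
  pam_side = "3prime",
  protospacer_length = 20L,
  exclude_polyT = TRUE,
  region_filter = "none",        # none|cds|exon|start_codon|stop_codon|tss
  tss_lower = -50L,
  tss_upper = 300L,
  max_mismatches = 3L,
  ignore_5prime = 0L,
  trim_3prime = 4L,
  allowed_pams = "NGG,NAG",      # IUPAC patterns, comma separated
  max_hits_reported = 30L,
  sensitivity = "high",
  ranking = "annotation_score,specificity_score,efficacy",
  on_target_score = "doench",    # doench|xu|none
  guides_per_gene = 30L,
  min_coverage = NA_integer_,    # NA -> guides_per_gene
  forbidden_sites = "GAAGAC,GTCTTC,GAATTC,CTTAAG,CAATTG,GTTAAC,CTCGAG,GAGCTC",
  adapter5 = "",
  adapter3 = "",
  seed_index_k = 4L,
  seed = 1L
)

#' Read a key=value run-parameter file
#'
#' Flat `key=value` lines; `#` starts a comment; blank lines ignored.
#' Unknown keys are rejected with the list of valid keys. Missing keys take
#' the documented defaults.
#'
#' @param path Parameter file path, or `NULL` for pure defaults.
#' @return Named list of resolved parameters.
#' @export
read_run_parameters <- function(path = NULL) {
  params <- PARAM_DEFAULTS
  if (!is.null(path)) {
    if (!file.exists(path)) stop("parameter file not found: ", path)
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      if (!grepl("=", ln, fixed = TRUE)) {
        stop("parameter line is not key=value: '", ln, "'")
      }
      key <- trimws(sub("=.*$", "", ln))
      val <- trimws(sub("^[^=]*=", "", ln))
      if (!key %in% names(PARAM_DEFAULTS)) {
        stop("unknown parameter '", key, "'. Valid keys: ",
             paste(names(PARAM_DEFAULTS), collapse = ", "))
      }
      proto <- PARAM_DEFAULTS[[key]]
      params[[key]] <- if (is.logical(proto)) {
        toupper(val) %in% c("TRUE", "T", "1", "YES")
      } else if (is.integer(proto)) {
        as.integer(val)
      } else if (is.numeric(proto)) {
        as.numeric(val)
      } else {
        val
      }
    }
  }
  if (is.na(params$min_coverage)) params$min_coverage <- params$guides_per_gene
  params
}

#' Write the fully resolved parameter set
#'
#' The written file, re-fed as the parameter file, reproduces the run.
#'
#' @param params Resolved parameter list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_parameters <- function(params, path) {
  fmt <- vapply(names(params), function(k) {
    v <- params[[k]]
    sprintf("%s=%s", k, if (is.logical(v)) tolower(as.character(v))
            else as.character(v))
  }, character(1))
  writeLines(fmt, path)
  invisible(path)
}

#' Read a gene list
#'
#' One token per line: either a gene identifier resolvable against the
#' annotation, or a genomic region `chrom:start-end` (0-based half-open).
#' `#` comments and blank lines are ignored.
#'
#' @param path Gene-list file path.
#' @return Tibble: `token`, `kind` (`"gene"` or `"region"`), and for regions
#'   `chrom`, `start`, `end`.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path)
  lines <- trimws(sub("#.*$", "", readLines(path)))
  lines <- lines[nzchar(lines)]
  is_region <- grepl("^[^:]+:[0-9]+-[0-9]+$", lines)
  tibble::tibble(
    token = lines,
    kind = ifelse(is_region, "region", "gene"),
    chrom = ifelse(is_region, sub(":.*$", "", lines), NA_character_),
    start = ifelse(is_region,
                   as.integer(sub("^[^:]+:([0-9]+)-.*$", "\\1", lines)), NA),
    end = ifelse(is_region,
                 as.integer(sub("^.*-([0-9]+)$", "\\1", lines)), NA)
  )
}

#' Run the full library design end to end
#'
#' Scan -> region filter -> off-target search -> scoring -> ranking ->
#' assembly/coverage filtering -> output writing, for every resolvable entry
#' of the gene list. Unresolvable gene identifiers are reported and skipped;
#' zero resolvable entries is an error. A per-gene stage-count log and the
#' fully resolved parameter set are written beside the outputs. Outputs are
#' byte-deterministic for identical inputs.
#'
#' @param genome_path FASTA genome path.
#' @param annotation_path GFF3/GTF annotation path.
#' @param gene_list_path Gene list path (see [read_gene_list()]).
#' @param params Resolved parameter list ([read_run_parameters()]), or a
#'   path to a parameter file.
#' @param out_dir Output directory.
#' @return Invisibly, a list: `summary` (per-gene stage counts),
#'   `library` (oligo tibble), `unresolved` (character), `paths`.
#' @export
run_end_to_end <- function(genome_path, annotation_path, gene_list_path,
                           params = NULL, out_dir) {
  if (is.character(params) || is.null(params)) {
    params <- read_run_parameters(params)
  }
  genome <- read_genome(genome_path)
  features <- read_annotations(annotation_path)
  tree <- annotation_tree(features)
  genes <- read_gene_list(gene_list_path)

  gene_feats <- dplyr::filter(features, .data$feature_type == "gene")
  regions <- list(); unresolved <- character()
  for (i in seq_len(nrow(genes))) {
    if (genes$kind[i] == "region") {
      regions[[length(regions) + 1L]] <- tibble::tibble(
        chrom = genes$chrom[i], start = as.integer(genes$start[i]),
        end = as.integer(genes$end[i]), gene_id = genes$token[i])
    } else {
      hit <- gene_feats[!is.na(gene_feats$gene_id) &
                          gene_feats$gene_id == genes$token[i], , drop = FALSE]
      if (nrow(hit) == 0L) {
        unresolved <- c(unresolved, genes$token[i])
      } else {
        regions[[length(regions) + 1L]] <- tibble::tibble(
          chrom = hit$chrom[1], start = hit$start[1], end = hit$end[1],
          gene_id = genes$token[i])
      }
    }
  }
  if (length(unresolved) > 0) {
    message("unresolvable gene identifier(s): ",
            paste(unresolved, collapse = ", "))
  }
  if (length(regions) == 0L) stop("no resolvable gene or region in the list")
  regions <- dplyr::bind_rows(regions)

  pam <- pam_spec(params$pam, side = params$pam_side,
                  protospacer_length = params$protospacer_length)
  sites <- scan_regions(genome, regions, pam = pam,
                        exclude_polyT = params$exclude_polyT)
  n_scanned <- dplyr::count(sites, .data$gene_id, name = "candidates")

  filt <- switch(params$region_filter,
    none = NULL,
    cds = region_filter(cds_only = TRUE),
    exon = region_filter(exon_only = TRUE),
    start_codon = region_filter(start_codon = TRUE),
    stop_codon = region_filter(stop_codon = TRUE),
    tss = region_filter(tss_window = c(params$tss_lower, params$tss_upper)),
    stop("unknown region_filter: ", params$region_filter)
  )
  if (!is.null(filt)) sites <- filter_by_region(sites, tree, filt)
  n_filtered <- dplyr::count(sites, .data$gene_id, name = "after_region_filter")

  allowed <- unlist(lapply(strsplit(params$allowed_pams, ",")[[1]],
                           function(p) iupac_expand(trimws(p))))
  policy <- search_policy(
    max_mismatches = params$max_mismatches,
    ignore_5prime = params$ignore_5prime,
    trim_3prime = params$trim_3prime,
    allowed_pams = unique(allowed),
    max_hits_reported = params$max_hits_reported,
    sensitivity = params$sensitivity
  )
  index <- build_seed_index(genome, k = params$seed_index_k)
  scored <- score_sites(sites, tree, index, genome, policy = policy,
                        on_target = params$on_target_score)

  order_keys <- trimws(strsplit(params$ranking, ",")[[1]])
  order_keys[order_keys == "efficacy"] <-
    if (params$on_target_score == "none") NA else params$on_target_score
  order_keys <- order_keys[!is.na(order_keys)]
  ranked <- rank_designs(scored, order = order_keys)

  config <- build_config(
    adapter5 = params$adapter5, adapter3 = params$adapter3,
    guides_per_gene = params$guides_per_gene,
    min_coverage = params$min_coverage,
    forbidden_sites = trimws(strsplit(params$forbidden_sites, ",")[[1]])
  )
  library <- assemble_and_filter(ranked, config)
  if (nrow(library) == 0L) stop("no design survived assembly/coverage filtering")
  paths <- write_outputs(library, out_dir)
  paths[["parameters"]] <- file.path(out_dir, "parameters.resolved.txt")
  write_run_parameters(params, paths[["parameters"]])

  summary <- regions["gene_id"] |>
    dplyr::left_join(n_scanned, by = "gene_id") |>
    dplyr::left_join(n_filtered, by = "gene_id") |>
    dplyr::left_join(dplyr::count(library, .data$gene_id, name = "designed"),
                     by = "gene_id") |>
    dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                ~ tidyr::replace_na(.x, 0L)))
  paths[["log"]] <- file.path(out_dir, "design_log.tsv")
  utils::write.table(summary, paths[["log"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (length(unresolved) > 0) {
    paths[["unresolved"]] <- file.path(out_dir, "unresolved_genes.txt")
    writeLines(unresolved, paths[["unresolved"]])
  }
  invisible(list(summary = summary, library = library,
                 unresolved = unresolved, paths = paths))
}
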