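#' Load a genome assembly from FASTA
#'
#' Reads every record of a FASTA file into an in-memory assembly. The
#' chromosome name is the header token before the first whitespace; sequences
#' are upper-cased. Duplicate chromosome names are an error.
#'
#' @param fasta_path Path to a FASTA file.
#' @return A `genome_assembly` object: named chromosome sequences with
#'   interval lookup via [genome_seq()].
#' @export
read_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  dna <- tryCatch(
    Biostrings::readDNAStringSet(fasta_path),
    error = function(e) stop("malformed FASTA (", fasta_path, "): ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(dna) == 0L) stop("FASTA contains no records: ", fasta_path)
  nm <- sub("\\s.*$", "", names(dna))
  if (anyDuplicated(nm)) {
    stop("duplicate chromosome name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  seqs <- toupper(as.character(dna))
  names(seqs) <- nm
  if (any(!nzchar(seqs))) {
    stop("empty sequence for chromosome(s): ",
         paste(nm[!nzchar(seqs)], collapse = ", "))
  }
  genome_assembly(seqs)
}

#' Construct a genome assembly from named sequences
#'
#' @param seqs Named character vector of chromosome sequences (A/C/G/T/N).
#' @return A `genome_assembly` object.
#' @export
genome_assembly <- function(seqs) {
  stopifnot(is.character(seqs), length(seqs) >= 1L,
            !is.null(names(seqs)), all(nzchar(names(seqs))))
  if (anyDuplicated(names(seqs))) stop("duplicate chromosome names")
  seqs <- toupper(seqs)
  if (any(grepl("[^ACGTN]", seqs))) {
    stop("genome sequences may contain only A/C/G/T/N")
  }
  structure(
    list(seq = seqs, lengths = nchar(seqs)),
    class = "genome_assembly"
  )
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat("<genome_assembly> ", length(x$seq), " chromosome(s), ",
      format(sum(x$lengths), big.mark = ","), " nt total\n", sep = "")
  nm <- utils::head(names(x$seq), 8)
  for (n in nm) cat("  ", n, ": ", x$lengths[[n]], " nt\n", sep = "")
  if (length(x$seq) > 8) cat("  ...\n")
  invisible(x)
}

#' Chromosome names and lengths of an assembly
#'
#' @param genome A `genome_assembly`.
#' @return A tibble with columns `chrom` and `length`.
#' @export
genome_chromosomes <- function(genome) {
  stopifnot(inherits(genome, "genome_assembly"))
  tibble::tibble(chrom = names(genome$seq), length = unname(genome$lengths))
}

#' Extract a genomic subsequence
#'
#' Coordinates are 0-based half-open: `genome_seq(g, "chr1", 0, 5)` returns
#' the first five bases.
#'
#' @param genome A `genome_assembly`.
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval; `start < end`.
#' @return The requested subsequence (upper-case string).
#' @export
genome_seq <- function(genome, chrom, start, end) {
  stopifnot(inherits(genome, "genome_assembly"))
  if (!chrom %in% names(genome$seq)) stop("unknown chromosome: ", chrom)
  len <- genome$lengths[[chrom]]
  if (start < 0 || end > len || start >= end) {
    stop(sprintf("interval [%d,%d) out of bounds for %s (length %d)",
                 start, end, chrom, len))
  }
  substr(genome$seq[[chrom]], start + 1L, end)
}

#' Write an assembly to FASTA
#'
#' @param genome A `genome_assembly`.
#' @param path Output file path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "genome_assembly"))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome$seq)) {
    writeLines(paste0(">", nm), con)
    s <- genome$seq[[nm]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
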