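# Shared sequence helpers. All user-facing coordinates in this package are
# 0-based half-open; conversion to/from 1-based closed happens only at the
# GFF boundary and when calling substr()/IRanges.

IUPAC_CLASSES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

# complement map covering the full IUPAC alphabet
IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

#' Reverse complement of nucleotide strings
#'
#' Vectorized over `x`; accepts the full IUPAC alphabet.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' revcomp(c("ACGT", "NGG"))
revcomp <- function(x) {
  stopifnot(is.character(x))
  out <- character(length(x))
  ok <- !is.na(x) & nzchar(x)
  out[!ok] <- x[!ok]
  if (any(ok)) {
    out[ok] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[ok]))
    )
  }
  out
}

#' Expand an IUPAC pattern into its concrete ACGT strings
#'
#' @param pattern A single IUPAC nucleotide string, e.g. `"NGG"`.
#' @return Character vector of all plain ACGT strings matching the pattern.
#' @export
#' @examples
#' iupac_expand("NGG")
iupac_expand <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  bad <- setdiff(chars, names(IUPAC_CLASSES))
  if (length(bad) > 0) {
    stop("invalid IUPAC code(s): ", paste(unique(bad), collapse = ", "))
  }
  sets <- lapply(chars, function(ch) strsplit(IUPAC_CLASSES[[ch]], "")[[1]])
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  sort(apply(grid[, rev(seq_along(sets)), drop = FALSE], 1, paste0, collapse = ""))
}

# does `x` (plain ACGT, single string) match IUPAC `pattern` of equal length?
iupac_matches <- function(x, pattern) {
  if (nchar(x) != nchar(pattern)) return(FALSE)
  grepl(iupac_regex(pattern), x, perl = TRUE)
}

iupac_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "", fixed = TRUE)[[1]]
  paste0("^", paste0(
    vapply(chars, function(ch) {
      cls <- IUPAC_CLASSES[[ch]]
      if (nchar(cls) == 1L) cls else paste0("[", cls, "]")
    }, character(1)),
    collapse = ""
  ), "$")
}

# scalar reverse complement for plain ACGTN strings; avoids XStringSet
# construction overhead in per-query hot paths
rc1 <- function(x) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", x))))
}

# random ACGT strings, n of length len, from the current RNG stream
random_dna <- function(n, len) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE),
              nrow = len)
  apply(m, 2, paste0, collapse = "")
}

# assert a scalar integer-ish value
assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
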