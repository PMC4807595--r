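# Independent oracles. These deliberately share no code path with the
# package implementation: brute-force scans, straight-line coefficient sums,
# and closed-form statistics used to freeze expected values.

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  vapply(x, function(s) {
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# exhaustive off-target oracle: every genomic window on either strand whose
# evaluated query (protospacer minus ignore5/trim3) is within `mm`
# mismatches AND whose protospacer-equivalent window carries an allowed PAM.
# Returns protospacer-equivalent 0-based starts, like find_offtargets().
oracle_offtargets <- function(genome, protospacer, mm, ignore5 = 0L,
                              trim3 = 0L, allowed_pams = NULL) {
  P <- nchar(protospacer)
  q <- substr(protospacer, ignore5 + 1L, P - trim3)
  m <- nchar(q)
  pamlen <- if (is.null(allowed_pams)) 0L else nchar(allowed_pams[1])
  qc <- strsplit(q, "")[[1]]
  qc_rc <- strsplit(oracle_revcomp(q), "")[[1]]
  out <- list()
  for (chrom in names(genome$seq)) {
    s <- genome$seq[[chrom]]
    L <- nchar(s)
    if (L < m) next
    ch <- strsplit(s, "")[[1]]
    n_win <- L - m + 1L
    mm_fwd <- integer(n_win); mm_rev <- integer(n_win)
    for (j in seq_len(m)) {
      seg <- ch[j:(j + n_win - 1L)]
      mm_fwd <- mm_fwd + (seg != qc[j])
      mm_rev <- mm_rev + (seg != qc_rc[j])
    }
    for (w in which(mm_fwd <= mm)) {
      ps <- (w - 1L) - ignore5           # 0-based protospacer start
      if (ps < 0 || ps + P + pamlen > L) next
      pam <- if (pamlen > 0) substr(s, ps + P + 1L, ps + P + pamlen) else ""
      if (is.null(allowed_pams) || pam %in% allowed_pams) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = ps, strand = "+",
          mismatch_count = mm_fwd[w], stringsAsFactors = FALSE)
      }
    }
    for (w in which(mm_rev <= mm)) {
      # rc(q) at 0-based w-1; protospacer-equivalent minus-strand window
      ps <- (w - 1L) - trim3
      if (ps - pamlen < 0 || ps + P > L) next
      pam <- if (pamlen > 0)
        oracle_revcomp(substr(s, ps - pamlen + 1L, ps)) else ""
      if (is.null(allowed_pams) || pam %in% allowed_pams) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, start = ps, strand = "-",
          mismatch_count = mm_rev[w], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      strand = character(), mismatch_count = integer()))
  }
  do.call(rbind, out)
}

# linear-scan overlap oracle over a feature data frame
oracle_overlaps <- function(features, chrom, start, end) {
  which(features$chrom == chrom & features$start < end & features$end > start)
}

# straight-line Rule Set 1 computation from the packaged table, written
# independently of the package's vectorized engine
oracle_doench <- function(context30) {
  rs <- rule_set1_weights()
  lt <- rs$intercept
  proto <- substr(context30, 5, 24)
  gc <- lengths(regmatches(proto, gregexpr("[GC]", proto)))
  lt <- lt + if (gc < 10) (10 - gc) * rs$gc_low else (gc - 10) * rs$gc_high
  w <- rs$weights
  for (i in seq_len(nrow(w))) {
    if (substr(context30, w$pos[i], w$pos[i] + nchar(w$seq[i]) - 1L) == w$seq[i]) {
      lt <- lt + w$weight[i]
    }
  }
  1 / (1 + exp(-lt))
}

oracle_xu <- function(context) {
  w <- xu_weights()
  ch <- strsplit(context, "")[[1]]
  total <- 0
  for (i in seq_along(ch)) total <- total + w[i, ch[i]]
  total
}

# closed-form Wilcoxon rank-sum p (normal approximation, tie correction,
# continuity correction), matching the documented test contract
oracle_wilcox_p <- function(x, y, alternative = "greater") {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  ties <- table(r)
  sigma <- sqrt((nx * ny / 12) *
                  ((nx + ny + 1) - sum(ties^3 - ties) /
                     ((nx + ny) * (nx + ny - 1))))
  if (alternative == "greater") {
    stats::pnorm((W - mu - 0.5) / sigma, lower.tail = FALSE)
  } else if (alternative == "less") {
    stats::pnorm((W - mu + 0.5) / sigma)
  } else {
    z <- W - mu
    z <- z - sign(z) * 0.5
    2 * min(stats::pnorm(z / sigma), stats::pnorm(z / sigma, lower.tail = FALSE), 0.5)
  }
}

# small random genome helper for property tests
random_genome <- function(len, n_chroms = 1L, seed = NULL) {
  draw <- function() {
    seqs <- vapply(seq_len(n_chroms), function(i) {
      paste0(sample(c("A", "C", "G", "T"), len, replace = TRUE),
             collapse = "")
    }, character(1))
    names(seqs) <- paste0("chr", seq_len(n_chroms))
    genome_assembly(seqs)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
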