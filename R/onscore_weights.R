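# Packaged on-target scoring constants.
#
# rule_set1: Doench 2014 "Rule Set 1" logistic-regression weights over a
# 30-mer context (4 nt 5' flank, 20 nt protospacer, 3 nt PAM, 3 nt 3'
# flank). Positions are 1-based within the 30-mer; `seq` is the single
# nucleotide or dinucleotide whose presence at that position adds `weight`
# to the linear term. The GC terms penalize protospacer GC counts away from
# 10. Table version: rule_set1/v1.

RULE_SET1_INTERCEPT <- 0.59763615
RULE_SET1_GC_LOW <- -0.2026259   # per unit of (10 - GC), GC < 10
RULE_SET1_GC_HIGH <- -0.1665878  # per unit of (GC - 10), GC >= 10

RULE_SET1_WEIGHTS <- tibble::tribble(
  ~pos, ~seq, ~weight,
  2L, "G", -0.2753771,
  3L, "A", -0.3238875,
  3L, "C", 0.17212887,
  4L, "C", -0.1006662,
  5L, "C", -0.2018029,
  5L, "G", 0.24595663,
  6L, "A", 0.03644004,
  6L, "C", 0.09837684,
  7L, "C", -0.7411813,
  7L, "G", -0.3932644,
  12L, "A", -0.466099,
  15L, "A", 0.08537695,
  15L, "C", -0.013814,
  16L, "A", 0.27262051,
  16L, "C", -0.1190226,
  16L, "T", -0.2859442,
  17L, "C", 0.09745459,
  17L, "G", -0.1755462,
  18L, "C", -0.3457955,
  18L, "G", -0.6780964,
  19L, "A", 0.22508903,
  19L, "C", -0.5077941,
  20L, "G", -0.4173736,
  20L, "T", -0.054307,
  21L, "G", 0.37989937,
  21L, "T", -0.0907126,
  22L, "C", 0.05782332,
  22L, "T", -0.5305673,
  23L, "T", -0.8770074,
  24L, "C", -0.8762358,
  24L, "G", 0.27891626,
  24L, "T", -0.4031022,
  25L, "A", -0.0773007,
  25L, "C", 0.28793562,
  25L, "T", -0.2216372,
  28L, "G", -0.6890167,
  28L, "T", 0.11787758,
  29L, "C", -0.1604453,
  30L, "G", 0.38634258,
  2L, "GT", -0.6257787,
  5L, "GC", 0.30004332,
  6L, "AA", -0.8348362,
  6L, "TA", 0.76062777,
  7L, "GG", -0.4908167,
  12L, "GG", -1.5169074,
  12L, "TA", 0.7092612,
  12L, "TC", 0.49629861,
  12L, "TT", -0.5868739,
  13L, "GG", -0.3345637,
  14L, "GA", 0.76384993,
  14L, "GC", -0.5370252,
  17L, "TG", -0.7981461,
  19L, "GG", -0.6668087,
  19L, "TC", 0.35318325,
  20L, "CC", 0.74807209,
  20L, "TG", -0.3672668,
  21L, "AC", 0.56820913,
  21L, "CG", 0.32907207,
  21L, "GA", -0.8364568,
  21L, "GG", -0.7822076,
  22L, "TC", -1.029693,
  23L, "CG", 0.85619782,
  23L, "CT", -0.4632077,
  24L, "AA", -0.5794924,
  24L, "AG", 0.64907554,
  25L, "AG", -0.0773007,
  25L, "CG", 0.28793562,
  25L, "TG", -0.2216372,
  28L, "GT", 0.11787758,
  29L, "GG", -0.6978789
)

#' Rule Set 1 coefficient table
#'
#' The packaged Doench-2014-style logistic-regression constants used by
#' [doench_score()]: intercept, GC-count terms, and position-specific mono-
#' and dinucleotide weights over the 30-mer context. Positions are 1-based
#' within the 30-mer (protospacer occupies positions 5-24, PAM 25-27).
#'
#' @return A list with `intercept`, `gc_low`, `gc_high` and a `weights`
#'   tibble (`pos`, `seq`, `weight`).
#' @export
rule_set1_weights <- function() {
  list(intercept = RULE_SET1_INTERCEPT,
       gc_low = RULE_SET1_GC_LOW,
       gc_high = RULE_SET1_GC_HIGH,
       weights = RULE_SET1_WEIGHTS,
       version = "rule_set1/v1")
}

# Position-by-base weight matrix for the linear on-target score of
# xu_score(). Rows = positions 1..30 of the same 30-mer context, columns =
# A/C/G/T. SYNTHETIC CALIBRATION: the matrix reproduces the qualitative
# structure of published spacer position-weight scores (strong PAM-proximal
# effects, G favoured at protospacer position 20, weak distal effects) but
# its numeric values are a packaged calibration of this package, not a
# verified transcription of any publication. Table version: pwm/v1-synthetic.
XU_WEIGHTS <- local({
  m <- matrix(0, nrow = 30, ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  w <- rbind(
    # pos  A       C       G       T
    c(14, 0.024, 0.000, -0.020, 0.000),
    c(15, 0.000, -0.066, 0.000, 0.000),
    c(16, 0.000, -0.113, 0.091, 0.000),
    c(17, 0.000, 0.000, 0.064, -0.066),
    c(18, 0.000, -0.094, 0.088, 0.000),
    c(19, 0.000, -0.044, 0.000, -0.077),
    c(20, 0.000, 0.000, 0.063, -0.038),
    c(21, 0.000, -0.064, 0.075, -0.079),
    c(22, 0.037, 0.000, 0.000, -0.087),
    c(23, 0.000, -0.026, 0.207, -0.055),
    c(24, 0.000, 0.000, 0.266, -0.099),
    c(28, 0.000, 0.000, 0.048, 0.000),
    c(29, 0.031, 0.000, 0.000, -0.046),
    c(30, 0.000, 0.000, 0.037, 0.000)
  )
  for (i in seq_len(nrow(w))) m[w[i, 1], ] <- w[i, 2:5]
  m
})

#' Position-weight matrix of the linear on-target score
#'
#' Constants used by [xu_score()]. The matrix is a synthetic calibration
#' shipped with this package (see the source comment for provenance); the
#' scoring engine itself — a position-by-base linear sum — is exact.
#'
#' @return A 30 x 4 numeric matrix (positions x A/C/G/T).
#' @export
xu_weights <- function() XU_WEIGHTS
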