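DNA_BASES <- c("A", "C", "G", "T")

# IUPAC nucleotide codes as base sets, keyed by the sorted base string.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)
# reverse map: sorted concatenated base set -> code
IUPAC_FROM_SET <- setNames(
  names(IUPAC_SETS),
  vapply(IUPAC_SETS, function(b) paste(sort(b), collapse = ""), "")
)

is_dna <- function(x) {
  length(x) == 1L && is.character(x) && !is.na(x) && nzchar(x) &&
    !grepl("[^ACGT]", x)
}

assert_dna <- function(x, what = deparse(substitute(x))) {
  if (!is_dna(x)) {
    stop(sprintf("'%s' must be a non-empty string over A/C/G/T", what),
         call. = FALSE)
  }
  invisible(x)
}

assert_prob <- function(x, what = deparse(substitute(x))) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("'%s' must be a single probability in [0, 1]", what),
         call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, what = deparse(substitute(x)), min = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", what, min),
         call. = FALSE)
  }
  invisible(x)
}

#' Derive a per-stage RNG seed from a master seed
#'
#' Every simulator fans a single user seed out to independent per-stage
#' streams with a fixed multiplicative congruential rule, so that adding a
#' stage (or a replicate) never perturbs the draws of another stage. The
#' result always lies in `[1, 2^31 - 2]`.
#'
#' @param seed master seed (single integer).
#' @param stage stage index (single non-negative integer); replicate `r`,
#'   stage `s` conventionally uses `stage = 100 * r + s`.
#' @return a single integer seed.
#' @export
#' @examples
#' fan_seed(1, 1)
#' fan_seed(1, 2)
fan_seed <- function(seed, stage) {
  assert_count(seed, "seed", min = 0)
  assert_count(stage, "stage", min = 0)
  m <- 2147483647 # 2^31 - 1 (prime)
  x <- (as.numeric(seed) %% m)
  x <- (x * 48271 + as.numeric(stage) * 69621 + 1) %% m
  as.integer(x) + 1L
}

# Random DNA strings: n strings of length len (uniform over ACGT).
random_dna <- function(n, len) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# In-place substitution errors at per-base rate; substitutions only, each
# error replaced by a uniformly chosen different base. Vector of sequences
# may have unequal lengths.
apply_seq_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  lens <- nchar(seqs)
  total <- sum(lens)
  n_err <- rbinom(1L, total, rate)
  if (n_err == 0L) return(seqs)
  idx <- sample.int(total, n_err)
  ends <- cumsum(lens)
  read_i <- findInterval(idx - 1L, ends) + 1L
  pos <- idx - c(0L, ends)[read_i]
  for (e in seq_len(n_err)) {
    r <- read_i[e]; p <- pos[e]
    old <- substr(seqs[r], p, p)
    new <- sample(setdiff(DNA_BASES, old), 1L)
    substr(seqs[r], p, p) <- new
  }
  seqs
}

# reverse complement for plain character vectors
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
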