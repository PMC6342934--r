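#' Locate the fixed protospacer anchor in reads
#'
#' Substitution-only sliding scan for the best anchor occurrence with at
#' most `max_mismatches` mismatches; on mismatch-count ties the leftmost
#' occurrence wins. `N` in a read never matches. Gapped matches are
#' deliberately not considered: the randomized PAM window is defined by its
#' fixed offset from the anchor, so an indel between them would make the
#' extraction meaningless.
#'
#' @param reads character vector of read sequences (or a
#'   `Biostrings::DNAStringSet`).
#' @param anchor anchor sequence over A/C/G/T.
#' @param max_mismatches maximum substitutions tolerated (default 1).
#' @return integer vector of 0-based anchor start positions, `NA` where no
#'   occurrence qualifies. The mismatch count of each hit is attached as
#'   attribute `mismatches`.
#' @export
#' @examples
#' locate_anchor(c("AAAACGTGG", "TTTTTTTTT"), "CGT", 0)
locate_anchor <- function(reads, anchor, max_mismatches = 1L) {
  reads <- as.character(reads)
  assert_dna(anchor)
  assert_count(max_mismatches, "max_mismatches", min = 0)
  hits <- .anchor_scan(reads, anchor, as.integer(max_mismatches))
  pos <- hits[1L, ]
  mm <- hits[2L, ]
  pos[pos < 0L] <- NA_integer_
  mm[is.na(pos)] <- NA_integer_
  structure(pos, mismatches = mm)
}

#' Extract the randomized PAM window 5' of the anchor
#'
#' Returns the `k` bases ending immediately before the anchor, written
#' 5' to 3' (so the last character is position -1, adjacent to the
#' protospacer). Windows that are truncated (fewer than `k` bases upstream)
#' or contain non-A/C/G/T characters yield `NA`.
#'
#' @param reads character vector of read sequences.
#' @param anchor_pos 0-based anchor start positions from [locate_anchor()]
#'   (NA propagates).
#' @param k PAM window length (8 for the raw randomized region).
#' @return character vector of k-mers with `NA` for invalid windows.
#' @export
extract_pam <- function(reads, anchor_pos, k = 8L) {
  reads <- as.character(reads)
  assert_count(k, "k")
  stopifnot(length(anchor_pos) == length(reads))
  out <- rep(NA_character_, length(reads))
  ok <- !is.na(anchor_pos) & anchor_pos >= k
  if (any(ok)) {
    # anchor_pos is 0-based: window is [anchor_pos - k, anchor_pos)
    w <- substr(reads[ok], anchor_pos[ok] - k + 1L, anchor_pos[ok])
    w[grepl("[^ACGT]", w)] <- NA_character_
    out[ok] <- w
  }
  out
}

#' Condense raw 8-mer PAMs by dropping the two most distal positions
#'
#' The screen showed no sequence preference 7-8 bp upstream of the spacer,
#' so count tables are condensed to the 6 positions nearest the
#' protospacer: the first `nchar - to` characters (positions -8, -7 for an
#' 8-mer) are dropped.
#'
#' @param pams character vector of PAMs over A/C/G/T, all the same length.
#' @param to condensed length (default 6; must be shorter than the input).
#' @return character vector of condensed PAMs.
#' @export
#' @examples
#' condense_pam("GCATTACA")
condense_pam <- function(pams, to = 6L) {
  assert_count(to, "to")
  k <- unique(nchar(pams))
  if (length(k) != 1L || is.na(k)) {
    stop("all PAMs must be non-NA and of equal length", call. = FALSE)
  }
  if (k <= to) stop("PAMs must be longer than 'to' to condense", call. = FALSE)
  if (any(grepl("[^ACGT]", pams))) {
    stop("PAMs must be over A/C/G/T", call. = FALSE)
  }
  substr(pams, k - to + 1L, k)
}

#' Count PAMs in a read set
#'
#' Runs [locate_anchor()] then [extract_pam()] (then [condense_pam()] when
#' `condense = TRUE`) and tallies the valid PAM windows. Reads with no
#' anchor hit, a truncated window, or non-A/C/G/T bases in the window count
#' toward `total_reads` only.
#'
#' @param reads character vector / `DNAStringSet` of reads, or a path to a
#'   FASTQ file (gzip transparent).
#' @param anchor anchor sequence (default [FNPSP1]).
#' @param max_mismatches anchor mismatch tolerance.
#' @param k raw PAM window length.
#' @param condense condense to the 6 positions nearest the protospacer?
#' @param both_strands also search the reverse-complemented read when the
#'   forward orientation has no anchor hit (off by default; the library
#'   orientation is fixed by the sequencing primer).
#' @param sample_id,replicate_id bookkeeping labels.
#' @return an object of class `pam_count_table`: list with `k`, `counts`
#'   (named integer vector, names are PAMs), `total_reads`, `valid_reads`,
#'   `sample_id`, `replicate_id`.
#' @export
#' @examples
#' reads <- paste0("ACGT", c("GCATTACA", "GCATTACA", "TTTTTTTT"), FNPSP1)
#' count_pams(reads, max_mismatches = 0, condense = FALSE)
count_pams <- function(reads, anchor = FNPSP1, max_mismatches = 1L, k = 8L,
                       condense = TRUE, both_strands = FALSE,
                       sample_id = NA_character_,
                       replicate_id = NA_character_) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  reads <- as.character(reads)
  pos <- locate_anchor(reads, anchor, max_mismatches)
  if (both_strands && anyNA(pos)) {
    miss <- which(is.na(pos))
    rc <- revcomp(reads[miss])
    rc_pos <- locate_anchor(rc, anchor, max_mismatches)
    found <- !is.na(rc_pos)
    reads[miss[found]] <- rc[found]
    pos[miss[found]] <- rc_pos[found]
  }
  pams <- extract_pam(reads, pos, k = k)
  pams <- pams[!is.na(pams)]
  if (condense && length(pams)) pams <- condense_pam(pams)
  counts <- if (length(pams)) {
    tab <- table(pams)
    setNames(as.integer(tab), names(tab))
  } else {
    setNames(integer(0), character(0))
  }
  structure(list(k = if (condense) 6L else as.integer(k),
                 counts = counts,
                 total_reads = length(reads),
                 valid_reads = length(pams),
                 sample_id = sample_id, replicate_id = replicate_id),
            class = "pam_count_table")
}

#' @export
print.pam_count_table <- function(x, ...) {
  cat(sprintf(
    "pam_count_table: k=%d, %d distinct PAMs, %d/%d valid reads%s\n",
    x$k, length(x$counts), x$valid_reads, x$total_reads,
    if (is.na(x$sample_id)) "" else paste0(" [", x$sample_id, "]")))
  if (length(x$counts)) {
    print(head(sort(x$counts, decreasing = TRUE), 5L))
  }
  invisible(x)
}
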