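# Synthetic 200-nt amplicon standing in for a Cas12b-targetable locus:
# ATTC PAM at [60,64), 23-nt protospacer at [64,87), TG dinucleotide at
# [86,88) that the ssODN donor converts to CA. Constructed, not a genomic
# sequence.
SYNTHETIC_AMPLICON_SEQ <- paste0(
  "GGCCGCCAGCTTAGGTCGTAAGATAACCATGCAGCAAAAATTTAGTGCTGGATGCTCGGG",
  "ATTCACCGCCTTGATATAAAGCGTTTTGAAGAAATCGGCC",
  "AAAGGAGTTAAGACTAAGATGATAAAGGTGGTCACTACGAAACGTAGCCATCACACAATG",
  "GTAGATATTACTGAGACGTGCGGTCCCATTTCCCGAAACA")

#' Annotated amplicon reference for edit-outcome calling
#'
#' Bundles the reference sequence with the intervals the caller needs: the
#' PAM, the protospacer, the window in which indels are attributed to the
#' nuclease cut, the 36-nt window in which an HDR outcome must match the
#' donor exactly to count as a perfect edit, and the list of donor edits.
#' All intervals are 0-based half-open on the reference.
#'
#' @param sequence reference amplicon sequence (A/C/G/T).
#' @param pam integer interval `c(start, end)` of the PAM.
#' @param spacer integer interval of the protospacer (23 nt by default
#'   design; other lengths are allowed but flagged).
#' @param cut_window interval in which net indels are counted as nuclease
#'   edits (default design: 20 bp over the PAM-distal end of the
#'   protospacer, where Cas12-family nucleases cut).
#' @param hdr_window 36-nt interval defining the perfect-edit test.
#' @param donor_edits data.frame with columns `start` (0-based position on
#'   the reference), `ref`, `alt` (equal-length base strings; substitutions
#'   only) and `primary` (logical; exactly one TRUE row marks the
#'   conversion edit, e.g. TG-to-CA, whose presence defines a converted
#'   read).
#' @return an object of class `amplicon_reference`.
#' @seealso [default_amplicon_reference()], [donor_sequence()]
#' @export
amplicon_reference <- function(sequence, pam, spacer, cut_window, hdr_window,
                               donor_edits) {
  assert_dna(sequence)
  L <- nchar(sequence)
  chk_iv <- function(iv, what) {
    if (!is.numeric(iv) || length(iv) != 2L || anyNA(iv) ||
        iv[1] < 0 || iv[2] > L || iv[1] >= iv[2]) {
      stop(sprintf("'%s' must be a 0-based half-open interval within [0, %d)",
                   what, L), call. = FALSE)
    }
    as.integer(iv)
  }
  pam <- chk_iv(pam, "pam")
  spacer <- chk_iv(spacer, "spacer")
  cut_window <- chk_iv(cut_window, "cut_window")
  hdr_window <- chk_iv(hdr_window, "hdr_window")
  if (diff(hdr_window) != 36L) {
    stop("'hdr_window' must have length 36", call. = FALSE)
  }
  if (diff(spacer) != 23L) {
    warning("protospacer length is ", diff(spacer), ", not the 23-nt default")
  }
  stopifnot(is.data.frame(donor_edits),
            all(c("start", "ref", "alt", "primary") %in% names(donor_edits)),
            nrow(donor_edits) >= 1L, sum(donor_edits$primary) == 1L)
  for (i in seq_len(nrow(donor_edits))) {
    st <- donor_edits$start[i]
    rf <- donor_edits$ref[i]; al <- donor_edits$alt[i]
    if (nchar(rf) != nchar(al)) {
      stop("donor edits must be substitutions (ref and alt same length)",
           call. = FALSE)
    }
    if (substr(sequence, st + 1L, st + nchar(rf)) != rf) {
      stop(sprintf("donor edit %d: reference does not carry '%s' at %d",
                   i, rf, st), call. = FALSE)
    }
  }
  structure(list(sequence = sequence, pam = pam, spacer = spacer,
                 cut_window = cut_window, hdr_window = hdr_window,
                 donor_edits = donor_edits),
            class = "amplicon_reference")
}

#' Default synthetic amplicon target
#'
#' A constructed 200-nt amplicon emulating an ssODN-editable locus: ATTC PAM at `[60, 64)`, 23-nt protospacer at
#' `[64, 87)`, cut window `[77, 97)`, 36-nt HDR window `[69, 105)`, and a
#' donor carrying the primary TG-to-CA conversion at `[86, 88)` plus a
#' PAM-disrupting T-to-C change at position 62.
#'
#' @return an [amplicon_reference()].
#' @export
default_amplicon_reference <- function() {
  amplicon_reference(
    sequence = SYNTHETIC_AMPLICON_SEQ,
    pam = c(60L, 64L),
    spacer = c(64L, 87L),
    cut_window = c(77L, 97L),
    hdr_window = c(69L, 105L),
    donor_edits = data.frame(
      start = c(86L, 62L),
      ref = c("TG", "T"),
      alt = c("CA", "C"),
      primary = c(TRUE, FALSE),
      stringsAsFactors = FALSE
    )
  )
}

# reference with all donor edits applied (coordinates unchanged;
# substitutions only)
edited_sequence <- function(ref) {
  s <- ref$sequence
  for (i in seq_len(nrow(ref$donor_edits))) {
    st <- ref$donor_edits$start[i]
    al <- ref$donor_edits$alt[i]
    substr(s, st + 1L, st + nchar(al)) <- al
  }
  s
}

#' ssODN donor sequence for an amplicon reference
#'
#' The donor is the donor-edited reference restricted to a window of
#' `length` nt centered on the primary conversion edit (120 nt by default,
#' a standard ssODN length), so its homology arms match the reference
#' outside the edits.
#'
#' @param ref an [amplicon_reference()].
#' @param length donor length in nt.
#' @return list with `sequence` (the donor) and `start` (0-based offset of
#'   the donor on the reference).
#' @export
donor_sequence <- function(ref, length = 120L) {
  stopifnot(inherits(ref, "amplicon_reference"))
  assert_count(length, "length")
  pe <- ref$donor_edits[ref$donor_edits$primary, , drop = FALSE]
  center <- pe$start[1] + nchar(pe$ref[1]) / 2
  start <- as.integer(round(center - length / 2))
  start <- max(0L, min(start, nchar(ref$sequence) - length))
  if (start < 0L) stop("donor longer than the reference", call. = FALSE)
  list(sequence = substr(edited_sequence(ref), start + 1L, start + length),
       start = start)
}

#' @export
print.amplicon_reference <- function(x, ...) {
  cat(sprintf(paste0("amplicon_reference: %d nt; PAM [%d,%d) '%s'; ",
                     "protospacer [%d,%d); cut_window [%d,%d); ",
                     "hdr_window [%d,%d); %d donor edit(s)\n"),
              nchar(x$sequence), x$pam[1], x$pam[2],
              substr(x$sequence, x$pam[1] + 1L, x$pam[2]),
              x$spacer[1], x$spacer[2], x$cut_window[1], x$cut_window[2],
              x$hdr_window[1], x$hdr_window[2], nrow(x$donor_edits)))
  invisible(x)
}
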