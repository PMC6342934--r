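#' Default alignment scoring for amplicon reads
#'
#' Match +2, mismatch -3, gap open -6, gap extend -1; a gap of length L
#' scores `gap_open + L * gap_extend`.
#' @return named list of the four scoring parameters.
#' @export
default_scoring <- function() {
  list(match = 2, mismatch = -3, gap_open = -6, gap_extend = -1)
}

#' Align a read to an amplicon reference
#'
#' Affine-gap alignment (Gotoh's three-state recurrence), global in the
#' read; by default the reference ends are free (fitting alignment), so a
#' read covering only part of the amplicon aligns without end-gap penalty
#' and its unaligned reference flanks are not reported as deletion events.
#' Among equal-scoring alignments, gaps are placed leftmost (5'-most),
#' making indel placement in homopolymers deterministic.
#'
#' @param read read sequence (non-empty).
#' @param ref an [amplicon_reference()] or a plain reference sequence.
#' @param scoring list with `match`, `mismatch`, `gap_open`, `gap_extend`
#'   (see [default_scoring()]); a gap of length L scores
#'   `gap_open + L * gap_extend`.
#' @param free_ref_ends penalty-free unaligned reference flanks (default
#'   TRUE); with FALSE the alignment is fully global and terminal gaps are
#'   reported as events.
#' @return an object of class `read_alignment`: list with `score`,
#'   `aligned_ref`/`aligned_read` (gapped strings), `events` (data.frame
#'   `type` del/ins, `ref_start` 0-based, `length` signed: negative =
#'   deletion), and `substitutions` (data.frame `ref_pos`, `ref`, `read`).
#'   Removing the gap characters reproduces the inputs.
#' @export
#' @examples
#' aln <- align_read("ACGTAAA", "ACGTTTTAAA")
#' aln$events
align_read <- function(read, ref, scoring = default_scoring(),
                       free_ref_ends = TRUE) {
  refseq <- if (inherits(ref, "amplicon_reference")) ref$sequence else ref
  if (!is.character(read) || length(read) != 1L || is.na(read) ||
      !nzchar(read)) {
    stop("'read' must be a single non-empty sequence", call. = FALSE)
  }
  raw <- .gotoh_align(refseq, read, scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend, free_ref_ends)
  ar <- strsplit(raw$aligned_ref, "")[[1]]
  aq <- strsplit(raw$aligned_read, "")[[1]]
  # 0-based ref coordinate of each alignment column (position of the ref
  # base in that column; for insertion columns, the next ref position)
  ref_pos <- cumsum(ar != "-") - (ar != "-")

  gap_read <- aq == "-"
  gap_ref <- ar == "-"
  events <- data.frame(type = character(0), ref_start = integer(0),
                       length = integer(0), stringsAsFactors = FALSE)
  runs <- rle(ifelse(gap_read, "D", ifelse(gap_ref, "I", "M")))
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep_runs <- which(runs$values != "M")
  if (free_ref_ends) {
    # terminal deletion runs are unaligned reference flanks, not events
    keep_runs <- setdiff(keep_runs,
                         c(which(runs$values == "D" & starts == 1L),
                           which(runs$values == "D" &
                                   ends == length(ar))))
  }
  for (r in keep_runs) {
    col <- starts[r]
    events <- rbind(events, data.frame(
      type = if (runs$values[r] == "D") "del" else "ins",
      ref_start = ref_pos[col],
      length = if (runs$values[r] == "D") -runs$lengths[r]
               else runs$lengths[r],
      stringsAsFactors = FALSE))
  }
  sub <- !gap_read & !gap_ref & ar != aq
  substitutions <- data.frame(ref_pos = ref_pos[sub], ref = ar[sub],
                              read = aq[sub], stringsAsFactors = FALSE)
  structure(list(score = raw$score,
                 aligned_ref = raw$aligned_ref,
                 aligned_read = raw$aligned_read,
                 events = events, substitutions = substitutions,
                 scoring = scoring, read_len = nchar(read)),
            class = "read_alignment")
}

# net indel length within a 0-based half-open window: deletions count when
# their deleted ref interval intersects the window, insertions when their
# insertion point lies in [start, end]
net_indel_in_window <- function(events, window) {
  if (nrow(events) == 0L) return(0L)
  w1 <- window[1]; w2 <- window[2]
  hit <- ifelse(events$type == "del",
                events$ref_start < w2 & events$ref_start - events$length > w1,
                events$ref_start >= w1 & events$ref_start <= w2)
  sum(events$length[hit])
}

#' Classify an aligned amplicon read
#'
#' Precedence: (1) all donor edits present and the 36-nt HDR window an
#' exact, gap-free match to the donor-edited reference gives
#' `HDR_PERFECT`; (2) otherwise the primary conversion edit present gives
#' `HDR_CONVERTED` (a co-occurring indel is noted but does not change the
#' class); (3) otherwise a nonzero net indel within the cut window gives
#' `INDEL`; (4) otherwise `WT`. Reads whose alignment score falls below
#' `min_score_frac` of the perfect-match score are `AMBIGUOUS`.
#' Substitutions outside the HDR window never change the class, which makes
#' calls robust to sequencing errors.
#'
#' @param aln a [align_read()] result.
#' @param ref the [amplicon_reference()] the read was aligned to.
#' @param min_score_frac alignment-quality floor as a fraction of
#'   `match * read_length` (default 0.5).
#' @return an object of class `edit_call`: list with `class`,
#'   `net_indel_length` (0 unless INDEL) and `notes`.
#' @export
classify_read <- function(aln, ref, min_score_frac = 0.5) {
  stopifnot(inherits(aln, "read_alignment"),
            inherits(ref, "amplicon_reference"))
  mk <- function(class, net = 0L, notes = "") {
    structure(list(class = class, net_indel_length = as.integer(net),
                   notes = notes), class = "edit_call")
  }
  if (aln$score < min_score_frac * aln$scoring$match * aln$read_len) {
    return(mk("AMBIGUOUS", notes = "alignment score below quality floor"))
  }
  ar <- strsplit(aln$aligned_ref, "")[[1]]
  aq <- strsplit(aln$aligned_read, "")[[1]]
  keep <- ar != "-"
  read_at_ref <- aq[keep] # read char aligned over each ref position, or '-'
  L <- length(read_at_ref)

  edit_present <- function(start, alt) {
    idx <- start + seq_len(nchar(alt)) # 1-based ref index
    if (any(idx > L)) return(FALSE)
    identical(paste(read_at_ref[idx], collapse = ""), alt)
  }
  edits <- ref$donor_edits
  all_present <- all(vapply(seq_len(nrow(edits)), function(i) {
    edit_present(edits$start[i], edits$alt[i])
  }, logical(1)))
  net <- net_indel_in_window(aln$events, ref$cut_window)

  if (all_present) {
    w1 <- ref$hdr_window[1]; w2 <- ref$hdr_window[2]
    win_read <- paste(read_at_ref[(w1 + 1L):w2], collapse = "")
    win_donor <- substr(edited_sequence(ref), w1 + 1L, w2)
    ins_inside <- nrow(aln$events) > 0L &&
      any(aln$events$type == "ins" & aln$events$ref_start > w1 &
            aln$events$ref_start < w2)
    if (identical(win_read, win_donor) && !ins_inside) {
      return(mk("HDR_PERFECT"))
    }
  }
  primary <- edits[edits$primary, , drop = FALSE]
  if (edit_present(primary$start[1], primary$alt[1])) {
    return(mk("HDR_CONVERTED",
              notes = if (net != 0L) "conversion with additional indel"
                      else ""))
  }
  if (net != 0L) return(mk("INDEL", net = net))
  mk("WT")
}

#' Align and classify a batch of amplicon reads
#'
#' @param reads named character vector of reads (or a FASTQ path).
#' @param ref an [amplicon_reference()].
#' @param scoring see [default_scoring()].
#' @param min_read_len reads shorter than this are excluded before
#'   alignment and reported via the `n_filtered` attribute (default 40).
#' @param min_score_frac see [classify_read()].
#' @return data.frame with `read_id`, `class`, `net_indel_length`, `score`,
#'   `notes`; attribute `n_filtered` counts length-filtered reads.
#' @export
call_edits <- function(reads, ref, scoring = default_scoring(),
                       min_read_len = 40L, min_score_frac = 0.5) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  nm <- names(reads)
  reads <- as.character(reads)
  names(reads) <- if (is.null(nm)) {
    sprintf("read_%06d", seq_along(reads))
  } else {
    nm
  }
  short <- nchar(reads) < min_read_len
  kept <- reads[!short]
  rows <- lapply(seq_along(kept), function(i) {
    aln <- align_read(kept[i], ref, scoring)
    cl <- classify_read(aln, ref, min_score_frac)
    data.frame(read_id = names(kept)[i], class = cl$class,
               net_indel_length = cl$net_indel_length, score = aln$score,
               notes = cl$notes, stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(read_id = character(0), class = character(0),
               net_indel_length = integer(0), score = numeric(0),
               notes = character(0), stringsAsFactors = FALSE)
  }
  attr(out, "n_filtered") <- sum(short)
  out
}

#' Summarize edit-outcome calls
#'
#' Rates are percentages of classified (non-AMBIGUOUS) reads: the indel
#' rate, the mean absolute net indel length over INDEL reads, the net-length
#' histogram, the conversion rate (reads carrying the donor conversion,
#' perfect or not) and the perfect-edit rate.
#'
#' @param calls data.frame from [call_edits()] (columns `class`,
#'   `net_indel_length`).
#' @return an object of class `edit_summary`: list with `n_reads`,
#'   `n_classified`, `n_filtered`, `indel_rate`, `mean_abs_indel_length`,
#'   `length_histogram`, `hdr_converted_rate`, `hdr_perfect_rate`.
#' @export
summarize_edits <- function(calls) {
  stopifnot(is.data.frame(calls),
            all(c("class", "net_indel_length") %in% names(calls)))
  cls <- calls$class
  classified <- cls != "AMBIGUOUS"
  n_cls <- sum(classified)
  if (n_cls == 0L) stop("no classifiable reads", call. = FALSE)
  ind <- classified & cls == "INDEL"
  n_perf <- sum(cls == "HDR_PERFECT")
  n_conv <- sum(cls %in% c("HDR_CONVERTED", "HDR_PERFECT"))
  lens <- calls$net_indel_length[ind]
  structure(list(
    n_reads = nrow(calls),
    n_classified = n_cls,
    n_filtered = attr(calls, "n_filtered") %||% 0L,
    indel_rate = 100 * sum(ind) / n_cls,
    mean_abs_indel_length = if (any(ind)) mean(abs(lens)) else NA_real_,
    length_histogram = table(factor(lens)),
    hdr_converted_rate = 100 * n_conv / n_cls,
    hdr_perfect_rate = 100 * n_perf / n_cls
  ), class = "edit_summary")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.edit_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "edit_summary: %d reads (%d classified, %d filtered)\n",
    "  indel rate          %6.2f %%\n",
    "  mean |indel| length %6.2f nt\n",
    "  HDR converted rate  %6.2f %%\n",
    "  HDR perfect rate    %6.2f %%\n"),
    x$n_reads, x$n_classified, x$n_filtered, x$indel_rate,
    if (is.na(x$mean_abs_indel_length)) NaN else x$mean_abs_indel_length,
    x$hdr_converted_rate, x$hdr_perfect_rate))
  invisible(x)
}

#' @export
print.read_alignment <- function(x, ...) {
  cat(sprintf("read_alignment: score %.1f, %d event(s), %d substitution(s)\n",
              x$score, nrow(x$events), nrow(x$substitutions)))
  cat(" ref:", x$aligned_ref, "\n")
  cat("read:", x$aligned_read, "\n")
  invisible(x)
}
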