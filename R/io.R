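#' Read a FASTQ file as a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] (gzip transparent);
#' qualities are not used anywhere in the pipeline and are dropped.
#'
#' @param path FASTQ file.
#' @return named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(x), names(x))
}

#' Write reads as 4-line FASTQ with constant quality
#'
#' @param reads named character vector of sequences.
#' @param path output file (`.gz` suffix compresses).
#' @param quality_char constant Phred+33 quality character (default `"I"`,
#'   Q40).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  if (is.null(names(reads))) {
    names(reads) <- sprintf("read_%06d", seq_along(reads))
  }
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::BStringSet(strrep(quality_char, nchar(reads)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write a reference as FASTA
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write / read a PAM count table as TSV
#'
#' The TSV body is `pam<TAB>count`; bookkeeping (`k`, totals, sample and
#' replicate ids, coordinate convention) travels in `# key: value` header
#' lines.
#'
#' @param table a [count_pams()] table.
#' @param path file path.
#' @return `path` (write) or a `pam_count_table` (read).
#' @export
write_pam_counts <- function(table, path) {
  stopifnot(inherits(table, "pam_count_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# k: %d", table$k),
    sprintf("# total_reads: %d", table$total_reads),
    sprintf("# valid_reads: %d", table$valid_reads),
    sprintf("# sample_id: %s", table$sample_id),
    sprintf("# replicate_id: %s", table$replicate_id),
    "# positions: 5'->3', -1 adjacent to the protospacer",
    "pam\tcount"), con)
  if (length(table$counts)) {
    writeLines(paste(names(table$counts), table$counts, sep = "\t"), con)
  }
  invisible(path)
}

#' @rdname write_pam_counts
#' @export
read_pam_counts <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  get <- function(key) {
    v <- sub(sprintf("^# %s: ", key), "",
             grep(sprintf("^# %s: ", key), hdr, value = TRUE))
    if (length(v)) v[1] else NA_character_
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[-1L] # column header
  counts <- if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    setNames(as.integer(vapply(parts, `[`, "", 2L)),
             vapply(parts, `[`, "", 1L))
  } else {
    setNames(integer(0), character(0))
  }
  structure(list(k = as.integer(get("k")), counts = counts,
                 total_reads = as.integer(get("total_reads")),
                 valid_reads = as.integer(get("valid_reads")),
                 sample_id = get("sample_id"),
                 replicate_id = get("replicate_id")),
            class = "pam_count_table")
}

#' Write a depletion table (or set) as TSV
#' @param table a [compute_depletion()] or [combine_depletion()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_depletion <- function(table, path) {
  stopifnot(is.data.frame(table))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# k: %d", attr(table, "k")), con)
  write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Export a motif as a transfac-style count matrix
#'
#' Plain-text matrix consumable by sequence-logo tools: one row per
#' position with A/C/G/T frequencies scaled by the number of PAMs.
#'
#' @param motif a [build_motif()] result.
#' @param path output file.
#' @param id matrix identifier.
#' @return `path`, invisibly.
#' @export
write_motif_transfac <- function(motif, path, id = "PAM") {
  stopifnot(inherits(motif, "pam_motif"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("XX", paste("ID", id), "XX", "P0\tA\tC\tG\tT"), con)
  counts <- round(motif$pfm * motif$n_pams, 4)
  for (p in seq_len(ncol(counts))) {
    writeLines(paste(c(sprintf("%02d", p), counts[, p]), collapse = "\t"),
               con)
  }
  writeLines("XX", con)
  invisible(path)
}

#' Export PAM counts as Krona ImportText rows
#'
#' One row per PAM: `count<TAB>base1<TAB>base2...`, the input format of
#' Krona's ImportText.pl, which renders the PAM wheel.
#'
#' @param counts named numeric vector (PAM -> count/mass) or a
#'   [count_pams()] table.
#' @param path output file.
#' @param order see [pam_wheel()].
#' @return `path`, invisibly.
#' @export
write_krona <- function(counts, path, order = c("inward", "outward")) {
  order <- match.arg(order)
  if (inherits(counts, "pam_count_table")) counts <- counts$counts
  stopifnot(length(counts) > 0L, !is.null(names(counts)))
  pams <- names(counts)
  if (order == "outward") {
    pams <- vapply(strsplit(pams, ""),
                   function(ch) paste(rev(ch), collapse = ""), "")
  }
  rows <- paste0(unname(counts), "\t",
                 vapply(strsplit(pams, ""), paste, "", collapse = "\t"))
  writeLines(rows, path)
  invisible(path)
}

#' Write a simulator configuration as YAML
#'
#' @param cfg a `library_sim_config`, `amplicon_sim_config` or
#'   `gel_sim_config`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$config_class <- class(cfg)[1]
  if (!is.null(x$ref)) { # amplicon reference flattens to its fields
    r <- x$ref
    x$ref <- list(sequence = r$sequence, pam = r$pam, spacer = r$spacer,
                  cut_window = r$cut_window, hdr_window = r$hdr_window,
                  donor_edits = as.list(r$donor_edits))
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Write a simulation truth table as TSV
#' @param truth data.frame of per-unit ground truth.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
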