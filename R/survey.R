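#' IUPAC PAM pattern for target-site surveys
#'
#' @param iupac degenerate PAM, 5' of the protospacer (e.g. `"ATTN"` for
#'   BhCas12b, `"TTTV"` for AsCas12a).
#' @param spacer_len protospacer length required immediately 3' of the PAM
#'   (default 23).
#' @return an object of class `pam_pattern`.
#' @export
pam_pattern <- function(iupac, spacer_len = 23L) {
  codes <- strsplit(toupper(iupac), "")[[1]]
  if (length(codes) == 0L || !all(codes %in% names(IUPAC_SETS))) {
    stop("'iupac' must be a non-empty string of IUPAC nucleotide codes",
         call. = FALSE)
  }
  assert_count(spacer_len, "spacer_len")
  structure(list(iupac = paste(codes, collapse = ""),
                 spacer_len = as.integer(spacer_len)),
            class = "pam_pattern")
}

#' Enumerate PAM-compatible target sites on both strands
#'
#' Reports every position, on either strand, where the IUPAC PAM matches
#' and a full protospacer of `spacer_len` bases fits immediately 3' of it.
#' Overlapping sites are all reported. `N` (or any non-A/C/G/T character)
#' in the subject never matches a pattern position. Reverse-strand sites
#' are reported in forward-axis coordinates with `strand = "-"`.
#'
#' @param x subject sequence(s): a character vector (optionally named by
#'   contig), a `Biostrings::DNAStringSet`, or a FASTA path.
#' @param pattern a [pam_pattern()] (or an IUPAC string, taken with the
#'   default spacer length).
#' @return an object of class `site_list`: data.frame with `contig`,
#'   `strand`, `pam_start`, `pam_end`, `protospacer_start`,
#'   `protospacer_end` (all 0-based half-open on the forward strand);
#'   attributes `surveyed_length` and `pattern`.
#' @export
#' @examples
#' scan_sites(paste0("ATTC", strrep("G", 23)), pam_pattern("ATTN"))
scan_sites <- function(x, pattern) {
  if (is.character(pattern)) pattern <- pam_pattern(pattern)
  stopifnot(inherits(pattern, "pam_pattern"))
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    x <- Biostrings::readDNAStringSet(x)
  }
  if (!inherits(x, "DNAStringSet")) {
    nm <- names(x)
    x <- Biostrings::DNAStringSet(toupper(as.character(x)))
    names(x) <- nm
  }
  if (is.null(names(x))) names(x) <- paste0("contig", seq_along(x))
  plen <- nchar(pattern$iupac)
  slen <- pattern$spacer_len
  pat <- Biostrings::DNAString(pattern$iupac)

  one_strand <- function(subject, L) {
    # matchPattern treats pattern N as matching subject N; drop any window
    # touching a non-ACGT base afterwards
    m <- Biostrings::matchPattern(pat, subject, fixed = "subject")
    st <- Biostrings::start(m) # 1-based
    if (length(st)) {
      sstr <- as.character(subject)
      win <- substring(sstr, st, st + plen - 1L)
      st <- st[!grepl("[^ACGT]", win)]
    }
    st[st - 1L + plen + slen <= L] - 1L # 0-based, spacer must fit
  }

  res <- lapply(seq_along(x), function(ci) {
    subject <- x[[ci]]
    L <- length(subject)
    fwd <- one_strand(subject, L)
    rc <- one_strand(Biostrings::reverseComplement(subject), L)
    # rc hit at 0-based s covers forward interval [L - s - plen, L - s)
    data.frame(
      contig = rep(names(x)[ci], length(fwd) + length(rc)),
      strand = rep(c("+", "-"), c(length(fwd), length(rc))),
      pam_start = c(fwd, L - rc - plen),
      pam_end = c(fwd + plen, L - rc),
      protospacer_start = c(fwd + plen, L - rc - plen - slen),
      protospacer_end = c(fwd + plen + slen, L - rc - plen),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$contig, out$pam_start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, surveyed_length = sum(Biostrings::width(x)),
            pattern = pattern,
            class = c("site_list", "data.frame"))
}

#' Targetable-site density
#'
#' @param sites a [scan_sites()] result.
#' @return data.frame with one row per strand plus a `both` row:
#'   `n_sites`, `sites_per_kb` (`n * 1000 / surveyed_length`).
#' @export
site_density <- function(sites) {
  stopifnot(inherits(sites, "site_list"))
  L <- attr(sites, "surveyed_length")
  if (is.null(L) || L <= 0) stop("surveyed length must be > 0", call. = FALSE)
  n <- c("+" = sum(sites$strand == "+"), "-" = sum(sites$strand == "-"))
  data.frame(strand = c(names(n), "both"),
             n_sites = c(unname(n), sum(n)),
             sites_per_kb = c(unname(n), sum(n)) * 1000 / L,
             stringsAsFactors = FALSE)
}

#' Write target sites as BED6
#'
#' One feature per site spanning PAM through protospacer, 0-based half-open
#' as BED requires; `name` is the PAM pattern, `score` 0, `strand` as
#' reported.
#'
#' @param sites a [scan_sites()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  stopifnot(inherits(sites, "site_list"))
  pat <- attr(sites, "pattern")$iupac
  bed <- data.frame(
    chrom = sites$contig,
    start = pmin(sites$pam_start, sites$protospacer_start),
    end = pmax(sites$pam_end, sites$protospacer_end),
    name = pat, score = 0L, strand = sites$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
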