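#' Position frequency matrix and motif summary of depleted PAMs
#'
#' Builds a position frequency matrix (PFM) from a set of PAMs, optionally
#' weighted (e.g. by depletion mass), with the per-position information
#' content `2 - H` bits (`H` the Shannon entropy of the base frequencies)
#' and an IUPAC consensus: at each position, the smallest degenerate code
#' covering all bases whose frequency reaches `consensus_cutoff`.
#'
#' @param pams non-empty character vector of PAMs over A/C/G/T, all the
#'   same length.
#' @param weights optional non-negative weights, one per PAM (default
#'   uniform).
#' @param consensus_cutoff minimum base frequency for inclusion in the
#'   consensus code (default 0.25, just above uniform background).
#' @return an object of class `pam_motif`: list with `pfm` (4 x k matrix,
#'   rows A/C/G/T, columns positions -k..-1, each column summing to 1),
#'   `info_content` (k values in `[0, 2]` bits), `consensus` (IUPAC
#'   string), `n_pams`, `weighting`.
#' @export
#' @examples
#' build_motif(c("TTTTTA", "TTTTTC"))$consensus
build_motif <- function(pams, weights = NULL, consensus_cutoff = 0.25) {
  if (length(pams) == 0L) stop("'pams' must be non-empty", call. = FALSE)
  k <- unique(nchar(pams))
  if (length(k) != 1L || anyNA(pams) || any(grepl("[^ACGT]", pams))) {
    stop("'pams' must all be over A/C/G/T and of equal length",
         call. = FALSE)
  }
  weighting <- if (is.null(weights)) "uniform" else "weighted"
  if (is.null(weights)) weights <- rep(1, length(pams))
  stopifnot(length(weights) == length(pams), all(weights >= 0),
            sum(weights) > 0)
  assert_prob(consensus_cutoff, "consensus_cutoff")

  chars <- matrix(strsplit(paste(pams, collapse = ""), "")[[1]],
                  nrow = k) # k x n, column per PAM
  pfm <- vapply(seq_len(k), function(p) {
    f <- vapply(DNA_BASES, function(b) sum(weights[chars[p, ] == b]),
                numeric(1))
    f / sum(f)
  }, numeric(4))
  dimnames(pfm) <- list(DNA_BASES, as.character(-k:-1))

  ic <- apply(pfm, 2L, function(f) {
    nz <- f[f > 0]
    2 + sum(nz * log2(nz))
  })
  consensus <- paste(apply(pfm, 2L, function(f) {
    keep <- DNA_BASES[f >= consensus_cutoff]
    if (length(keep) == 0L) keep <- DNA_BASES[which.max(f)]
    IUPAC_FROM_SET[[paste(keep, collapse = "")]]
  }), collapse = "")

  structure(list(pfm = pfm, info_content = ic, consensus = consensus,
                 n_pams = length(pams), weighting = weighting),
            class = "pam_motif")
}

#' @export
print.pam_motif <- function(x, ...) {
  cat(sprintf("pam_motif: %d PAMs (%s), consensus %s\n",
              x$n_pams, x$weighting, x$consensus))
  m <- rbind(round(x$pfm, 3), IC = round(x$info_content, 3))
  print(m)
  invisible(x)
}

#' Hierarchical PAM wheel tree
#'
#' Aggregates per-PAM counts position by position into the tree that Krona
#' renders as a PAM wheel. With `order = "inward"` the root splits on the
#' most distal position (leftmost character) and children proceed inward
#' toward the protospacer; `"outward"` reverses the traversal.
#'
#' @param counts named numeric vector (names are PAMs of equal length,
#'   values are counts or depletion mass), or a [count_pams()] table.
#' @param order `"inward"` (default) or `"outward"`.
#' @return the root node, a list with `label` (`"root"` or a base),
#'   `count`, and `children` (named list of child nodes); at every internal
#'   node the count equals the sum over children.
#' @export
#' @examples
#' w <- pam_wheel(c(TA = 5, TC = 3, GA = 2))
#' w$count
#' w$children$T$count
pam_wheel <- function(counts, order = c("inward", "outward")) {
  order <- match.arg(order)
  if (inherits(counts, "pam_count_table")) counts <- counts$counts
  if (length(counts) == 0L || is.null(names(counts))) {
    stop("'counts' must be a non-empty named vector", call. = FALSE)
  }
  pams <- names(counts)
  k <- unique(nchar(pams))
  if (length(k) != 1L) stop("PAMs must be of equal length", call. = FALSE)
  if (order == "outward") {
    pams <- vapply(strsplit(pams, ""),
                   function(ch) paste(rev(ch), collapse = ""), "")
  }
  build <- function(p, v, label) {
    node <- list(label = label, count = sum(v), children = list())
    if (nchar(p[1]) > 0L) {
      first <- substr(p, 1L, 1L)
      rest <- substring(p, 2L)
      for (b in intersect(DNA_BASES, unique(first))) {
        sel <- first == b
        node$children[[b]] <- build(rest[sel], v[sel], b)
      }
    }
    node
  }
  build(pams, unname(counts), "root")
}
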