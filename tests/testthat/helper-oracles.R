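# Independent reference implementations used as oracles. Deliberately
# naive and separate from the package's code paths.

# reverse complement without Biostrings
rc_chr <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
  }, "", USE.NAMES = FALSE)
}

random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# quadratic-time score-only affine-gap DP; global in the read, optionally
# free reference end gaps (fitting). Gap of length L costs go + L * ge.
oracle_align_score <- function(ref, read, match = 2, mismatch = -3,
                               go = -6, ge = -1, free_ref_ends = TRUE) {
  R <- nchar(ref); Q <- nchar(read)
  rc <- strsplit(ref, "")[[1]]; qc <- strsplit(read, "")[[1]]
  NEG <- -1e18
  M <- matrix(NEG, R + 1, Q + 1)
  X <- matrix(NEG, R + 1, Q + 1)
  Y <- matrix(NEG, R + 1, Q + 1)
  M[1, 1] <- 0
  if (R >= 1) {
    X[2:(R + 1), 1] <- if (free_ref_ends) 0 else go + (1:R) * ge
  }
  if (Q >= 1) Y[1, 2:(Q + 1)] <- go + (1:Q) * ge
  for (i in seq_len(R) + 1L) {
    for (j in seq_len(Q) + 1L) {
      s <- if (rc[i - 1] == qc[j - 1]) match else mismatch
      M[i, j] <- s + max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      X[i, j] <- max(M[i - 1, j] + go + ge, X[i - 1, j] + ge,
                     Y[i - 1, j] + go + ge)
      Y[i, j] <- max(M[i, j - 1] + go + ge, Y[i, j - 1] + ge,
                     X[i, j - 1] + go + ge)
    }
  }
  final <- pmax(M[, Q + 1], X[, Q + 1], Y[, Q + 1])
  if (free_ref_ends) max(final) else final[R + 1]
}

# score an explicit pair of gapped strings under the affine model; terminal
# deletion runs are free when free_ref_ends
score_alignment <- function(ar, aq, match = 2, mismatch = -3,
                            go = -6, ge = -1, free_ref_ends = TRUE) {
  a <- strsplit(ar, "")[[1]]; b <- strsplit(aq, "")[[1]]
  stopifnot(length(a) == length(b))
  lab <- ifelse(a == "-", "I", ifelse(b == "-", "D", "M"))
  runs <- rle(lab)
  s <- 0
  mcols <- lab == "M"
  s <- s + sum(ifelse(a[mcols] == b[mcols], match, mismatch))
  nruns <- length(runs$values)
  for (r in seq_len(nruns)) {
    if (runs$values[r] == "M") next
    if (free_ref_ends && runs$values[r] == "D" && (r == 1 || r == nruns)) next
    s <- s + go + runs$lengths[r] * ge
  }
  s
}

# exhaustive enumeration of optimal global alignments (tiny strings only);
# returns the set of optimal (aligned_ref, aligned_read) pairs
enum_opt_alignments <- function(ref, read, ..., free_ref_ends = TRUE) {
  out <- list()
  R <- nchar(ref); Q <- nchar(read)
  rec <- function(i, j, ar, aq) {
    if (i > R && j > Q) {
      out[[length(out) + 1L]] <<- c(ar, aq)
      return(invisible())
    }
    if (i <= R && j <= Q) {
      rec(i + 1L, j + 1L, paste0(ar, substr(ref, i, i)),
          paste0(aq, substr(read, j, j)))
    }
    if (i <= R) rec(i + 1L, j, paste0(ar, substr(ref, i, i)), paste0(aq, "-"))
    if (j <= Q) rec(i, j + 1L, paste0(ar, "-"), paste0(aq, substr(read, j, j)))
  }
  rec(1L, 1L, "", "")
  sc <- vapply(out, function(x) {
    score_alignment(x[1], x[2], ..., free_ref_ends = free_ref_ends)
  }, 0)
  out[sc == max(sc)]
}

# brute-force best anchor position: leftmost among minimal-mismatch windows
oracle_locate_anchor <- function(read, anchor, tol) {
  rl <- nchar(read); al <- nchar(anchor)
  if (al > rl) return(NA_integer_)
  rcv <- strsplit(read, "")[[1]]; acv <- strsplit(anchor, "")[[1]]
  best <- NA_integer_; best_mm <- tol + 1L
  for (off in 0:(rl - al)) {
    w <- rcv[(off + 1):(off + al)]
    mm <- sum(w != acv | w == "N")
    if (mm < best_mm) {
      best_mm <- mm
      best <- off
    }
  }
  best
}

# brute-force IUPAC site scan, both strands, 0-based forward-axis pam_start
oracle_scan_sites <- function(seq, iupac, slen) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
               S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
               V = c("A", "C", "G"), H = c("A", "C", "T"),
               D = c("A", "G", "T"), B = c("C", "G", "T"),
               N = c("A", "C", "G", "T"))
  plen <- nchar(iupac)
  codes <- strsplit(iupac, "")[[1]]
  scan1 <- function(s) {
    L <- nchar(s)
    ch <- strsplit(s, "")[[1]]
    hits <- integer(0)
    if (L >= plen + slen) {
      for (p in 0:(L - plen - slen)) {
        ok <- all(vapply(seq_len(plen), function(q) {
          ch[p + q] %in% sets[[codes[q]]]
        }, TRUE))
        if (ok) hits <- c(hits, p)
      }
    }
    hits
  }
  L <- nchar(seq)
  fwd <- scan1(seq)
  rev <- scan1(rc_chr(seq))
  data.frame(strand = rep(c("+", "-"), c(length(fwd), length(rev))),
             pam_start = c(fwd, L - rev - plen))
}

# build a pam_count_table fixture directly from a named count vector
make_count_table <- function(counts, k, total = sum(counts)) {
  structure(list(k = as.integer(k),
                 counts = setNames(as.integer(counts), names(counts)),
                 total_reads = as.integer(total),
                 valid_reads = as.integer(sum(counts)),
                 sample_id = "fixture", replicate_id = "1"),
            class = "pam_count_table")
}
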