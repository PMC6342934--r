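#' Score per-PAM depletion of a sample library against a control
#'
#' Pseudocounted relative frequencies
#' `freq = (count + pseudocount) / (valid_reads + pseudocount * 4^k)` are
#' computed for both libraries and each PAM is scored as
#' `log2(freq_control / freq_sample)`: positive scores mean the PAM was
#' depleted from the nuclease-expressing sample, i.e. the nuclease is
#' active at that PAM.
#'
#' @param sample,control [count_pams()] tables of equal `k` with nonzero
#'   `valid_reads`.
#' @param pseudocount added to every count (default 0.5; keeps scores
#'   finite at zero counts).
#' @param dense include all `4^k` PAMs rather than only those observed in
#'   either library.
#' @return an object of class `depletion_table`: data.frame with columns
#'   `pam`, `count_sample`, `count_control`, `freq_sample`, `freq_control`,
#'   `log2_depletion`, sorted by decreasing score; attributes `k` and
#'   `pseudocount`.
#' @export
compute_depletion <- function(sample, control, pseudocount = 0.5,
                              dense = FALSE) {
  stopifnot(inherits(sample, "pam_count_table"),
            inherits(control, "pam_count_table"))
  if (sample$k != control$k) {
    stop("sample and control tables have different k", call. = FALSE)
  }
  if (sample$valid_reads == 0L || control$valid_reads == 0L) {
    stop("both tables must have nonzero valid reads", call. = FALSE)
  }
  if (!is.numeric(pseudocount) || length(pseudocount) != 1L ||
      pseudocount < 0) {
    stop("'pseudocount' must be a single number >= 0", call. = FALSE)
  }
  k <- sample$k
  pams <- if (dense) {
    all_kmers(k)
  } else {
    sort(union(names(sample$counts), names(control$counts)))
  }
  cs <- unname(sample$counts[pams]); cs[is.na(cs)] <- 0L
  cc <- unname(control$counts[pams]); cc[is.na(cc)] <- 0L
  denom_s <- sample$valid_reads + pseudocount * 4^k
  denom_c <- control$valid_reads + pseudocount * 4^k
  fs <- (cs + pseudocount) / denom_s
  fc <- (cc + pseudocount) / denom_c
  out <- data.frame(pam = pams, count_sample = cs, count_control = cc,
                    freq_sample = fs, freq_control = fc,
                    log2_depletion = log2(fc / fs),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$log2_depletion, out$pam), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, k = k, pseudocount = pseudocount,
            class = c("depletion_table", "data.frame"))
}

all_kmers <- function(k) {
  g <- do.call(expand.grid,
               c(rep(list(DNA_BASES), k), stringsAsFactors = FALSE))
  # vary the last position fastest so the result is in lexicographic order
  sort(do.call(paste0, g))
}

#' Combine per-replicate depletion scores
#'
#' Joins replicate [compute_depletion()] tables on the union of PAMs
#' (absent PAMs rescored at zero counts under that replicate's
#' pseudocounted frequencies) and appends the across-replicate mean score.
#'
#' @param tables list of `depletion_table`s, one per replicate.
#' @return an object of class `depletion_set`: data.frame with `pam`, one
#'   `score_rep<i>` column per replicate, and `score_mean`.
#' @export
combine_depletion <- function(tables) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, TRUE, "depletion_table")))
  k <- unique(vapply(tables, attr, 0L, "k"))
  if (length(k) != 1L) stop("replicate tables differ in k", call. = FALSE)
  pams <- sort(Reduce(union, lapply(tables, `[[`, "pam")))
  scores <- vapply(tables, function(tb) {
    s <- setNames(tb$log2_depletion, tb$pam)[pams]
    if (anyNA(s)) {
      # PAM unobserved in this replicate: both counts zero => score 0
      s[is.na(s)] <- 0
    }
    unname(s)
  }, numeric(length(pams)))
  scores <- matrix(scores, nrow = length(pams))
  out <- data.frame(pam = pams, scores, stringsAsFactors = FALSE)
  names(out)[-1L] <- paste0("score_rep", seq_along(tables))
  out$score_mean <- rowMeans(scores)
  out <- out[order(-out$score_mean, out$pam), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, k = k, class = c("depletion_set", "data.frame"))
}

#' Call depleted PAMs
#'
#' A PAM is called depleted when its log2 depletion score meets the
#' threshold (inclusive) under the replicate rule: `"all-replicates"`
#' requires every replicate to meet it, `"mean"` requires the mean score
#' to.
#'
#' @param table a `depletion_table` (single replicate) or `depletion_set`.
#' @param threshold minimal log2 depletion score (> 0; default 2, i.e.
#'   4-fold).
#' @param rule `"all-replicates"` (default) or `"mean"`.
#' @return character vector of depleted PAMs (possibly empty).
#' @export
call_depleted <- function(table, threshold = 2,
                          rule = c("all-replicates", "mean")) {
  rule <- match.arg(rule)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("'threshold' must be a single number > 0", call. = FALSE)
  }
  if (inherits(table, "depletion_table")) {
    return(table$pam[table$log2_depletion >= threshold])
  }
  stopifnot(inherits(table, "depletion_set"))
  reps <- grep("^score_rep", names(table))
  hit <- if (rule == "all-replicates") {
    rowSums(as.matrix(table[, reps, drop = FALSE]) >= threshold) ==
      length(reps)
  } else {
    table$score_mean >= threshold
  }
  table$pam[hit]
}

#' @export
print.depletion_table <- function(x, ...) {
  cat(sprintf("depletion_table: k=%d, %d PAMs, pseudocount %g\n",
              attr(x, "k"), nrow(x), attr(x, "pseudocount")))
  print.data.frame(head(x, 5L))
  invisible(x)
}

#' @export
print.depletion_set <- function(x, ...) {
  cat(sprintf("depletion_set: k=%d, %d PAMs, %d replicates\n",
              attr(x, "k"), nrow(x), length(grep("^score_rep", names(x)))))
  print.data.frame(head(x, 5L))
  invisible(x)
}
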