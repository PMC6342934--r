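#' Configuration for the amplicon-read simulator
#'
#' Defaults emulate ssODN-mediated editing at the synthetic target of
#' [default_amplicon_reference()]: a 120-nt donor converting TG to CA, and
#' an indel outcome spectrum concentrated on 5-15 bp deletions, the pattern
#' characteristic of Cas12b end-joining repair.
#'
#' @param ref an [amplicon_reference()].
#' @param indel_rate,hdr_rate per-read probabilities of an indel outcome and
#'   of donor conversion (`indel_rate + hdr_rate <= 1`; the remainder is
#'   wild type).
#' @param indel_length_distribution named numeric vector of probabilities
#'   over net indel lengths; names are signed integers (negative =
#'   deletion). Default: uniform over deletions of 5-15 bp.
#' @param donor_length ssODN donor length in nt (see [donor_sequence()]).
#' @param read_len read length; reads are the first `read_len` bases of the
#'   (possibly edited) amplicon. Default: full amplicon.
#' @param n_reads number of reads.
#' @param seq_error_rate per-base substitution error probability.
#' @param seed master seed (see [fan_seed()]).
#' @return an object of class `amplicon_sim_config`.
#' @export
amplicon_sim_config <- function(ref = default_amplicon_reference(),
                                indel_rate = 0.3,
                                hdr_rate = 0,
                                indel_length_distribution = setNames(
                                  rep(1 / 11, 11), as.character(-(5:15))),
                                donor_length = 120L,
                                read_len = NULL,
                                n_reads = 2000L,
                                seq_error_rate = 0.001,
                                seed = 1L) {
  stopifnot(inherits(ref, "amplicon_reference"))
  assert_prob(indel_rate)
  assert_prob(hdr_rate)
  if (indel_rate + hdr_rate > 1) {
    stop("indel_rate + hdr_rate must be <= 1", call. = FALSE)
  }
  lens <- suppressWarnings(as.integer(names(indel_length_distribution)))
  if (length(indel_length_distribution) == 0L || anyNA(lens) ||
      any(lens == 0L) || any(indel_length_distribution < 0) ||
      abs(sum(indel_length_distribution) - 1) > 1e-8) {
    stop(paste("'indel_length_distribution' must be a probability vector",
               "named by nonzero signed lengths"), call. = FALSE)
  }
  if (any(lens < 0 & -lens > diff(ref$cut_window))) {
    stop("deletions longer than the cut window cannot be placed inside it",
         call. = FALSE)
  }
  assert_count(donor_length, "donor_length")
  if (is.null(read_len)) read_len <- nchar(ref$sequence)
  assert_count(read_len, "read_len")
  assert_count(n_reads, "n_reads")
  assert_prob(seq_error_rate)
  assert_count(seed, "seed", min = 0)
  donor <- donor_sequence(ref, donor_length) # validates arm consistency
  structure(list(ref = ref, indel_rate = indel_rate, hdr_rate = hdr_rate,
                 indel_length_distribution = indel_length_distribution,
                 donor = donor, read_len = as.integer(read_len),
                 n_reads = as.integer(n_reads),
                 seq_error_rate = seq_error_rate, seed = as.integer(seed)),
            class = "amplicon_sim_config")
}

#' Simulate amplicon-sequencing reads with known edit outcomes
#'
#' Each read is wild type, carries one net indel (length drawn from the
#' configured distribution and placed uniformly inside the cut window), or
#' is the donor-converted amplicon (all donor edits applied). Substitution
#' sequencing errors are then applied at `seq_error_rate`.
#'
#' @param cfg an [amplicon_sim_config()].
#' @return list with `reads` (named character vector) and `truth`
#'   (data.frame: `read_id`, `class` in WT/INDEL/HDR, `net_len`).
#' @export
#' @examples
#' sim <- simulate_amplicon_reads(amplicon_sim_config(
#'   n_reads = 50, indel_rate = 1,
#'   indel_length_distribution = c("-7" = 1), seq_error_rate = 0))
#' unique(nchar(sim$reads))
simulate_amplicon_reads <- function(cfg = amplicon_sim_config()) {
  stopifnot(inherits(cfg, "amplicon_sim_config"))
  ref <- cfg$ref
  L <- nchar(ref$sequence)
  edited <- edited_sequence(ref)
  lens <- as.integer(names(cfg$indel_length_distribution))

  set.seed(fan_seed(cfg$seed, 11L))
  u <- runif(cfg$n_reads)
  cls <- ifelse(u < cfg$hdr_rate, "HDR",
                ifelse(u < cfg$hdr_rate + cfg$indel_rate, "INDEL", "WT"))
  n_ind <- sum(cls == "INDEL")
  net <- integer(cfg$n_reads)

  set.seed(fan_seed(cfg$seed, 12L))
  seqs <- rep(ref$sequence, cfg$n_reads)
  seqs[cls == "HDR"] <- edited
  if (n_ind > 0L) {
    ilen <- lens[sample.int(length(lens), n_ind, replace = TRUE,
                            prob = cfg$indel_length_distribution)]
    net[cls == "INDEL"] <- ilen
    w1 <- ref$cut_window[1]; w2 <- ref$cut_window[2]
    idx <- which(cls == "INDEL")
    for (t in seq_len(n_ind)) {
      l <- ilen[t]
      if (l < 0L) {
        # delete |l| bases wholly inside the cut window
        start <- w1 + sample.int(w2 - w1 + l + 1L, 1L) - 1L # 0-based
        seqs[idx[t]] <- paste0(substr(ref$sequence, 1L, start),
                               substr(ref$sequence, start - l + 1L, L))
      } else {
        # insert l random bases at a point inside the cut window
        at <- w1 + sample.int(w2 - w1 + 1L, 1L) - 1L # insert before 'at'
        seqs[idx[t]] <- paste0(substr(ref$sequence, 1L, at),
                               random_dna(1L, l),
                               substr(ref$sequence, at + 1L, L))
      }
    }
  }
  seqs <- substr(seqs, 1L, cfg$read_len)
  set.seed(fan_seed(cfg$seed, 13L))
  seqs <- apply_seq_errors(seqs, cfg$seq_error_rate)
  ids <- sprintf("amp_%06d", seq_len(cfg$n_reads))
  names(seqs) <- ids
  list(reads = seqs,
       truth = data.frame(read_id = ids, class = cls, net_len = net,
                          stringsAsFactors = FALSE))
}
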