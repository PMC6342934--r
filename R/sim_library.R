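#' The FnPSP1 protospacer used as the fixed library anchor
#'
#' 31-nt protospacer placed 3' of the randomized PAM region in the plasmid
#' library; reads are anchored on it to locate the PAM window.
#' @export
FNPSP1 <- "GAGAAGTCATTTAATAAGGCCACTGTTAAAA"

#' Configuration for the randomized-PAM plasmid library simulator
#'
#' Defaults emulate the screen design: an 8-base randomized region
#' immediately 5' of the fixed FnPSP1 protospacer, read out on a 75-cycle
#' single-end run (20 + 8 + 31 + 16 = 75 nt read layout).
#'
#' @param anchor fixed protospacer sequence 3' of the randomized region.
#' @param random_len length of the randomized PAM region (bases 5' of the
#'   anchor).
#' @param upstream_pad,downstream_pad constant plasmid context flanking the
#'   randomized region and the anchor in the read.
#' @param n_plasmids number of plasmids in the transformed pool; the
#'   default gives about 15-fold coverage of the 65536-sequence 8N space, a
#'   modest but realistic transformation yield.
#' @param reads_per_sample sequencing depth per sample.
#' @param seq_error_rate per-base substitution error probability.
#' @param seed master seed; per-stage streams are derived with [fan_seed()].
#' @return an object of class `library_sim_config`.
#' @export
library_sim_config <- function(anchor = FNPSP1,
                               random_len = 8L,
                               upstream_pad = "TCCCGATTACTGAGCTAGCT",
                               downstream_pad = "GGCTAGTCAATCGATG",
                               n_plasmids = 1000000L,
                               reads_per_sample = 100000L,
                               seq_error_rate = 0.001,
                               seed = 1L) {
  assert_dna(anchor)
  assert_count(random_len, "random_len")
  if (nzchar(upstream_pad)) assert_dna(upstream_pad)
  if (nzchar(downstream_pad)) assert_dna(downstream_pad)
  assert_count(n_plasmids, "n_plasmids")
  assert_count(reads_per_sample, "reads_per_sample")
  assert_prob(seq_error_rate)
  assert_count(seed, "seed", min = 0)
  structure(list(anchor = anchor, random_len = as.integer(random_len),
                 upstream_pad = upstream_pad, downstream_pad = downstream_pad,
                 n_plasmids = as.integer(n_plasmids),
                 reads_per_sample = as.integer(reads_per_sample),
                 seq_error_rate = seq_error_rate, seed = as.integer(seed)),
            class = "library_sim_config")
}

#' Simulate one replicate of a PAM depletion screen
#'
#' Draws a plasmid pool with uniformly random PAMs, eliminates each plasmid
#' with probability `depletion_strength * activity(PAM)` (the selective
#' pressure of an active nuclease in the host), and sequences the control
#' library from the undepleted pool and the sample library from the
#' survivors, resampling with replacement (outgrowth after transformation).
#' Reads have the fixed layout `upstream_pad + PAM + anchor +
#' downstream_pad` with substitution errors at `seq_error_rate`.
#'
#' @param model a [nuclease_pam_model()]; its weight matrix must have
#'   `random_len` rows.
#' @param cfg a [library_sim_config()].
#' @return list with elements `sample` and `control` (named character
#'   vectors of reads), and `truth`, a data.frame with one row per plasmid
#'   (`plasmid_id`, `pam`, `activity`, `survived`).
#' @export
#' @examples
#' m <- pam_model_from_iupac("NNNNTTTN", depletion_strength = 1)
#' sim <- simulate_pam_library(m, library_sim_config(
#'   n_plasmids = 500, reads_per_sample = 500, seq_error_rate = 0))
#' table(sim$truth$survived)
simulate_pam_library <- function(model, cfg = library_sim_config()) {
  stopifnot(inherits(model, "nuclease_pam_model"),
            inherits(cfg, "library_sim_config"))
  if (nrow(model$weights) != cfg$random_len) {
    stop("model has ", nrow(model$weights),
         " PAM positions but cfg$random_len is ", cfg$random_len,
         call. = FALSE)
  }
  # stage 1: plasmid pool
  set.seed(fan_seed(cfg$seed, 1L))
  pams <- random_dna(cfg$n_plasmids, cfg$random_len)
  act <- pam_activity(model, pams)
  # stage 2: selection
  set.seed(fan_seed(cfg$seed, 2L))
  eliminated <- runif(cfg$n_plasmids) < model$depletion_strength * act
  survived <- !eliminated
  if (!any(survived)) {
    stop("no plasmid survived selection; nothing to sequence", call. = FALSE)
  }
  truth <- data.frame(plasmid_id = seq_len(cfg$n_plasmids), pam = pams,
                      activity = act, survived = survived,
                      stringsAsFactors = FALSE)

  make_reads <- function(pool_pams, stage_pick, stage_err, prefix) {
    set.seed(fan_seed(cfg$seed, stage_pick))
    picked <- pool_pams[sample.int(length(pool_pams), cfg$reads_per_sample,
                                   replace = TRUE)]
    reads <- paste0(cfg$upstream_pad, picked, cfg$anchor, cfg$downstream_pad)
    set.seed(fan_seed(cfg$seed, stage_err))
    reads <- apply_seq_errors(reads, cfg$seq_error_rate)
    names(reads) <- sprintf("%s_%06d", prefix, seq_along(reads))
    reads
  }
  control <- make_reads(pams, 3L, 4L, "ctrl")
  sample_reads <- make_reads(pams[survived], 5L, 6L, "samp")
  list(sample = sample_reads, control = control, truth = truth)
}

#' Simulate a replicated PAM depletion screen
#'
#' Runs [simulate_pam_library()] once per replicate with independent plasmid
#' pools (independent transformations), deriving each replicate's seed from
#' the master seed.
#'
#' @inheritParams simulate_pam_library
#' @param n_reps number of independent replicates.
#' @return list of length `n_reps`, each element as returned by
#'   [simulate_pam_library()].
#' @export
simulate_pam_screen <- function(model, cfg = library_sim_config(),
                                n_reps = 2L) {
  assert_count(n_reps, "n_reps")
  lapply(seq_len(n_reps), function(r) {
    rcfg <- cfg
    rcfg$seed <- fan_seed(cfg$seed, 1000L + r)
    simulate_pam_library(model, rcfg)
  })
}
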