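ref <- default_amplicon_reference()

test_that("reference constructor enforces its interval invariants", {
  expect_equal(nchar(ref$sequence), 200)
  expect_equal(substr(ref$sequence, ref$pam[1] + 1, ref$pam[2]), "ATTC")
  expect_equal(diff(ref$spacer), 23)
  expect_error(amplicon_reference("ACGT", c(0, 2), c(2, 4), c(0, 4),
                                  c(0, 4), ref$donor_edits),
               "length 36")
  bad_edit <- ref$donor_edits
  bad_edit$ref[1] <- "AA"
  expect_error(amplicon_reference(ref$sequence, ref$pam, ref$spacer,
                                  ref$cut_window, ref$hdr_window, bad_edit),
               "does not carry")
})

test_that("donor sequence is the edited reference window of ssODN length", {
  d <- donor_sequence(ref, 120)
  expect_equal(nchar(d$sequence), 120)
  # carries the conversion, arms match the unedited reference
  rel <- ref$donor_edits$start[1] - d$start
  expect_equal(substr(d$sequence, rel + 1, rel + 2), "CA")
  plain <- substr(ref$sequence, d$start + 1, d$start + 120)
  diffs <- which(strsplit(d$sequence, "")[[1]] != strsplit(plain, "")[[1]])
  expect_true(all((diffs - 1 + d$start) %in%
                    unlist(mapply(function(s, r) s + seq_len(nchar(r)) - 1,
                                  ref$donor_edits$start,
                                  ref$donor_edits$ref))))
})

test_that("alignment reproduces planted events and alignment invariants", {
  # perfect read
  aln <- align_read(ref$sequence, ref)
  expect_equal(aln$score, 2 * 200)
  expect_equal(nrow(aln$events), 0)
  # substring read: fitting alignment, no end-gap penalty, no events
  sub <- substr(ref$sequence, 41, 160)
  asub <- align_read(sub, ref)
  expect_equal(asub$score, 2 * 120)
  expect_equal(nrow(asub$events), 0)
  # 7-nt deletion inside the cut window
  del7 <- paste0(substr(ref$sequence, 1, 80), substr(ref$sequence, 88, 200))
  a7 <- align_read(del7, ref)
  expect_equal(a7$events$length, -7)
  expect_true(a7$events$ref_start >= ref$cut_window[1] &&
                a7$events$ref_start < ref$cut_window[2])
  # gap removal reproduces the inputs
  expect_equal(gsub("-", "", a7$aligned_read), del7)
  expect_equal(gsub("-", "", a7$aligned_ref), ref$sequence)
  # insertion
  ins <- paste0(substr(ref$sequence, 1, 85), "ACGTA",
                substr(ref$sequence, 86, 200))
  ai <- align_read(ins, ref)
  expect_equal(ai$events$length, 5)
  expect_equal(ai$events$type, "ins")
})

test_that("equal-cost gaps are placed leftmost in homopolymers", {
  # TAAAAG vs TAAAG: four co-optimal single-deletion placements
  a <- align_read("TAAAG", "TAAAAG", free_ref_ends = FALSE)
  expect_equal(a$events$ref_start, 1)
  expect_equal(a$aligned_read, "T-AAAG")
  # enumeration oracle: the emitted alignment is optimal and its deletion
  # column is the leftmost among all optimal alignments
  opts <- enum_opt_alignments("TAAAAG", "TAAAG", free_ref_ends = FALSE)
  gapcols <- vapply(opts, function(x) {
    regexpr("-", x[2], fixed = TRUE)[[1]]
  }, 0L)
  expect_true(a$aligned_read %in% vapply(opts, `[`, "", 2))
  expect_equal(regexpr("-", a$aligned_read, fixed = TRUE)[[1]],
               min(gapcols))
  # insertion homopolymer
  b <- align_read("CGGGGA", "CGGGA", free_ref_ends = FALSE)
  expect_equal(b$events$type, "ins")
  expect_equal(b$events$ref_start, 1)
})

test_that("alignment scores agree with the quadratic DP oracle", {
  set.seed(77)
  for (i in 1:80) {
    refseq <- random_seq(sample(10:60, 1))
    read <- if (runif(1) < 0.5) {
      random_seq(sample(5:60, 1)) # unrelated
    } else { # mutated copy
      x <- refseq
      for (q in sample(nchar(x), sample(0:3, 1))) {
        substr(x, q, q) <- sample(c("A", "C", "G", "T"), 1)
      }
      if (runif(1) < 0.5 && nchar(x) > 10) {
        cut <- sort(sample(nchar(x), 2))
        x <- paste0(substr(x, 1, cut[1]), substr(x, cut[2], nchar(x)))
      }
      x
    }
    for (free in c(TRUE, FALSE)) {
      got <- align_read(read, refseq, free_ref_ends = free)
      expect_equal(got$score,
                   oracle_align_score(refseq, read, free_ref_ends = free))
      # emitted alignment achieves the reported score
      expect_equal(score_alignment(got$aligned_ref, got$aligned_read,
                                   free_ref_ends = free), got$score)
    }
  }
})

test_that("aligner cross-checks against Biostrings on global pairs", {
  set.seed(5)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  for (i in 1:25) {
    a <- random_seq(sample(10:40, 1))
    b <- random_seq(sample(10:40, 1))
    ours <- align_read(b, a, free_ref_ends = FALSE)$score
    # pairwiseAlignment charges gapOpening once plus gapExtension per base
    theirs <- Biostrings::pairwiseAlignment(
      b, a, type = "global", substitutionMatrix = mat,
      gapOpening = 6, gapExtension = 1, scoreOnly = TRUE)
    expect_equal(ours, theirs)
  }
})

test_that("classification follows the documented precedence", {
  sc <- default_scoring()
  # (i) reference read
  wt <- classify_read(align_read(ref$sequence, ref), ref)
  expect_equal(wt$class, "WT")
  # (ii) donor-perfect read
  donor_read <- pamscreen:::edited_sequence(ref)
  perf <- classify_read(align_read(donor_read, ref), ref)
  expect_equal(perf$class, "HDR_PERFECT")
  # (iii) conversion plus a 2-nt deletion inside the window
  conv <- paste0(substr(donor_read, 1, 79), substr(donor_read, 82, 200))
  cc <- classify_read(align_read(conv, ref), ref)
  expect_equal(cc$class, "HDR_CONVERTED")
  expect_match(cc$notes, "indel")
  # conversion without the PAM-disrupting edit is converted, not perfect
  only_tg <- ref$sequence
  substr(only_tg, 87, 88) <- "CA"
  expect_equal(classify_read(align_read(only_tg, ref), ref)$class,
               "HDR_CONVERTED")
  # indel read
  del <- paste0(substr(ref$sequence, 1, 80), substr(ref$sequence, 88, 200))
  ic <- classify_read(align_read(del, ref), ref)
  expect_equal(ic$class, "INDEL")
  expect_equal(ic$net_indel_length, -7L)
  # substitutions outside the HDR window never change the class
  subst <- ref$sequence
  substr(subst, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                   substr(subst, 10, 10))[1]
  expect_equal(classify_read(align_read(subst, ref), ref)$class, "WT")
  # garbage reads fall below the quality floor
  amb <- classify_read(align_read(strrep("ACGG", 30), ref), ref)
  expect_equal(amb$class, "AMBIGUOUS")
})

test_that("summaries match a hand-counted call set", {
  calls <- data.frame(
    read_id = sprintf("r%d", 1:4),
    class = c("WT", "INDEL", "INDEL", "HDR_PERFECT"),
    net_indel_length = c(0L, -7L, 1L, 0L),
    score = 0, notes = "", stringsAsFactors = FALSE)
  s <- summarize_edits(calls)
  expect_equal(s$indel_rate, 50)
  expect_equal(s$hdr_perfect_rate, 25)
  expect_equal(s$hdr_converted_rate, 25)
  expect_equal(s$mean_abs_indel_length, 4)
  expect_equal(sum(s$length_histogram), 2L)
  allwt <- data.frame(read_id = "r", class = "WT", net_indel_length = 0L,
                      score = 0, notes = "")
  swt <- summarize_edits(allwt)
  expect_equal(swt$indel_rate, 0)
  expect_equal(swt$hdr_perfect_rate, 0)
  expect_true(is.na(swt$mean_abs_indel_length))
  amb <- data.frame(read_id = "r", class = "AMBIGUOUS",
                    net_indel_length = 0L, score = 0, notes = "")
  expect_error(summarize_edits(amb), "no classifiable")
})

test_that("batch calling filters short reads and is order invariant", {
  reads <- c(long = ref$sequence, short = "ACGTACGT")
  calls <- call_edits(reads, ref)
  expect_equal(nrow(calls), 1)
  expect_equal(attr(calls, "n_filtered"), 1L)
  sim <- simulate_amplicon_reads(amplicon_sim_config(
    n_reads = 60, indel_rate = 0.4, seed = 21))
  c1 <- call_edits(sim$reads, ref)
  set.seed(9)
  perm <- sample(length(sim$reads))
  c2 <- call_edits(sim$reads[perm], ref)
  expect_identical(c1$class[perm], c2$class)
})

test_that("the caller recovers simulated indel and HDR rates", {
  cfg <- amplicon_sim_config(indel_rate = 0.25, hdr_rate = 0.2,
                             n_reads = 600, seq_error_rate = 0.001,
                             seed = 31)
  sim <- simulate_amplicon_reads(cfg)
  calls <- call_edits(sim$reads, ref)
  s <- summarize_edits(calls)
  truth_ind <- mean(sim$truth$class == "INDEL")
  truth_hdr <- mean(sim$truth$class == "HDR")
  expect_lt(abs(s$indel_rate / 100 - truth_ind), 0.02)
  expect_lt(abs(s$hdr_converted_rate / 100 - truth_hdr), 0.02)
  # per-read agreement between truth and calls for indel reads
  merged <- merge(sim$truth, calls, by = "read_id")
  ind <- merged$class.x == "INDEL"
  expect_gt(mean(merged$class.y[ind] == "INDEL"), 0.99)
  expect_equal(merged$net_indel_length[ind], merged$net_len[ind])
})
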