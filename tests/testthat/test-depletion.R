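test_that("identical sample and control give zero depletion everywhere", {
  tb <- make_count_table(c(AC = 10, GT = 30, TT = 60), k = 2)
  dep <- compute_depletion(tb, tb)
  expect_true(all(dep$log2_depletion == 0))
})

test_that("depletion scores match direct evaluation of the formula", {
  # pseudocount 0: log2(0.5 / 0.0625) = 3
  ctrl <- make_count_table(c(AA = 8, CC = 2, GG = 2, TT = 4), k = 2)
  samp <- make_count_table(c(AA = 1, CC = 5, GG = 5, TT = 5), k = 2)
  dep <- compute_depletion(samp, ctrl, pseudocount = 0)
  expect_equal(dep$log2_depletion[dep$pam == "AA"], log2(0.5 / 0.0625))
  expect_equal(dep$log2_depletion[dep$pam == "AA"], 3)

  # pseudocount 0.5, k = 2, absent key: spreadsheet-style evaluation
  ctrl2 <- make_count_table(c(AA = 10, CC = 10), k = 2)
  samp2 <- make_count_table(c(AA = 20), k = 2)
  dep2 <- compute_depletion(samp2, ctrl2, pseudocount = 0.5)
  denc <- 20 + 0.5 * 16
  dens <- 20 + 0.5 * 16
  expect_equal(dep2$log2_depletion[dep2$pam == "AA"],
               log2((10.5 / denc) / (20.5 / dens)))
  expect_equal(dep2$log2_depletion[dep2$pam == "CC"],
               log2((10.5 / denc) / (0.5 / dens)))
  expect_setequal(dep2$pam, c("AA", "CC"))
})

test_that("dense mode covers the full k-mer space", {
  tb <- make_count_table(c(AA = 5), k = 2)
  dep <- compute_depletion(tb, tb, dense = TRUE)
  expect_equal(nrow(dep), 16)
  expect_true(all(dep$log2_depletion == 0))
})

test_that("depletion is antisymmetric under sample/control swap", {
  set.seed(20)
  pams <- unique(replicate(12, random_seq(3)))
  a <- make_count_table(setNames(sample(0:50, length(pams), TRUE), pams),
                        k = 3)
  b <- make_count_table(setNames(sample(1:50, length(pams), TRUE), pams),
                        k = 3)
  d1 <- compute_depletion(a, b)
  d2 <- compute_depletion(b, a)
  m1 <- setNames(d1$log2_depletion, d1$pam)
  m2 <- setNames(d2$log2_depletion, d2$pam)
  expect_equal(m1[sort(names(m1))], -m2[sort(names(m1))])
})

test_that("raising a PAM's sample count never raises its score", {
  ctrl <- make_count_table(c(AA = 40, AC = 30, GG = 30), k = 2)
  scores <- vapply(c(1, 5, 20, 80), function(n) {
    samp <- make_count_table(c(AA = n, AC = 30, GG = 30), k = 2)
    dep <- compute_depletion(samp, ctrl)
    dep$log2_depletion[dep$pam == "AA"]
  }, 0)
  expect_true(all(diff(scores) < 0))
})

test_that("mismatched or empty tables are rejected", {
  t2 <- make_count_table(c(AA = 5), k = 2)
  t3 <- make_count_table(c(AAA = 5), k = 3)
  expect_error(compute_depletion(t2, t3), "different k")
  empty <- make_count_table(setNames(integer(0), character(0)), k = 2,
                            total = 10)
  expect_error(compute_depletion(t2, empty), "nonzero valid")
})

test_that("replicate calls respect threshold boundary and rule", {
  # exact score 2 in both replicates with pseudocount 0:
  # control A:8/C:2 vs sample A:2/C:8 gives log2(.8/.2) = 2 for A
  ctrl <- make_count_table(c(A = 8, C = 2), k = 1)
  samp <- make_count_table(c(A = 2, C = 8), k = 1)
  dep <- compute_depletion(samp, ctrl, pseudocount = 0)
  expect_equal(dep$log2_depletion[dep$pam == "A"], 2)
  both <- combine_depletion(list(dep, dep))
  expect_true("A" %in% call_depleted(both, threshold = 2))
  expect_false("C" %in% call_depleted(both, threshold = 2))
  # one replicate below threshold blocks the all-replicates rule
  samp_lo <- make_count_table(c(A = 4, C = 6), k = 1)
  dep_lo <- compute_depletion(samp_lo, ctrl, pseudocount = 0)
  mixed <- combine_depletion(list(dep, dep_lo))
  expect_false("A" %in% call_depleted(mixed, threshold = 2))
  # the mean rule can still call it
  mean_score <- mean(c(2, dep_lo$log2_depletion[dep_lo$pam == "A"]))
  expect_equal("A" %in% call_depleted(mixed, threshold = 2, rule = "mean"),
               mean_score >= 2)
  expect_error(call_depleted(both, threshold = 0), "> 0")
  # a table with no qualifying PAM yields an empty set
  expect_length(call_depleted(both, threshold = 99), 0)
})

test_that("simulated TTT-preferring screens are recovered end to end", {
  m <- pam_model_from_iupac("NNNNTTTN", depletion_strength = 0.95)
  scr <- simulate_pam_screen(m, library_sim_config(seed = 11), n_reps = 2)
  deps <- lapply(scr, function(r) {
    compute_depletion(count_pams(r$sample), count_pams(r$control))
  })
  called <- call_depleted(combine_depletion(deps), threshold = 2)
  truthset <- grep("^..TTT.$",
                   apply(expand.grid(rep(list(c("A", "C", "G", "T")), 6)),
                         1, paste, collapse = ""),
                   value = TRUE)
  sens <- mean(truthset %in% called)
  false_calls <- sum(!called %in% truthset)
  expect_gte(sens, 0.95)
  expect_lte(false_calls / max(1, length(called)), 0.05)
  mot <- build_motif(called)
  top <- rownames(mot$pfm)[apply(mot$pfm, 2, which.max)]
  expect_equal(top[3:5], c("T", "T", "T")) # positions -4..-2
})

test_that("motif statistics match hand entropy computations", {
  mot <- build_motif(c("TTTTTA", "TTTTTC"))
  expect_equal(unname(mot$info_content), c(2, 2, 2, 2, 2, 1))
  expect_equal(mot$consensus, "TTTTTM")
  expect_equal(unname(mot$pfm["T", 1:5]), rep(1, 5))
  expect_equal(unname(mot$pfm[c("A", "C"), 6]), c(0.5, 0.5))
  expect_true(all(abs(colSums(mot$pfm) - 1) < 1e-9))

  single <- build_motif("ACGTAC")
  expect_equal(unname(single$info_content), rep(2, 6))
  expect_equal(single$consensus, "ACGTAC")

  all6 <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 6)), 1,
                paste, collapse = "")
  flat <- build_motif(all6)
  expect_equal(unname(flat$info_content), rep(0, 6), tolerance = 1e-12)
  expect_equal(flat$consensus, "NNNNNN")
  expect_error(build_motif(character(0)), "non-empty")
})

test_that("depletion-weighted motifs shift toward the heavy PAMs", {
  mot <- build_motif(c("TTTTTA", "TTTTTC"), weights = c(3, 1))
  expect_equal(unname(mot$pfm["A", 6]), 0.75)
  expect_equal(mot$weighting, "weighted")
})

test_that("PAM wheel trees aggregate counts level by level", {
  w <- pam_wheel(c(TA = 5, TC = 3, GA = 2))
  expect_equal(w$count, 10)
  expect_equal(w$children$T$count, 8)
  expect_equal(w$children$T$children$A$count, 5)
  expect_equal(w$children$T$children$C$count, 3)
  expect_equal(w$children$G$count, 2)
  expect_equal(w$children$G$children$A$count, 2)
  # single PAM: one path, constant count
  w1 <- pam_wheel(c(ACG = 7))
  expect_equal(w1$count, 7)
  expect_equal(w1$children$A$count, 7)
  expect_equal(w1$children$A$children$C$children$G$count, 7)
  # conservation at every internal node on random input
  set.seed(33)
  pams <- unique(replicate(30, random_seq(4)))
  counts <- setNames(sample(1:100, length(pams), TRUE), pams)
  check_node <- function(node) {
    if (length(node$children) == 0) return(invisible(TRUE))
    expect_equal(node$count, sum(vapply(node$children, `[[`, 0, "count")))
    for (ch in node$children) check_node(ch)
  }
  check_node(pam_wheel(counts))
  # outward order reverses the split hierarchy
  wo <- pam_wheel(c(TA = 5, TC = 3, GA = 2), order = "outward")
  expect_equal(wo$children$A$count, 7)
  expect_equal(wo$children$C$count, 3)
})

test_that("Krona and transfac exports carry the full table", {
  counts <- c(TA = 5, TC = 3, GA = 2)
  kr <- tempfile(fileext = ".tsv")
  write_krona(counts, kr)
  lines <- readLines(kr)
  expect_length(lines, 3)
  expect_true("5\tT\tA" %in% lines)
  tf <- tempfile(fileext = ".txt")
  write_motif_transfac(build_motif(c("TTTTTA", "TTTTTC")), tf)
  expect_true(any(grepl("^P0", readLines(tf))))
})
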