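test_that("identical gap-free sequences yield one window spanning the alignment", {
  rs <- ref_set(sprintf("s%02d", 1:10),
                rep(strrep("ACGTTGCA", 5), 10),
                rep("Archaea;Euryarchaeota", 10))
  w <- scan_conserved_windows(rs)
  expect_identical(nrow(w), 1L)
  expect_identical(w$start_column, 0L)
  expect_identical(w$end_column, 40L)
  expect_identical(w$consensus, strrep("ACGTTGCA", 5))
  expect_equal(w$max_mismatch_fraction, 0)
})

test_that("a planted conserved motif is found exactly; short motifs are not", {
  motif20 <- "TCCGGTTGATCCTGCAGGAT" # 20 solid columns
  gen <- generate_reference_set(synth_config(
    n_target = 50, n_nontarget = 0, alignment_length = 200,
    motifs = list(motif_spec(80, motif20)), gap_prob = 0, seed = 101
  ))
  w <- scan_conserved_windows(gen$refset)
  expect_identical(nrow(w), 1L)
  expect_identical(w$start_column, 80L)
  expect_identical(w$end_column, 100L)

  gen15 <- generate_reference_set(synth_config(
    n_target = 50, n_nontarget = 0, alignment_length = 200,
    motifs = list(motif_spec(80, substr(motif20, 1, 15))),
    gap_prob = 0, seed = 102
  ))
  w15 <- scan_conserved_windows(gen15$refset)
  expect_identical(nrow(w15), 0L)
})

test_that("degenerate primer construction follows the frequency floor", {
  # single column: 100% A -> A; 60/40 A/G -> R; sub-floor base excluded
  mk <- function(col_chars) {
    ref_set(sprintf("s%03d", seq_along(col_chars)), col_chars,
            rep("Archaea;Euryarchaeota", length(col_chars)))
  }
  rs <- mk(rep("A", 10))
  expect_identical(as.character(build_degenerate_primer(rs, 0, 1)), "A")
  rs <- mk(c(rep("A", 6), rep("G", 4)))
  expect_identical(
    as.character(build_degenerate_primer(rs, 0, 1,
                                         max_degenerate_fraction = 2)),
    "R"
  )
  rs <- mk(c(rep("A", 199), "G"))
  expect_identical(
    as.character(build_degenerate_primer(rs, 0, 1, frequency_floor = 0.01)),
    "A"
  )
  expect_error(build_degenerate_primer(mk(rep("-", 5)), 0, 1), "all gaps")

  # self-consistency: targets = the 12 expansions of a catalogue primer
  pat <- "TCCGGTTGATCCYGCBRG"
  ex <- iupac_expand(pat)
  rs <- ref_set(sprintf("s%03d", seq_along(ex)), ex,
                rep("Archaea;Euryarchaeota", length(ex)))
  rebuilt <- build_degenerate_primer(rs, 0, nchar(pat),
                                     frequency_floor = 0.005)
  expect_identical(as.character(rebuilt), pat)
  # a mostly degenerate window is refused
  nn <- ref_set(sprintf("s%d", 1:8),
                vapply(1:8, function(i) random_seq(10), character(1)),
                rep("Archaea;Euryarchaeota", 8))
  expect_error(
    build_degenerate_primer(nn, 0, 10, frequency_floor = 0.005),
    "degenerate positions"
  )
})

test_that("criteria evaluation measures coverage and specificity fractions", {
  pat <- "TCCGGTTGATCCYGCBRG"
  rs <- selfcons_refset(pat, "fwd")
  rep <- evaluate_criteria(rs, pat, start_column = 0,
                           end_column = nchar(pat), orientation = "forward")
  ch <- rep$checks
  val <- function(m) ch$value[ch$measure == m]
  verdict <- function(m) ch$verdict[ch$measure == m]
  expect_equal(val("terminal_coverage"), 1.0)
  expect_equal(val("mismatch_coverage"), 1.0)
  expect_identical(verdict("terminal_coverage"), "PASS")
  expect_identical(verdict("mismatch_coverage"), "PASS")
  expect_identical(verdict("rare_phylum_inclusivity"), "PASS")
  expect_equal(val("nontarget_specificity"), 1.0)
  expect_identical(verdict("nontarget_specificity"), "PASS")

  # exactly 1% of 200 targets carrying 2 mismatches fails the 99.5% bound
  ex <- iupac_expand(pat)
  targets <- rep(ex, length.out = 200)
  bad <- oracle_chars(targets[1]); bad[3] <- "A"; bad[5] <- "A"
  targets[1:2] <- paste(bad, collapse = "")
  rs2 <- ref_set(sprintf("q%03d", 1:200), targets,
                 rep("Archaea;Euryarchaeota", 200))
  rep2 <- evaluate_criteria(rs2, pat, start_column = 0,
                            end_column = nchar(pat))
  ch2 <- rep2$checks
  expect_equal(ch2$value[ch2$measure == "mismatch_coverage"], 0.99)
  expect_identical(ch2$verdict[ch2$measure == "mismatch_coverage"], "FAIL")

  # a rare phylum whose members never bind is reported as excluded
  rare_seqs <- c(ex, chartr("TCC", "AGG", ex[1]))
  rs3 <- ref_set(sprintf("r%03d", seq_along(rare_seqs)), rare_seqs,
                 c(rep("Archaea;Euryarchaeota", length(ex)),
                   "Archaea;Woesearchaeota"))
  rep3 <- evaluate_criteria(rs3, pat, start_column = 0,
                            end_column = nchar(pat))
  expect_identical(rep3$excluded_rare_phyla, "Woesearchaeota")
  expect_identical(
    rep3$checks$verdict[rep3$checks$measure == "rare_phylum_inclusivity"],
    "FAIL"
  )
})

test_that("criteria fractions equal brute-force per-sequence counting", {
  set.seed(77)
  pat <- "GGATTAGATACCCBNGTA"
  ex <- iupac_expand(pat)
  n <- 120
  windows <- vapply(seq_len(n), function(i) {
    ch <- oracle_chars(ex[sample(length(ex), 1)])
    k <- sample(0:3, 1)
    if (k > 0) {
      for (p in sample(length(ch), k)) {
        ch[p] <- sample(c("A", "C", "G", "T"), 1)
      }
    }
    paste(ch, collapse = "")
  }, character(1))
  rs <- ref_set(sprintf("s%03d", 1:n), windows,
                rep("Archaea;Euryarchaeota", n))
  rep <- evaluate_criteria(rs, pat, start_column = 0, end_column = nchar(pat))
  mm <- t(vapply(windows, function(wd) {
    unlist(oracle_mismatches(pat, wd))
  }, numeric(2)))
  expect_equal(rep$checks$value[rep$checks$measure == "terminal_coverage"],
               mean(mm[, "terminal"] == 0))
  expect_equal(rep$checks$value[rep$checks$measure == "mismatch_coverage"],
               mean(mm[, "total"] < 2))
})

test_that("gap positions in a binding site count as mismatches", {
  pat <- "ACGTACGTACGTACGTAC"
  seqs <- c(pat, sub("^AC", "--", pat))
  rs <- ref_set(c("a", "b"), seqs, rep("Archaea;Euryarchaeota", 2))
  rep <- evaluate_criteria(rs, pat, start_column = 0, end_column = nchar(pat))
  expect_equal(rep$checks$value[rep$checks$measure == "mismatch_coverage"],
               0.5)
})

test_that("the design pipeline recovers a planted specific motif", {
  gen <- generate_reference_set(synth_config(
    n_target = 80, n_nontarget = 80, alignment_length = 260,
    motifs = list(motif_spec(120, "TCCGGTTGATCCYGCBRG")),
    gap_prob = 0.01, seed = 1234
  ))
  d <- design_primers(gen$refset)
  pass <- d[d$tier == "pass", ]
  expect_gte(nrow(pass), 1L)
  fwd <- pass[pass$orientation == "fwd", ]
  expect_identical(fwd$sequence, "TCCGGTTGATCCYGCBRG")
  expect_identical(fwd$start_column, 120L)

  # no conserved stretch: iid random columns give an empty pass list
  flat <- generate_reference_set(synth_config(
    n_target = 40, n_nontarget = 40, alignment_length = 150,
    gap_prob = 0, seed = 55
  ))
  d0 <- design_primers(flat$refset)
  expect_identical(sum(d0$tier == "pass"), 0L)

  # motif shared with the non-target background lands in the near-miss tier
  shared <- generate_reference_set(synth_config(
    n_target = 60, n_nontarget = 60, alignment_length = 220,
    motifs = list(motif_spec(100, "TCCGGTTGATCCYGCBRG",
                             violation = "shared_with_nontarget")),
    gap_prob = 0.01, seed = 77
  ))
  ds <- design_primers(shared$refset)
  expect_identical(sum(ds$tier == "pass"), 0L)
  expect_gte(sum(ds$tier == "near_miss"), 1L)
})

test_that("design output is invariant to input record order", {
  gen <- generate_reference_set(synth_config(
    n_target = 40, n_nontarget = 40, alignment_length = 200,
    motifs = list(motif_spec(90, "GGATTAGATACCCGGGTA")),
    gap_prob = 0.01, seed = 9
  ))
  d1 <- design_primers(gen$refset)
  set.seed(4)
  shuffled <- tibble::as_tibble(gen$refset)[sample(nrow(gen$refset)), ]
  rs2 <- ref_set(shuffled$id, shuffled$aligned_seq, shuffled$lineage)
  d2 <- design_primers(rs2)
  cols <- c("sequence", "orientation", "tier", "start_column")
  expect_identical(
    dplyr::arrange(tibble::as_tibble(d1)[, cols], sequence, orientation),
    dplyr::arrange(tibble::as_tibble(d2)[, cols], sequence, orientation)
  )
})
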