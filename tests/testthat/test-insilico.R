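test_that("binding sites are found with the configured allowances", {
  primer <- "ACGTACGTACGTACGTAA"
  seq1 <- paste0(random_seq_at(50, 1), primer, random_seq_at(50, 2))
  hits <- find_binding_sites(seq1, primer, "fwd")
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$start, 50L)
  expect_identical(hits$total, 0L)
  # one internal substitution, zero allowance: no site
  mut <- oracle_chars(primer); mut[9] <- "T"
  seq2 <- paste0(random_seq_at(50, 3), paste(mut, collapse = ""),
                 random_seq_at(50, 4))
  expect_identical(
    nrow(find_binding_sites(seq2, primer, "fwd", max_total_mismatch = 0)),
    0L
  )
  expect_identical(
    nrow(find_binding_sites(seq2, primer, "fwd", max_total_mismatch = 1)),
    1L
  )
})

test_that("site scans equal the brute-force sliding-window oracle", {
  set.seed(41)
  for (i in 1:6) {
    primer <- random_pattern(12, c("A", "C", "G", "T", "R", "Y"))
    s <- random_seq(2000)
    # implant two exact sites
    site <- iupac_expand(primer)[1]
    substr(s, 300, 311) <- site
    substr(s, 1500, 1511) <- site
    for (orient in c("fwd", "rev")) {
      got <- find_binding_sites(s, primer, orient, max_total_mismatch = 1,
                                max_terminal_mismatch = 0)
      want <- oracle_scan(s, primer, orient, 1, 0)
      expect_identical(got$start, as.integer(want$start))
      expect_identical(got$total, as.integer(want$total))
      expect_identical(got$terminal, as.integer(want$terminal))
    }
  }
})

test_that("in-silico PCR assembles products with correct arithmetic", {
  fwd <- "TCCGGTTGATCCYGCBRG"
  rev <- "GGCCATGCAMYWCCTCTC" # stored 5'->3' on the minus strand
  fwd_site <- iupac_expand(fwd)[5]
  rev_site_plus <- iupac_expand(iupac_revcomp(rev))[2]
  insert <- random_seq_at(400, 99)
  template <- paste0(random_seq_at(30, 98), fwd_site, insert,
                     rev_site_plus, random_seq_at(30, 97))
  rs <- tibble::tibble(id = "ref1", seq = template)
  hits <- in_silico_pcr(rs, fwd, rev)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$product_length,
                   400L + nchar(fwd) + nchar(rev))
  expect_identical(hits$fwd_start, 30L)
  expect_true(hits$primary)

  # no reverse site: no product
  rs2 <- tibble::tibble(id = "ref2",
                        seq = paste0(random_seq_at(30, 96), fwd_site,
                                     insert))
  expect_identical(nrow(in_silico_pcr(rs2, fwd, rev)), 0L)
  # out-of-bounds product length
  expect_identical(nrow(in_silico_pcr(rs, fwd, rev, min_len = 500)), 0L)
  expect_identical(nrow(in_silico_pcr(rs, fwd, rev, max_len = 400)), 0L)
  # two forward primers are an orientation error
  expect_error(
    in_silico_pcr(rs, tibble::tibble(name = "a", sequence = fwd,
                                     orientation = "fwd"),
                  tibble::tibble(name = "b", sequence = fwd,
                                 orientation = "fwd")),
    "reverse orientation"
  )
})

test_that("PCR hits equal the brute-force expansion-pair oracle", {
  set.seed(61)
  fwd <- "ACGTRCGTACGT"
  rev <- "TTGCAYGCATGG"
  rev_plus <- iupac_revcomp(rev)
  for (i in 1:5) {
    s <- random_seq(600)
    if (i <= 3) { # implant a product for some cases
      substr(s, 100, 111) <- iupac_expand(fwd)[1]
      substr(s, 350, 361) <- iupac_expand(rev_plus)[1]
    }
    got <- in_silico_pcr(tibble::tibble(id = "r", seq = s), fwd, rev,
                         max_total_mismatch = 0)
    f_hits <- oracle_scan(s, fwd, "fwd", 0, 0)
    r_hits <- oracle_scan(s, rev, "rev", 0, 0)
    want <- 0L
    pairs <- list()
    for (fs in f_hits$start) {
      lens <- c()
      for (rs_ in r_hits$start) {
        if (rs_ >= fs + nchar(fwd)) {
          lens <- c(lens, rs_ + nchar(rev) - fs)
        }
      }
      if (length(lens)) pairs[[length(pairs) + 1]] <- sort(lens)
    }
    expect_identical(nrow(got), length(unlist(pairs)))
    if (length(pairs)) {
      expect_setequal(got$product_length, unlist(pairs))
      expect_identical(sum(got$primary), length(pairs))
    }
  }
})

test_that("reverse-complementing references and swapping roles preserves products", {
  fwd <- tibble::tibble(name = "f", sequence = "TCCGGTTGATCCYGCBRG",
                        orientation = "fwd")
  rev <- tibble::tibble(name = "r", sequence = "GGCCATGCAMYWCCTCTC",
                        orientation = "rev")
  set.seed(71)
  seqs <- vapply(1:5, function(i) {
    paste0(random_seq(40), iupac_expand(fwd$sequence)[1], random_seq(200),
           iupac_expand(iupac_revcomp(rev$sequence))[1], random_seq(40))
  }, character(1))
  rs <- tibble::tibble(id = sprintf("r%d", 1:5), seq = seqs)
  h1 <- in_silico_pcr(rs, fwd, rev)
  rc <- tibble::tibble(id = rs$id, seq = vapply(seqs, iupac_revcomp,
                                                character(1)))
  h2 <- in_silico_pcr(rc,
                      tibble::tibble(name = "r", sequence = rev$sequence,
                                     orientation = "fwd"),
                      tibble::tibble(name = "f", sequence = fwd$sequence,
                                     orientation = "rev"))
  expect_identical(sort(h1$product_length), sort(h2$product_length))
})

test_that("coverage tables tabulate per-taxon amplification", {
  fwd <- "TCCGGTTGATCCYGCBRG"
  rev <- "GGCCATGCAMYWCCTCTC"
  f_site <- iupac_expand(fwd)[1]
  r_site <- iupac_expand(iupac_revcomp(rev))[1]
  set.seed(81)
  mk <- function(amplifiable) {
    if (amplifiable) paste0(f_site, random_seq(150), r_site)
    else random_seq(150 + nchar(fwd) + nchar(rev))
  }
  n_per <- 30
  seqs <- c(vapply(seq_len(n_per), function(i) mk(TRUE), character(1)),
            vapply(seq_len(n_per), function(i) mk(i <= n_per / 2),
                   character(1)),
            vapply(seq_len(n_per), function(i) mk(FALSE), character(1)))
  rs <- ref_set(sprintf("s%03d", seq_along(seqs)), seqs,
                rep(c("Archaea;FullCover", "Archaea;HalfCover",
                      "Archaea;NoCover"), each = n_per))
  hits <- in_silico_pcr(rs, fwd, rev)
  cov <- coverage_table(hits, rs, "phylum")
  expect_identical(cov$taxon, c("FullCover", "HalfCover", "NoCover", "TOTAL"))
  expect_equal(cov$coverage_0mm[cov$taxon == "FullCover"], 1.0)
  expect_equal(cov$coverage_0mm[cov$taxon == "HalfCover"], 0.5)
  expect_equal(cov$coverage_0mm[cov$taxon == "NoCover"], 0.0)
  expect_equal(cov$coverage_0mm[cov$taxon == "TOTAL"], 0.5)
  expect_identical(cov$n_sequences[cov$taxon == "TOTAL"], nrow(rs))

  # no hits at all: zero coverage, sequence counts unchanged
  empty <- in_silico_pcr(rs, "AAAAAAAAAAAAAAAAAA", rev)
  cov0 <- coverage_table(empty, rs, "phylum")
  expect_true(all(cov0$coverage_1mm == 0))
  expect_identical(cov0$n_sequences[cov0$taxon == "TOTAL"], nrow(rs))
})

test_that("coverage is monotone in the mismatch allowance", {
  gen <- generate_reference_set(synth_config(
    n_target = 40, n_nontarget = 0, alignment_length = 400,
    motifs = list(motif_spec(50, "TCCGGTTGATCCYGCBRG"),
                  motif_spec(300, iupac_revcomp("GGCCATGCAMYWCCTCTC"))),
    gap_prob = 0.01, seed = 19
  ))
  fwd <- "TCCGGTTGATCCYGCBRG"
  rev <- "GGCCATGCAMYWCCTCTC"
  covs <- vapply(0:2, function(mm) {
    hits <- in_silico_pcr(gen$refset, fwd, rev, max_total_mismatch = mm)
    cov <- coverage_table(hits, gen$refset, "domain")
    cov$coverage_1mm[cov$taxon == "TOTAL"]
  }, numeric(1))
  expect_true(all(diff(covs) >= 0))
})

test_that("nominal spans derive from catalogued positions", {
  primers <- read_primer_table(catalogue_path())
  fwd <- primers[primers$name == "SSU1ArF", ]
  rev <- primers[primers$name == "SSU1000ArR", ]
  span <- nominal_amplicon_span(fwd, rev)
  expect_identical(span, 1017L)
  expect_lt(abs(span - 1000L), nchar(rev$sequence) + 1L)
  same <- nominal_amplicon_span(fwd, dplyr::mutate(rev, position = 1L))
  expect_identical(same, nchar(rev$sequence))
  expect_error(nominal_amplicon_span("ACGT", rev), "position")
})
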