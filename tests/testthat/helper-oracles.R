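# Independent oracles used by the property tests. Deliberately written
# without package internals: their own IUPAC tables, their own DP.

ORACLE_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# minimum Hamming distance over all expansions of a degenerate primer
oracle_min_hamming <- function(primer, target) {
  min(vapply(iupac_expand(primer), function(e) {
    sum(oracle_chars(e) != oracle_chars(target))
  }, numeric(1)))
}

# direct per-position set-intersection mismatch count
oracle_mismatches <- function(primer, target, zone = 2,
                              three_prime = "right") {
  p <- oracle_chars(primer)
  t <- oracle_chars(target)
  mm <- vapply(seq_along(p), function(i) {
    !t[i] %in% ORACLE_SETS[[p[i]]]
  }, logical(1))
  L <- length(p)
  zi <- if (three_prime == "right") (L - zone + 1):L else 1:zone
  list(total = sum(mm), terminal = sum(mm[zi]))
}

# brute-force binding-site scan over every offset
oracle_scan <- function(sequence, primer, orientation = "fwd",
                        max_total = 1, max_terminal = 0, zone = 2) {
  pat <- if (orientation == "fwd") primer else iupac_revcomp(primer)
  side <- if (orientation == "fwd") "right" else "left"
  L <- nchar(pat)
  n <- nchar(sequence) - L + 1
  hits <- list()
  for (s in seq_len(max(n, 0))) {
    mm <- oracle_mismatches(pat, substr(sequence, s, s + L - 1), zone, side)
    if (mm$total <= max_total && mm$terminal <= max_terminal) {
      hits[[length(hits) + 1]] <- data.frame(start = s - 1, total = mm$total,
                                             terminal = mm$terminal)
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(start = integer(), total = integer(), terminal = integer())
}

# plain affine-gap global alignment score by dynamic programming
oracle_nw_score <- function(a, b, match = 1, mismatch = -1,
                            gap_open = 5, gap_extend = 2) {
  a <- oracle_chars(a); b <- oracle_chars(b)
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -(gap_open + gap_extend * i)
  for (j in seq_len(m)) Y[1, j + 1] <- -(gap_open + gap_extend * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend,
                             Y[i, j + 1] - gap_open - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend,
                             X[i + 1, j] - gap_open - gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_pattern <- function(n, codes = names(ORACLE_SETS)) {
  paste(sample(codes, n, replace = TRUE), collapse = "")
}

random_seq_at <- function(n, seed) {
  set.seed(seed)
  random_seq(n)
}

# small hand-built reference set: expansions of a primer as targets plus
# non-targets carrying a forced off-pattern base in the 3'-terminal zone
selfcons_refset <- function(primer, orientation = "fwd", n_nontarget = 30) {
  plus <- if (orientation == "fwd") primer else iupac_revcomp(primer)
  targets <- iupac_expand(plus)
  L <- nchar(plus)
  zone_pos <- if (orientation == "fwd") L else 1
  pbits <- oracle_chars(plus)
  allowed <- ORACLE_SETS[[pbits[zone_pos]]]
  off <- setdiff(c("A", "C", "G", "T"), allowed)
  if (length(off) == 0) stop("terminal position is N; pick another primer")
  nt <- vapply(seq_len(n_nontarget), function(i) {
    e <- oracle_chars(targets[1 + (i - 1) %% length(targets)])
    e[zone_pos] <- off[1 + (i - 1) %% length(off)]
    paste(e, collapse = "")
  }, character(1))
  ref_set(
    id = c(sprintf("T%03d", seq_along(targets)),
           sprintf("N%03d", seq_len(n_nontarget))),
    aligned_seq = c(targets, nt),
    lineage = c(rep("Archaea;Euryarchaeota", length(targets)),
                rep("Bacteria;Proteobacteria", n_nontarget))
  )
}

catalogue_path <- function() {
  system.file("extdata", "catalogue_primers.tsv", package = "primarch")
}
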