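# TestPrime-style in-silico PCR: binding-site location on ungapped
# references, product simulation for primer pairs, per-taxon coverage.

encode_plain <- function(sequence) {
  chars <- strsplit(normalize_pattern(sequence), "", fixed = TRUE)[[1]]
  bits <- unname(IUPAC_BITS[chars])
  if (anyNA(bits) || any(bits == 0L)) {
    stop("reference sequence must be gap-free nucleotides", call. = FALSE)
  }
  bits
}

# mismatch profile of a pattern along a sequence: for every offset,
# total and terminal-zone mismatches (optimistic IUPAC matching)
scan_pattern <- function(seq_bits, pattern_bits, terminal_zone,
                         three_prime) {
  L <- length(pattern_bits)
  n <- length(seq_bits) - L + 1L
  if (n < 1L) {
    return(tibble::tibble(start = integer(), total = integer(),
                          terminal = integer()))
  }
  total <- integer(n)
  terminal <- integer(n)
  zone <- min(terminal_zone, L)
  zone_idx <- if (three_prime == "right") (L - zone + 1L):L else seq_len(zone)
  for (j in seq_len(L)) {
    mism <- bitwAnd(seq_bits[j:(j + n - 1L)], pattern_bits[j]) == 0L
    total <- total + mism
    if (j %in% zone_idx) terminal <- terminal + mism
  }
  tibble::tibble(start = 0:(n - 1L), total = total, terminal = terminal)
}

#' Locate primer binding sites on an ungapped sequence
#'
#' Scans every offset of the plus strand. A forward-orientation primer
#' is compared as given (3' end rightmost); a reverse-orientation primer
#' (stored 5'->3' on the minus strand) is compared as its reverse
#' complement with the 3' end leftmost, and hits are reported on the
#' minus strand.
#'
#' @param sequence Gap-free nucleotide sequence.
#' @param primer Degenerate pattern string.
#' @param orientation `"fwd"`/`"forward"` or `"rev"`/`"reverse"`.
#' @param max_total_mismatch,max_terminal_mismatch Allowances (defaults
#'   1 and 0: never a 3'-terminal mismatch).
#' @param terminal_zone 3'-terminal zone width.
#' @return Tibble sorted by `start`: `start`, `end` (0-based half-open
#'   plus-strand coordinates), `strand`, `total`, `terminal`.
#' @export
find_binding_sites <- function(sequence, primer,
                               orientation = c("fwd", "rev", "forward",
                                               "reverse"),
                               max_total_mismatch = 1L,
                               max_terminal_mismatch = 0L,
                               terminal_zone = 2L) {
  orientation <- match.arg(orientation)
  is_rev <- orientation %in% c("rev", "reverse")
  pattern <- if (is_rev) iupac_revcomp(primer) else normalize_pattern(primer)
  pbits <- encode_pattern(pattern, what = "primer")
  sbits <- encode_plain(sequence)
  prof <- scan_pattern(sbits, pbits, terminal_zone,
                       if (is_rev) "left" else "right")
  hits <- prof[prof$total <= max_total_mismatch &
                 prof$terminal <= max_terminal_mismatch, ]
  tibble::tibble(
    start = hits$start,
    end = hits$start + length(pbits),
    strand = if (is_rev) "minus" else "plus",
    total = hits$total,
    terminal = hits$terminal
  )
}

#' Simulate PCR for a primer pair over a reference set
#'
#' For every reference (ungapped), pairs each forward binding site with
#' reverse (minus-strand) sites downstream of it; the product spans the
#' forward site start to the reverse site end, inclusive of both primer
#' footprints. Per forward site the shortest in-bounds product is the
#' primary hit; longer ones are flagged `alternative`.
#'
#' @param refset A [ref_set()] (alignments are ungapped internally) or a
#'   tibble with columns `id` and `seq` of gap-free sequences.
#' @param fwd,rev One-row primer records (tibbles with `name`,
#'   `sequence`, `orientation`) or pattern strings.
#' @param max_total_mismatch,max_terminal_mismatch,terminal_zone
#'   Matching allowances per primer site.
#' @param min_len,max_len Product-length bounds in bases.
#' @return Tibble of class `amplicon_hits`: `sequence_id`, `fwd_start`,
#'   `fwd_end`, `rev_start`, `rev_end`, `product_length`, `fwd_total`,
#'   `fwd_terminal`, `rev_total`, `rev_terminal`, `primary`.
#' @export
in_silico_pcr <- function(refset, fwd, rev,
                          max_total_mismatch = 1L,
                          max_terminal_mismatch = 0L,
                          terminal_zone = 2L,
                          min_len = 0L, max_len = Inf) {
  fwd_seq <- if (is.data.frame(fwd)) fwd$sequence[1] else fwd
  rev_seq <- if (is.data.frame(rev)) rev$sequence[1] else rev
  fwd_orient <- if (is.data.frame(fwd)) fwd$orientation[1] else "fwd"
  rev_orient <- if (is.data.frame(rev)) rev$orientation[1] else "rev"
  if (!fwd_orient %in% c("fwd", "forward")) {
    stop("first primer must have forward orientation", call. = FALSE)
  }
  if (!rev_orient %in% c("rev", "reverse")) {
    stop("second primer must have reverse orientation", call. = FALSE)
  }
  ids <- refset$id
  seqs <- if ("aligned_seq" %in% names(refset)) ungap(refset$aligned_seq)
          else refset$seq
  rows <- purrr::map2_dfr(ids, seqs, function(id, s) {
    if (nchar(s) == 0L) return(NULL)
    f <- find_binding_sites(s, fwd_seq, "fwd", max_total_mismatch,
                            max_terminal_mismatch, terminal_zone)
    if (nrow(f) == 0L) return(NULL)
    r <- find_binding_sites(s, rev_seq, "rev", max_total_mismatch,
                            max_terminal_mismatch, terminal_zone)
    if (nrow(r) == 0L) return(NULL)
    out <- tidyr::crossing(
      tibble::tibble(fwd_start = f$start, fwd_end = f$end,
                     fwd_total = f$total, fwd_terminal = f$terminal),
      tibble::tibble(rev_start = r$start, rev_end = r$end,
                     rev_total = r$total, rev_terminal = r$terminal)
    )
    out <- dplyr::filter(out, .data$rev_start >= .data$fwd_end)
    out$product_length <- out$rev_end - out$fwd_start
    out <- dplyr::filter(out, .data$product_length >= min_len,
                         .data$product_length <= max_len)
    if (nrow(out) == 0L) return(NULL)
    out <- dplyr::arrange(out, .data$fwd_start, .data$product_length)
    out$primary <- !duplicated(out$fwd_start)
    out$sequence_id <- id
    out
  })
  if (nrow(rows) == 0L) {
    rows <- tibble::tibble(
      sequence_id = character(), fwd_start = integer(), fwd_end = integer(),
      fwd_total = integer(), fwd_terminal = integer(),
      rev_start = integer(), rev_end = integer(),
      rev_total = integer(), rev_terminal = integer(),
      product_length = integer(), primary = logical()
    )
  }
  rows <- dplyr::select(rows, "sequence_id", "fwd_start", "fwd_end",
                        "rev_start", "rev_end", "product_length",
                        "fwd_total", "fwd_terminal", "rev_total",
                        "rev_terminal", "primary")
  class(rows) <- c("amplicon_hits", class(rows))
  rows
}

#' Per-taxon coverage table for a primer pair
#'
#' Tabulates, at a chosen taxonomic rank, how many reference sequences
#' were amplified with zero mismatches in both primer sites and with at
#' most one total mismatch per site, plus a TOTAL row.
#'
#' @param hits Output of [in_silico_pcr()] run with
#'   `max_total_mismatch >= 1`.
#' @param refset The [ref_set()] the hits were computed on.
#' @param rank `"domain"` or `"phylum"`.
#' @return Tibble of class `coverage_table`: `taxon`, `n_sequences`,
#'   `n_amplified_0mm`, `n_amplified_1mm`, `coverage_0mm`,
#'   `coverage_1mm`; taxa sorted by name, TOTAL last.
#' @export
coverage_table <- function(hits, refset, rank = c("phylum", "domain")) {
  rank <- match.arg(rank)
  taxa <- refset[[rank]]
  if (all(is.na(taxa))) stop(sprintf("rank '%s' absent from lineages", rank),
                             call. = FALSE)
  taxa[is.na(taxa)] <- "unclassified"
  primary <- hits[hits$primary, ]
  amp1 <- unique(primary$sequence_id[primary$fwd_total <= 1L &
                                       primary$rev_total <= 1L])
  amp0 <- unique(primary$sequence_id[primary$fwd_total == 0L &
                                       primary$rev_total == 0L])
  per_taxon <- tibble::tibble(taxon = taxa, id = refset$id) |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(
      n_sequences = dplyr::n(),
      n_amplified_0mm = sum(.data$id %in% amp0),
      n_amplified_1mm = sum(.data$id %in% amp1),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$taxon)
  total <- tibble::tibble(
    taxon = "TOTAL",
    n_sequences = nrow(refset),
    n_amplified_0mm = length(amp0),
    n_amplified_1mm = length(amp1)
  )
  out <- dplyr::bind_rows(per_taxon, total)
  out$coverage_0mm <- out$n_amplified_0mm / out$n_sequences
  out$coverage_1mm <- out$n_amplified_1mm / out$n_sequences
  class(out) <- c("coverage_table", class(out))
  out
}

#' Nominal amplicon span of a primer pair from catalogued positions
#'
#' Positions are 1-based ungapped coordinates of the binding site's
#' 5'-most plus-strand base on a nominated reference; catalogued
#' positions are nominal annotations. The span is
#' `rev$position + nchar(rev$sequence) - fwd$position`.
#'
#' @param fwd,rev One-row primer records with `position` and `sequence`.
#' @return Integer span in bases.
#' @export
nominal_amplicon_span <- function(fwd, rev) {
  for (p in list(fwd, rev)) {
    if (!is.data.frame(p) || is.na(p$position[1])) {
      stop("both primers must carry a reference position", call. = FALSE)
    }
  }
  as.integer(rev$position[1] + nchar(rev$sequence[1]) - fwd$position[1])
}

#' Extract amplified products as FASTA
#'
#' @param hits Output of [in_silico_pcr()] (primary hits only are used).
#' @param refset The reference set the hits were computed on.
#' @param path Output FASTA path.
#' @return Invisibly, a named character vector of products.
#' @export
write_amplicon_fasta <- function(hits, refset, path) {
  primary <- hits[hits$primary, ]
  seqs <- ungap(refset$aligned_seq)[match(primary$sequence_id, refset$id)]
  prods <- substr(seqs, primary$fwd_start + 1L, primary$rev_end)
  names(prods) <- sprintf("%s_%d_%d", primary$sequence_id,
                          primary$fwd_start, primary$rev_end)
  x <- Biostrings::DNAStringSet(prods)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(prods)
}
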