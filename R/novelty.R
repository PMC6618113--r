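# Best-hit identity search and identity-threshold novelty classification.

#' Global pairwise alignment
#'
#' Needleman-Wunsch global alignment with affine gaps (match +1,
#' mismatch -1; a gap of length k costs `gap_open` + k * `gap_extend`).
#'
#' @param seq_a,seq_b Gap-free nucleotide sequences.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters
#'   (penalties as positive numbers).
#' @return A list with `score`, `matches` (identical aligned pairs),
#'   `columns` (total alignment columns) and `columns_trimmed` (columns
#'   excluding terminal gap runs).
#' @export
nw_align <- function(seq_a, seq_b, match = 1, mismatch = -1,
                     gap_open = 5, gap_extend = 2) {
  seq_a <- normalize_pattern(seq_a)
  seq_b <- normalize_pattern(seq_b)
  if (!nzchar(seq_a) || !nzchar(seq_b)) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  .nw_align_cpp(seq_a, seq_b, match, mismatch, gap_open, gap_extend)
}

#' Global-alignment identity between two sequences
#'
#' Identity is matching columns divided by alignment columns excluding
#' terminal gap runs (internal gap columns count against identity,
#' terminal overhangs do not), approximating the usearch_global
#' definition. Symmetric in its arguments.
#'
#' @inheritParams nw_align
#' @param denominator `"trimmed"` (default, exclude terminal gap runs) or
#'   `"all"` (every alignment column).
#' @return Identity fraction in [0, 1].
#' @examples
#' global_identity("ACGT", "ACGA") # 0.75
#' @export
global_identity <- function(seq_a, seq_b, match = 1, mismatch = -1,
                            gap_open = 5, gap_extend = 2,
                            denominator = c("trimmed", "all")) {
  denominator <- match.arg(denominator)
  aln <- nw_align(seq_a, seq_b, match, mismatch, gap_open, gap_extend)
  den <- if (denominator == "trimmed") aln$columns_trimmed else aln$columns
  if (den == 0L) return(0)
  aln$matches / den
}

# 8-mer set of a sequence (for the best-hit prefilter)
kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L))
}

#' Best reference hit for a query
#'
#' Finds the reference maximizing [global_identity()]. A k-mer prefilter
#' (shared `prefilter_kmer`-mer count) orders candidates and skips
#' references sharing no k-mer with the query unless none does; ties on
#' identity break by lexicographic reference id.
#'
#' @param query Gap-free query sequence.
#' @param references Named character vector (names are reference ids) or
#'   a tibble with columns `id` and `seq`.
#' @param prefilter_kmer K-mer size for the prefilter; 0 disables it.
#' @return A list with `ref_id` and `identity`.
#' @export
best_hit <- function(query, references, prefilter_kmer = 8L) {
  if (is.data.frame(references)) {
    refs <- stats::setNames(references$seq, references$id)
  } else {
    refs <- references
  }
  if (length(refs) == 0L) stop("reference set is empty", call. = FALSE)
  if (is.null(names(refs)) || any(!nzchar(names(refs)))) {
    stop("references must be named by id", call. = FALSE)
  }
  refs <- refs[order(names(refs))]
  query <- ungap(query)
  cand <- names(refs)
  shared <- stats::setNames(rep(1L, length(refs)), names(refs))
  if (prefilter_kmer > 0L) {
    qk <- kmer_set(query, prefilter_kmer)
    shared <- vapply(refs, function(r) {
      length(intersect(qk, kmer_set(ungap(r), prefilter_kmer)))
    }, integer(1))
    cand <- cand[order(-shared[cand], cand)]
  }
  best_id <- NA_character_
  best_idn <- -1
  for (id in cand) {
    # a candidate sharing no k-mer needs a difference in every k-window,
    # so its identity cannot exceed roughly 1 - 1/k; once the running
    # best is clearly above that bound such candidates cannot win
    if (shared[[id]] == 0L && best_idn >= 0.9) next
    idn <- global_identity(query, ungap(refs[[id]]))
    if (idn > best_idn || (idn == best_idn && id < best_id)) {
      best_idn <- idn
      best_id <- id
    }
  }
  list(ref_id = best_id, identity = best_idn)
}

#' The default novelty threshold ladder
#'
#' Identity thresholds delineating new species, genera, families, orders,
#' classes and phyla at 97%, 95%, 92%, 89%, 86% and 83% respectively:
#' a best-hit identity at or above a rank's threshold is known at that
#' rank, strictly below the lowest threshold is phylum-level novelty.
#'
#' @param thresholds Named numeric vector, strictly decreasing fractions
#'   in (0, 1], names are the ranks.
#' @return A named numeric vector of class `threshold_ladder`.
#' @export
threshold_ladder <- function(thresholds = c(species = 0.97, genus = 0.95,
                                            family = 0.92, order = 0.89,
                                            class = 0.86, phylum = 0.83)) {
  stopifnot(is.numeric(thresholds), length(thresholds) >= 1)
  if (is.null(names(thresholds)) || any(!nzchar(names(thresholds)))) {
    stop("ladder thresholds must be named by rank", call. = FALSE)
  }
  if (any(diff(thresholds) >= 0)) {
    stop("ladder thresholds must be strictly decreasing", call. = FALSE)
  }
  if (any(thresholds <= 0 | thresholds > 1)) {
    stop("ladder thresholds must be in (0, 1]", call. = FALSE)
  }
  structure(thresholds, class = "threshold_ladder")
}

#' Classify best-hit identity into a novelty rank
#'
#' Boundary values belong to the higher (less novel) bin: identity
#' exactly at the species threshold is "none" (a known species).
#'
#' @param identity Numeric vector of identities in [0, 1].
#' @param ladder A [threshold_ladder()].
#' @return Character vector of ranks: "none" or the rank of novelty
#'   ("species", ..., "phylum").
#' @examples
#' classify_novelty(c(0.98, 0.90, 0.80))
#' @export
classify_novelty <- function(identity, ladder = threshold_ladder()) {
  if (!inherits(ladder, "threshold_ladder")) ladder <- threshold_ladder(ladder)
  stopifnot(all(identity >= 0 & identity <= 1))
  ranks <- c("none", names(ladder))
  # number of thresholds the identity fails to reach
  idx <- vapply(identity, function(x) sum(x < unclass(ladder)), integer(1))
  ranks[idx + 1L]
}

#' Best-hit novelty calls and summary for a set of query OTUs
#'
#' Runs [best_hit()] for every query, classifies each identity on the
#' ladder, and tabulates counts/proportions per novelty rank plus an
#' identity histogram whose bin edges include every ladder threshold.
#' Queries shorter than `min_query_length` bases are excluded from
#' classification (reported in the `skipped` element).
#'
#' @param queries Named character vector of query sequences or a tibble
#'   with columns `id`, `seq`.
#' @param references As in [best_hit()].
#' @param ladder A [threshold_ladder()].
#' @param min_query_length Minimum query length to classify (default 450,
#'   so only long, alignable OTU representatives are called).
#' @param prefilter_kmer Passed to [best_hit()].
#' @param bin_width Histogram bin width on the identity scale.
#' @return A `novelty_summary` list: `calls` (tibble query_id,
#'   best_hit_id, identity, novelty_rank), `summary` (counts and
#'   proportions per rank), `histogram` (bin edges and counts),
#'   `skipped` (ids of too-short queries), `ladder`.
#' @export
novelty_summary <- function(queries, references,
                            ladder = threshold_ladder(),
                            min_query_length = 450L,
                            prefilter_kmer = 8L, bin_width = 0.01) {
  if (is.data.frame(queries)) {
    queries <- stats::setNames(queries$seq, queries$id)
  }
  if (length(queries) == 0L) stop("no query sequences", call. = FALSE)
  queries <- stats::setNames(ungap(queries), names(queries))
  long <- nchar(queries) >= min_query_length
  skipped <- names(queries)[!long]
  kept <- queries[long]
  calls <- purrr::map2_dfr(kept, names(kept), function(s, qid) {
    hit <- best_hit(s, references, prefilter_kmer)
    tibble::tibble(query_id = qid, best_hit_id = hit$ref_id,
                   identity = hit$identity)
  })
  if (nrow(calls) == 0L) {
    calls <- tibble::tibble(query_id = character(),
                            best_hit_id = character(),
                            identity = numeric(),
                            novelty_rank = character())
  } else {
    calls$novelty_rank <- classify_novelty(calls$identity, ladder)
  }
  rank_levels <- c("none", names(ladder))
  counts <- table(factor(calls$novelty_rank, levels = rank_levels))
  summary <- tibble::tibble(
    novelty_rank = rank_levels,
    n = as.integer(counts),
    proportion = if (nrow(calls)) as.integer(counts) / nrow(calls) else 0
  )
  edges <- sort(unique(c(seq(0, 1, by = bin_width), unclass(ladder), 1)))
  hist_counts <- if (nrow(calls)) {
    # bins are [edge_i, edge_{i+1}); last bin closed at 1
    as.integer(table(cut(calls$identity, breaks = edges,
                         right = FALSE, include.lowest = TRUE)))
  } else {
    integer(length(edges) - 1L)
  }
  out <- list(
    calls = calls,
    summary = summary,
    histogram = tibble::tibble(bin_start = edges[-length(edges)],
                               bin_end = edges[-1], n = hist_counts),
    skipped = skipped,
    ladder = ladder
  )
  class(out) <- "novelty_summary"
  out
}

#' @export
print.novelty_summary <- function(x, ...) {
  cat(sprintf("Novelty summary: %d queries classified, %d skipped (< length cutoff)\n",
              nrow(x$calls), length(x$skipped)))
  print(x$summary)
  invisible(x)
}
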