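# Conserved-window scanning, degenerate primer construction and the
# nine-point acceptance scheme:
#   stretch selection -- (i) ungapped length > 17 bp, (ii) < 25%
#   mismatches to the target-group consensus in any representative;
#   primer acceptance -- (iii) no 3'-terminal (last two bases) mismatches
#   in >= 99.5% of target sequences, (iv) < 2 total mismatches in
#   >= 99.5% of target sequences, (v) no rare target phylum (beyond the
#   exempt major phyla) wholly excluded, (vi) terminal mismatch or > 1
#   non-terminal mismatch in > 99.5% of non-target sequences,
#   (vii) GC content 40-60% (warning-level), (viii) Tm 56-62 C
#   (warning-level), (ix) < 50% degenerate positions.

#' Design configuration
#'
#' Bundles every tunable threshold of the design pipeline. Defaults
#' mirror the published acceptance scheme; `strict_physchem` escalates
#' the GC/Tm checks from WARN to FAIL.
#'
#' @param min_ungapped_length Minimum conserved-stretch length in bases
#'   (default 18, i.e. strictly more than 17 bp).
#' @param max_consensus_mismatch Per-sequence mismatch-fraction ceiling
#'   against the window consensus (default 0.25).
#' @param segmentation_floor Column base-set frequency floor used when
#'   segmenting the alignment into candidate stretches (default 0.05).
#' @param candidate_lengths Primer lengths to enumerate (default 18:20,
#'   the range of the published primer catalogue).
#' @param frequency_floor Minimum per-column base frequency for
#'   inclusion in the degenerate code (default 0.005, the complement of
#'   the 99.5% coverage goal).
#' @param coverage_threshold,specificity_threshold Fractions (default
#'   0.995 each).
#' @param rare_phyla_exemption Major phyla that the rare-phylum
#'   inclusivity check ignores.
#' @param terminal_zone 3'-terminal zone width (default 2 bases).
#' @param tm_method,gc_range,tm_range,max_degenerate_fraction
#'   Physicochemical settings.
#' @param strict_physchem If TRUE, GC/Tm violations FAIL instead of WARN.
#' @return A list of class `design_config`.
#' @export
design_config <- function(min_ungapped_length = 18L,
                          max_consensus_mismatch = 0.25,
                          segmentation_floor = 0.05,
                          candidate_lengths = 18:20,
                          frequency_floor = 0.005,
                          coverage_threshold = 0.995,
                          specificity_threshold = 0.995,
                          rare_phyla_exemption = c("Euryarchaeota",
                                                   "Crenarchaeota"),
                          terminal_zone = 2L,
                          tm_method = "basic",
                          gc_range = c(0.40, 0.60),
                          tm_range = c(56, 62),
                          max_degenerate_fraction = 0.5,
                          strict_physchem = FALSE) {
  cfg <- list(
    min_ungapped_length = as.integer(min_ungapped_length),
    max_consensus_mismatch = max_consensus_mismatch,
    segmentation_floor = segmentation_floor,
    candidate_lengths = as.integer(candidate_lengths),
    frequency_floor = frequency_floor,
    coverage_threshold = coverage_threshold,
    specificity_threshold = specificity_threshold,
    rare_phyla_exemption = rare_phyla_exemption,
    terminal_zone = as.integer(terminal_zone),
    tm_method = tm_method,
    gc_range = gc_range,
    tm_range = tm_range,
    max_degenerate_fraction = max_degenerate_fraction,
    strict_physchem = isTRUE(strict_physchem)
  )
  class(cfg) <- "design_config"
  cfg
}

# character matrix (rows = sequences) of a group's aligned sequences
group_char_matrix <- function(refset, group) {
  ids <- group_ids(refset, group)
  seqs <- refset$aligned_seq[match(ids, refset$id)]
  mat <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
                nrow = length(seqs), byrow = TRUE)
  rownames(mat) <- ids
  mat
}

#' Scan a reference alignment for conserved stretches
#'
#' Two-stage scan of the target-group alignment. Stage one segments the
#' alignment into candidate stretches: a column anchors a stretch when
#' its base set (bases at frequency at least `segmentation_floor` among
#' the column's non-gap characters) has at most three members -- i.e. at
#' least one base is effectively absent, which distinguishes genuinely
#' constrained columns (including degenerate ones) from free-running
#' background -- and gaps are not the column majority. A single
#' non-anchor column flanked by anchors (e.g. an N position) is bridged.
#' Stage two applies the per-sequence selection criterion within each
#' stretch: a window is emitted only if every target representative has
#' a mismatch fraction below `max_consensus_mismatch` against the
#' majority consensus over the window (gaps count as mismatches); when a
#' full stretch fails, its maximal passing sub-windows are emitted.
#'
#' @param refset A [ref_set()].
#' @param target_group Group whose conservation is scanned.
#' @param min_ungapped_length Minimum consensus length in bases.
#' @param max_consensus_mismatch Mismatch-fraction ceiling.
#' @param segmentation_floor Minimum base frequency for membership in a
#'   column's base set during segmentation.
#' @return A tibble of class `conserved_windows`: `start_column`,
#'   `end_column` (0-based half-open alignment coordinates), `consensus`,
#'   `mean_mismatch_fraction`, `max_mismatch_fraction`,
#'   `n_target_sequences_evaluated`; ordered by `start_column`.
#' @export
scan_conserved_windows <- function(refset, target_group = "Archaea",
                                   min_ungapped_length = 18L,
                                   max_consensus_mismatch = 0.25,
                                   segmentation_floor = 0.05) {
  mat <- group_char_matrix(refset, target_group)
  if (nrow(mat) < 2L) {
    stop("need at least 2 target sequences to scan", call. = FALSE)
  }
  n_seq <- nrow(mat); n_col <- ncol(mat)
  base_counts <- vapply(c("A", "C", "G", "T"), function(b) {
    colSums(mat == b)
  }, numeric(n_col))
  if (n_col == 1L) base_counts <- matrix(base_counts, nrow = 1L)
  gap_counts <- colSums(mat == "-")
  non_gap <- pmax(n_seq - gap_counts, 1L)
  cons_idx <- max.col(base_counts, ties.method = "first")
  consensus <- c("A", "C", "G", "T")[cons_idx]
  set_size <- rowSums(base_counts / non_gap >= segmentation_floor)
  anchor <- set_size >= 1L & set_size <= 3L & gap_counts <= n_seq / 2
  bridged <- anchor
  if (n_col >= 3L) {
    interior <- 2:(n_col - 1L)
    bridged[interior] <- anchor[interior] |
      (anchor[interior - 1L] & anchor[interior + 1L])
  }
  conserved_col <- bridged
  # mismatch matrix against column consensus (gaps mismatch)
  mm <- mat != matrix(consensus, n_seq, n_col, byrow = TRUE)

  emit <- list()
  runs <- rle(conserved_col)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (r in which(runs$values & runs$lengths >= min_ungapped_length)) {
    s <- starts[r]; e <- ends[r]
    cum <- cbind(0, t(apply(mm[, s:e, drop = FALSE], 1, cumsum)))
    width <- e - s + 1L
    emit_window <- function(w_start, w_end) {
      a <- s + w_start - 2L # 0-based start column
      b <- s + w_end - 1L   # 0-based end column (exclusive)
      frac_seq <- (cum[, w_end + 1L] - cum[, w_start]) /
        (w_end - w_start + 1L)
      tibble::tibble(
        start_column = a, end_column = b,
        consensus = paste(consensus[(a + 1L):b], collapse = ""),
        mean_mismatch_fraction = mean(frac_seq),
        max_mismatch_fraction = max(frac_seq),
        n_target_sequences_evaluated = n_seq
      )
    }
    whole <- (cum[, width + 1L] - cum[, 1L]) / width
    if (max(whole) < max_consensus_mismatch) {
      emit[[length(emit) + 1L]] <- emit_window(1L, width)
      next
    }
    # the full stretch fails the per-sequence bound: emit its maximal
    # passing sub-windows (largest feasible end per start, minus those
    # contained in an earlier window)
    last_end <- 0L
    for (w_start in seq_len(width - min_ungapped_length + 1L)) {
      cand_ends <- (w_start + min_ungapped_length - 1L):width
      seg <- cum[, cand_ends + 1L, drop = FALSE] - cum[, w_start]
      worst <- apply(sweep(seg, 2, cand_ends - w_start + 1L, "/"), 2, max)
      feasible <- which(worst < max_consensus_mismatch)
      if (!length(feasible)) next
      w_end <- cand_ends[max(feasible)]
      if (w_end > last_end) {
        emit[[length(emit) + 1L]] <- emit_window(w_start, w_end)
        last_end <- w_end
      }
    }
  }
  out <- if (length(emit)) dplyr::bind_rows(emit) else tibble::tibble(
    start_column = integer(), end_column = integer(),
    consensus = character(), mean_mismatch_fraction = numeric(),
    max_mismatch_fraction = numeric(),
    n_target_sequences_evaluated = integer()
  )
  out <- dplyr::arrange(out, .data$start_column)
  attr(out, "target_group") <- target_group
  class(out) <- c("conserved_windows", class(out))
  out
}

#' Build a degenerate primer over an alignment window
#'
#' Per column, the included base set is every base whose frequency among
#' the target-group sequences (gaps ignored) is at least
#' `frequency_floor`; the set maps to its minimal IUPAC code.
#'
#' @param refset A [ref_set()].
#' @param start_column,end_column 0-based half-open alignment columns
#'   (e.g. from [scan_conserved_windows()]).
#' @param target_group Target group.
#' @param frequency_floor Minimum base frequency for inclusion.
#' @param orientation `"forward"` returns the plus-strand pattern;
#'   `"reverse"` returns its reverse complement (the primer as
#'   synthesized, 5'->3' on the minus strand).
#' @param max_degenerate_fraction Construction fails with a diagnostic
#'   when the fraction of degenerate positions reaches this bound.
#' @return Pattern string with attributes `start_column`, `end_column`,
#'   `orientation`.
#' @export
build_degenerate_primer <- function(refset, start_column, end_column,
                                    target_group = "Archaea",
                                    frequency_floor = 0.005,
                                    orientation = c("forward", "reverse"),
                                    max_degenerate_fraction = 0.5) {
  orientation <- match.arg(orientation)
  mat <- group_char_matrix(refset, target_group)
  stopifnot(start_column >= 0, end_column <= ncol(mat),
            end_column > start_column)
  cols <- (start_column + 1L):end_column
  bits <- vapply(cols, function(j) {
    col <- mat[, j]
    col <- col[col != "-"]
    if (length(col) == 0L) {
      stop(sprintf("column %d is all gaps in group '%s'", j - 1L,
                   target_group), call. = FALSE)
    }
    freqs <- table(factor(col, levels = c("A", "C", "G", "T"))) / length(col)
    mask <- sum(c(1L, 2L, 4L, 8L)[freqs >= frequency_floor])
    if (mask == 0L) {
      stop(sprintf(
        "no base reaches frequency floor %.4f in column %d; cannot form a code",
        frequency_floor, j - 1L
      ), call. = FALSE)
    }
    mask
  }, integer(1))
  pattern <- paste(BITS_TO_CODE[bits], collapse = "")
  degen_frac <- mean(BASES_PER_CODE[match(bits, IUPAC_BITS)] > 1L)
  if (degen_frac >= max_degenerate_fraction) {
    stop(sprintf(
      "primer '%s' has %.0f%% degenerate positions (limit < %.0f%%)",
      pattern, 100 * degen_frac, 100 * max_degenerate_fraction
    ), call. = FALSE)
  }
  if (orientation == "reverse") pattern <- iupac_revcomp(pattern)
  structure(pattern, start_column = as.integer(start_column),
            end_column = as.integer(end_column), orientation = orientation)
}

#' Evaluate a primer against the acceptance scheme
#'
#' Locates the binding window on every aligned sequence via the
#' alignment columns (gap positions count as mismatches) and measures
#' the coverage, rare-phylum inclusivity, non-target specificity and
#' physicochemical checks. Reports verdicts; never throws on a failing
#' check.
#'
#' @param refset A [ref_set()].
#' @param primer Pattern string; for `orientation = "reverse"` give the
#'   primer as synthesized (minus strand), it is reverse-complemented
#'   onto the plus strand internally and the 3'-terminal zone maps to
#'   the leftmost compared positions.
#' @param target_group Target group name.
#' @param start_column,end_column Alignment window (taken from the
#'   primer's attributes when omitted).
#' @param orientation `"forward"` or `"reverse"`.
#' @param config A [design_config()].
#' @return A `criteria_report`: list with `checks` (tibble: `measure`,
#'   `value`, `threshold`, `verdict`), `excluded_rare_phyla`, `physchem`
#'   and the measured fractions.
#' @export
evaluate_criteria <- function(refset, primer, target_group = "Archaea",
                              start_column = NULL, end_column = NULL,
                              orientation = NULL,
                              config = design_config()) {
  if (is.null(start_column)) start_column <- attr(primer, "start_column")
  if (is.null(end_column)) end_column <- attr(primer, "end_column")
  if (is.null(orientation)) {
    orientation <- attr(primer, "orientation") %||% "forward"
  }
  if (is.null(start_column) || is.null(end_column)) {
    stop("binding window columns are required", call. = FALSE)
  }
  primer <- as.character(primer)
  plus_pattern <- if (orientation == "reverse") iupac_revcomp(primer)
                  else primer
  three_prime <- if (orientation == "reverse") "left" else "right"
  bits <- encode_pattern(plus_pattern, what = "primer")
  L <- length(bits)
  if (end_column - start_column != L) {
    stop("window width must equal primer length", call. = FALSE)
  }

  target_ids <- group_ids(refset, target_group)
  is_target <- refset$id %in% target_ids
  windows <- substr(refset$aligned_seq, start_column + 1L, end_column)
  mm <- mismatch_counts(bits, windows, config$terminal_zone, three_prime,
                        allow_gaps = TRUE)
  t_mm <- mm[is_target, ]
  n_mm <- mm[!is_target, ]

  cov_terminal <- mean(t_mm$terminal == 0L)
  cov_total <- mean(t_mm$total < 2L)
  covered <- t_mm$terminal == 0L & t_mm$total < 2L
  t_phyla <- refset$phylum[is_target]
  rare <- setdiff(unique(t_phyla[!is.na(t_phyla)]),
                  config$rare_phyla_exemption)
  excluded_rare <- sort(rare[vapply(rare, function(p) {
    !any(covered[!is.na(t_phyla) & t_phyla == p])
  }, logical(1))])
  specificity <- if (nrow(n_mm)) {
    mean(n_mm$terminal >= 1L | (n_mm$total - n_mm$terminal) > 1L)
  } else {
    NA_real_
  }
  pc <- oligo_physchem(plus_pattern, tm_method = config$tm_method)

  soft <- if (config$strict_physchem) "FAIL" else "WARN"
  in_range <- function(x, r) !is.na(x) && x >= r[1] && x <= r[2]
  checks <- tibble::tibble(
    measure = c("terminal_coverage", "mismatch_coverage",
                "rare_phylum_inclusivity", "nontarget_specificity",
                "gc_content", "melting_temperature", "degenerate_fraction"),
    value = c(cov_terminal, cov_total, length(excluded_rare), specificity,
              pc$gc_mean, pc$tm_mean, pc$degenerate_fraction),
    threshold = c(config$coverage_threshold, config$coverage_threshold,
                  0, config$specificity_threshold,
                  NA, NA, config$max_degenerate_fraction),
    verdict = c(
      if (cov_terminal >= config$coverage_threshold) "PASS" else "FAIL",
      if (cov_total >= config$coverage_threshold) "PASS" else "FAIL",
      if (length(excluded_rare) == 0L) "PASS" else "FAIL",
      if (!is.na(specificity) &&
            specificity > config$specificity_threshold) "PASS" else "FAIL",
      if (in_range(pc$gc_mean, config$gc_range)) "PASS" else soft,
      if (in_range(pc$tm_mean, config$tm_range)) "PASS" else soft,
      if (pc$degenerate_fraction < config$max_degenerate_fraction) "PASS"
      else "FAIL"
    )
  )
  out <- list(
    primer = primer, orientation = orientation,
    start_column = start_column, end_column = end_column,
    target_group = target_group,
    checks = checks,
    excluded_rare_phyla = excluded_rare,
    physchem = pc,
    n_target = sum(is_target), n_nontarget = sum(!is_target)
  )
  class(out) <- "criteria_report"
  out
}

#' @export
print.criteria_report <- function(x, ...) {
  cat(sprintf("Criteria report for %s primer %s (columns %d-%d)\n",
              x$orientation, x$primer, x$start_column, x$end_column))
  print(x$checks)
  if (length(x$excluded_rare_phyla)) {
    cat("Excluded rare phyla:",
        paste(x$excluded_rare_phyla, collapse = ", "), "\n")
  }
  invisible(x)
}

report_passes <- function(report, strict = FALSE) {
  ch <- report$checks
  hard <- c("terminal_coverage", "mismatch_coverage",
            "rare_phylum_inclusivity", "nontarget_specificity",
            "degenerate_fraction")
  all(ch$verdict[ch$measure %in% hard] == "PASS") &&
    (!strict || all(ch$verdict != "FAIL"))
}

report_near_miss <- function(report) {
  ch <- report$checks
  hard <- c("terminal_coverage", "mismatch_coverage",
            "rare_phylum_inclusivity", "degenerate_fraction")
  all(ch$verdict[ch$measure %in% hard] == "PASS") &&
    ch$verdict[ch$measure == "nontarget_specificity"] != "PASS"
}

check_value <- function(report, measure) {
  report$checks$value[report$checks$measure == measure]
}

#' Run the full primer-design pipeline
#'
#' Scans the target-group alignment for conserved stretches, enumerates
#' candidate sub-windows at the configured lengths, builds a degenerate
#' primer for each in both orientations, evaluates the acceptance
#' scheme, and tiers the candidates: `"pass"` (all hard checks pass),
#' `"near_miss"` (fails only non-target specificity; usable when paired
#' with a fully specific partner), `"fail"` otherwise. Overlapping
#' passing candidates of the same orientation are reduced to the best
#' one (highest mismatch coverage, then lowest degeneracy, then leftmost
#' start).
#'
#' @param refset A [ref_set()].
#' @param config A [design_config()].
#' @param target_group Target group.
#' @param reference_id Sequence whose ungapped coordinates annotate the
#'   `position` column (default: first target sequence).
#' @return A tibble of class `primer_design`, one row per retained
#'   candidate, with measured fractions, tier, and the full
#'   `criteria_report` in the `report` list-column.
#' @export
design_primers <- function(refset, config = design_config(),
                           target_group = "Archaea",
                           reference_id = NULL) {
  windows <- scan_conserved_windows(refset, target_group,
                                    config$min_ungapped_length,
                                    config$max_consensus_mismatch,
                                    config$segmentation_floor)
  if (is.null(reference_id)) reference_id <- group_ids(refset, target_group)[1]
  ref_aln <- refset$aligned_seq[refset$id == reference_id]
  ref_chars <- strsplit(ref_aln, "", fixed = TRUE)[[1]]
  col_to_pos <- cumsum(ref_chars != "-")

  rows <- list()
  for (w in seq_len(nrow(windows))) {
    ws <- windows$start_column[w]; we <- windows$end_column[w]
    for (L in config$candidate_lengths) {
      if (we - ws < L) next
      for (s in ws:(we - L)) {
        primer <- tryCatch(
          build_degenerate_primer(refset, s, s + L, target_group,
                                  config$frequency_floor, "forward",
                                  config$max_degenerate_fraction),
          error = function(e) NULL
        )
        if (is.null(primer)) next
        for (orient in c("forward", "reverse")) {
          stored <- if (orient == "reverse") iupac_revcomp(primer)
                    else as.character(primer)
          rep <- evaluate_criteria(refset, stored, target_group,
                                   start_column = s, end_column = s + L,
                                   orientation = orient, config = config)
          tier <- if (report_passes(rep, config$strict_physchem)) "pass"
                  else if (report_near_miss(rep)) "near_miss"
                  else "fail"
          rows[[length(rows) + 1L]] <- tibble::tibble(
            name = sprintf("cand_c%d_L%d_%s", s, L,
                           if (orient == "forward") "F" else "R"),
            position = max(1L, col_to_pos[s + 1L]),
            sequence = stored,
            orientation = if (orient == "forward") "fwd" else "rev",
            target_group = target_group,
            reference = "designed",
            start_column = s, end_column = s + L,
            tier = tier,
            coverage_terminal = check_value(rep, "terminal_coverage"),
            coverage_total = check_value(rep, "mismatch_coverage"),
            specificity = check_value(rep, "nontarget_specificity"),
            degeneracy = rep$physchem$degeneracy,
            degenerate_fraction = rep$physchem$degenerate_fraction,
            gc_mean = rep$physchem$gc_mean,
            tm_mean = rep$physchem$tm_mean,
            excluded_rare_phyla = list(rep$excluded_rare_phyla),
            report = list(rep)
          )
        }
      }
    }
  }
  out <- if (length(rows)) {
    dplyr::bind_rows(rows)
  } else {
    tibble::tibble(
      name = character(), position = integer(), sequence = character(),
      orientation = character(), target_group = character(),
      reference = character(), start_column = integer(),
      end_column = integer(), tier = character(),
      coverage_terminal = numeric(), coverage_total = numeric(),
      specificity = numeric(), degeneracy = numeric(),
      degenerate_fraction = numeric(), gc_mean = numeric(),
      tm_mean = numeric(), excluded_rare_phyla = list(), report = list()
    )
  }
  if (nrow(out)) {
    out <- dplyr::arrange(out, .data$start_column, .data$end_column,
                          .data$orientation)
    # reduce overlapping pass-tier candidates to the best per cluster
    keep <- rep(TRUE, nrow(out))
    for (tier_level in c("pass", "near_miss")) {
      for (orient in c("fwd", "rev")) {
        idx <- which(out$tier == tier_level & out$orientation == orient)
        if (length(idx) < 2L) next
        o <- idx[order(out$start_column[idx])]
        cluster <- cumsum(c(1L, as.integer(
          out$start_column[o][-1] >= cummax(out$end_column[o][-length(o)])
        )))
        for (cl in split(o, cluster)) {
          if (length(cl) == 1L) next
          best <- cl[order(-out$coverage_total[cl], out$degeneracy[cl],
                           out$start_column[cl])][1]
          keep[setdiff(cl, best)] <- FALSE
        }
      }
    }
    out <- out[keep, ]
  }
  attr(out, "config") <- config
  attr(out, "windows") <- windows
  class(out) <- c("primer_design", class(out))
  out
}
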