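# Deterministic synthetic reference sets with planted ground truth.
# Emulates the structure of a dereplicated, taxonomically annotated 16S
# reference alignment: a target domain (Archaea) with major and rare
# phyla, a divergent non-target domain (Bacteria), planted conserved
# motifs, tunable background entropy and gap noise.

#' Planted-motif specification
#'
#' @param start_column 0-based alignment column where the motif starts.
#' @param pattern Degenerate IUPAC pattern; each in-scope sequence
#'   carries one random expansion at the motif columns.
#' @param scope `"target"` (motif only in target sequences) or `"both"`
#'   (also planted in non-target sequences, emulating a non-specific
#'   conserved region).
#' @param violation One of `"none"`, `"terminal_mismatch"` (a 3'-terminal
#'   base of the planted copy is mutated off-pattern),
#'   `"two_mismatches"` (two non-terminal bases mutated off-pattern),
#'   `"shared_with_nontarget"` (alias for scope "both"),
#'   `"too_short"` (no effect beyond the pattern's own length; plant a
#'   short pattern to exercise the length criterion).
#' @param violation_fraction Fraction of target sequences carrying the
#'   violation (default 0).
#' @return A list of class `motif_spec`.
#' @export
motif_spec <- function(start_column, pattern,
                       scope = c("target", "both"),
                       violation = c("none", "terminal_mismatch",
                                     "two_mismatches",
                                     "shared_with_nontarget", "too_short"),
                       violation_fraction = 0) {
  scope <- match.arg(scope)
  violation <- match.arg(violation)
  if (violation == "shared_with_nontarget") scope <- "both"
  encode_pattern(pattern, what = "motif pattern")
  stopifnot(start_column >= 0, violation_fraction >= 0,
            violation_fraction <= 1)
  structure(list(start_column = as.integer(start_column),
                 pattern = normalize_pattern(pattern),
                 scope = scope, violation = violation,
                 violation_fraction = violation_fraction),
            class = "motif_spec")
}

#' Synthetic reference-set configuration
#'
#' Defaults emulate the published reference structure: 1901 target
#' (Archaea) and 8647 non-target (Bacteria) dereplicated
#' representatives over a 1500-column alignment, with rare archaeal
#' phyla of 1-5 members to exercise the inclusivity check.
#'
#' @param n_target,n_nontarget Sequence counts per domain.
#' @param alignment_length Alignment columns.
#' @param taxonomy Tibble with columns `domain`, `phylum`, `size`,
#'   `is_rare`; sizes must sum to `n_target`/`n_nontarget` per domain.
#'   Default: two major archaeal phyla plus rare ones, four bacterial
#'   phyla.
#' @param motifs List of [motif_spec()]s.
#' @param background_entropy In [0, 1]: probability a background cell is
#'   drawn uniformly at random rather than copying its column's base
#'   (1 = fully random columns, 0 = fully conserved columns).
#' @param gap_prob Per-cell gap probability outside motif columns.
#' @param seed Integer seed; same seed and config give identical output.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_target = 1901L, n_nontarget = 8647L,
                         alignment_length = 1500L,
                         taxonomy = NULL,
                         motifs = list(),
                         background_entropy = 1,
                         gap_prob = 0.02,
                         seed = 1L) {
  if (is.null(taxonomy)) {
    taxonomy <- default_taxonomy(n_target, n_nontarget)
  }
  stopifnot(n_target >= 1, n_nontarget >= 0, alignment_length >= 1,
            background_entropy >= 0, background_entropy <= 1,
            gap_prob >= 0, gap_prob < 1)
  tgt_dom <- taxonomy$domain[1]
  if (sum(taxonomy$size[taxonomy$domain == tgt_dom]) != n_target) {
    stop("taxonomy sizes for the target domain must sum to n_target",
         call. = FALSE)
  }
  if (sum(taxonomy$size[taxonomy$domain != tgt_dom]) != n_nontarget) {
    stop("taxonomy sizes for the non-target domain must sum to n_nontarget",
         call. = FALSE)
  }
  for (m in motifs) {
    if (!inherits(m, "motif_spec")) stop("motifs must be motif_spec objects",
                                         call. = FALSE)
    if (m$start_column + nchar(m$pattern) > alignment_length) {
      stop("motif extends beyond the alignment", call. = FALSE)
    }
  }
  structure(list(n_target = as.integer(n_target),
                 n_nontarget = as.integer(n_nontarget),
                 alignment_length = as.integer(alignment_length),
                 taxonomy = taxonomy, motifs = motifs,
                 background_entropy = background_entropy,
                 gap_prob = gap_prob, seed = as.integer(seed)),
            class = "synth_config")
}

#' @rdname synth_config
#' @export
default_taxonomy <- function(n_target, n_nontarget) {
  rare <- tibble::tibble(
    domain = "Archaea",
    phylum = c("Woesearchaeota", "Lokiarchaeota", "Altiarchaeota",
               "Parvarchaeota", "Bathyarchaeota"),
    size = c(3L, 2L, 1L, 2L, 5L),
    is_rare = TRUE
  )
  rare <- rare[cumsum(rare$size) <= max(n_target - 2L, 0L), ]
  n_major <- n_target - sum(rare$size)
  major <- tibble::tibble(
    domain = "Archaea",
    phylum = c("Euryarchaeota", "Crenarchaeota"),
    size = c(ceiling(n_major / 2), floor(n_major / 2)),
    is_rare = FALSE
  )
  major <- major[major$size > 0L, ]
  nb <- c(Proteobacteria = ceiling(n_nontarget * 0.4),
          Firmicutes = ceiling(n_nontarget * 0.3),
          Actinobacteria = ceiling(n_nontarget * 0.2))
  nb <- pmin(nb, n_nontarget - c(0, cumsum(nb))[seq_along(nb)])
  nb <- nb[nb > 0]
  rest <- n_nontarget - sum(nb)
  bact <- tibble::tibble(
    domain = "Bacteria",
    phylum = c(names(nb), if (rest > 0) "Bacteroidetes"),
    size = as.integer(c(nb, if (rest > 0) rest)),
    is_rare = FALSE
  )
  dplyr::bind_rows(major, rare, bact)
}

# sample one expansion of a pattern, one character vector per draw
sample_expansion <- function(bits) {
  vapply(bits, function(b) {
    opts <- c("A", "C", "G", "T")[bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1))
}

# mutate positions of a planted copy to bases outside the pattern set
off_pattern <- function(copy, bits, positions) {
  for (p in positions) {
    opts <- c("A", "C", "G", "T")[bitwAnd(bits[p], c(1L, 2L, 4L, 8L)) == 0L]
    if (length(opts) == 0L) next # N column cannot be violated
    copy[p] <- if (length(opts) == 1L) opts else sample(opts, 1L)
  }
  copy
}

# positions where an off-pattern base exists (set size < 4)
violable_positions <- function(bits, candidates) {
  candidates[BASES_PER_CODE[match(bits[candidates], IUPAC_BITS)] < 4L]
}

#' Generate a synthetic aligned reference set with planted truth
#'
#' Target sequences carry one random expansion of each in-scope motif at
#' its columns, with the configured violation applied to a rounded
#' `violation_fraction` of them (deterministically the first k sequences
#' after a seeded shuffle). Background cells copy a per-column base or
#' draw uniformly per `background_entropy`; gaps are inserted outside
#' motif columns at `gap_prob`. All randomness comes from one stream
#' seeded by `config$seed`.
#'
#' @param config A [synth_config()].
#' @return A list: `refset` (a [ref_set()]) and `truth` (list with
#'   `motifs` tibble -- columns, pattern, scope, violation, violating
#'   sequence ids -- and `expected` tibble of expected per-motif check
#'   verdicts).
#' @export
generate_reference_set <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  n_col <- config$alignment_length
  tax <- config$taxonomy
  tgt_dom <- tax$domain[1]
  domains <- rep(tax$domain, tax$size)
  phyla <- rep(tax$phylum, tax$size)
  n <- length(domains)
  ids <- sprintf("%s_%04d", ifelse(domains == tgt_dom, "ARC", "BAC"),
                 seq_len(n))
  is_target <- domains == tgt_dom

  # background: per-column anchor base, per-domain (so the non-target
  # background is divergent from the target background)
  mat <- matrix("", n, n_col)
  bases <- c("A", "C", "G", "T")
  for (dom in unique(domains)) {
    rows_d <- which(domains == dom)
    anchor <- sample(bases, n_col, replace = TRUE)
    rand_mask <- matrix(
      stats::runif(length(rows_d) * n_col) < config$background_entropy,
      length(rows_d), n_col
    )
    block <- matrix(rep(anchor, each = length(rows_d)),
                    length(rows_d), n_col)
    n_rand <- sum(rand_mask)
    if (n_rand) block[rand_mask] <- sample(bases, n_rand, replace = TRUE)
    mat[rows_d, ] <- block
  }

  motif_cols <- integer(0)
  truth_rows <- list()
  for (m in config$motifs) {
    bits <- encode_pattern(m$pattern)
    L <- length(bits)
    cols <- (m$start_column + 1L):(m$start_column + L)
    motif_cols <- union(motif_cols, cols)
    carriers <- if (m$scope == "both") seq_len(n) else which(is_target)
    tgt_carriers <- intersect(carriers, which(is_target))
    k <- round(m$violation_fraction * length(tgt_carriers))
    violators <- if (k > 0) sample(tgt_carriers, k) else integer(0)
    for (r in carriers) {
      copy <- sample_expansion(bits)
      if (r %in% violators) {
        # scatter violation positions across sequences so no single
        # off-pattern base accumulates frequency at any one column
        copy <- switch(
          m$violation,
          terminal_mismatch = {
            zone <- violable_positions(bits, max(L - 1L, 1L):L)
            if (length(zone) == 0L) {
              stop("terminal zone of motif is all-N; cannot plant violation",
                   call. = FALSE)
            }
            off_pattern(copy, bits,
                        if (length(zone) == 1L) zone else sample(zone, 1L))
          },
          two_mismatches = {
            inner <- violable_positions(bits, seq_len(max(L - 2L, 1L)))
            if (length(inner) < 2L) {
              stop("motif interior too degenerate to plant two mismatches",
                   call. = FALSE)
            }
            off_pattern(copy, bits, sample(inner, 2L))
          },
          copy
        )
      }
      mat[r, cols] <- copy
    }
    truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
      start_column = m$start_column,
      end_column = m$start_column + L,
      pattern = m$pattern, scope = m$scope,
      violation = m$violation,
      violation_fraction = m$violation_fraction,
      violators = list(ids[violators])
    )
  }

  if (config$gap_prob > 0) {
    bg_cols <- setdiff(seq_len(n_col), motif_cols)
    if (length(bg_cols)) {
      sub <- mat[, bg_cols, drop = FALSE]
      gap_mask <- matrix(stats::runif(length(sub)) < config$gap_prob,
                         nrow(sub), ncol(sub))
      sub[gap_mask] <- "-"
      mat[, bg_cols] <- sub
    }
  }

  lineage <- paste(domains, phyla, sep = ";")
  refset <- ref_set(ids, apply(mat, 1, paste, collapse = ""), lineage)
  truth <- list(
    motifs = if (length(truth_rows)) dplyr::bind_rows(truth_rows)
             else tibble::tibble(),
    taxonomy = tax,
    config = config
  )
  list(refset = refset, truth = truth)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate query OTUs at planted identities
#'
#' Produces queries by point substitutions from parent sequences so that
#' the realized [global_identity()] to the parent is within `tol` of the
#' target (substitutions only: k mutations in a length-L parent give
#' identity (L-k)/L unless the aligner prefers gaps; rejection sampling
#' with re-draws enforces the tolerance).
#'
#' @param parents Named character vector of gap-free parent sequences,
#'   or a `ref_set` (ungapped internally).
#' @param spec Tibble with columns `parent_id`, `identity` (in
#'   (0.5, 1]), `count`.
#' @param seed Integer seed.
#' @param tol Identity tolerance (default 0.01).
#' @param max_tries Rejection-sampling budget per query.
#' @return A list: `queries` (tibble `id`, `seq`, `parent_id`,
#'   `target_identity`, `realized_identity`).
#' @export
generate_query_otus <- function(parents, spec, seed = 1L, tol = 0.01,
                                max_tries = 50L) {
  if (is.data.frame(parents) && "aligned_seq" %in% names(parents)) {
    parents <- stats::setNames(ungap(parents$aligned_seq), parents$id)
  }
  stopifnot(all(c("parent_id", "identity", "count") %in% names(spec)))
  if (any(spec$identity <= 0.5 | spec$identity > 1)) {
    stop("target identities must be in (0.5, 1]", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  rows <- list()
  qn <- 0L
  for (i in seq_len(nrow(spec))) {
    pid <- spec$parent_id[i]
    if (!pid %in% names(parents)) {
      stop("unknown parent id: ", pid, call. = FALSE)
    }
    parent <- normalize_pattern(parents[[pid]])
    L <- nchar(parent)
    target <- spec$identity[i]
    for (q in seq_len(spec$count[i])) {
      qn <- qn + 1L
      if (target == 1) {
        seqq <- parent
        realized <- 1
      } else {
        k <- max(1L, round((1 - target) * L))
        realized <- NA_real_
        for (try in seq_len(max_tries)) {
          chars <- strsplit(parent, "", fixed = TRUE)[[1]]
          pos <- sample(L, k)
          for (p in pos) chars[p] <- sample(setdiff(bases, chars[p]), 1L)
          cand <- paste(chars, collapse = "")
          idn <- global_identity(cand, parent)
          if (abs(idn - target) <= tol) {
            seqq <- cand; realized <- idn; break
          }
        }
        if (is.na(realized)) {
          stop(sprintf(
            "could not realize identity %.3f for parent '%s' in %d tries",
            target, pid, max_tries
          ), call. = FALSE)
        }
      }
      rows[[qn]] <- tibble::tibble(
        id = sprintf("OTU_%04d", qn), seq = seqq, parent_id = pid,
        target_identity = target, realized_identity = realized
      )
    }
  }
  list(queries = dplyr::bind_rows(rows))
}

#' Write synthetic fixtures to a directory
#'
#' Writes aligned FASTA, taxonomy TSV and the planted-truth table.
#'
#' @param generated Output of [generate_reference_set()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synth_fixtures <- function(generated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_aligned_fasta(generated$refset,
                      file.path(dir, "reference.afa"),
                      file.path(dir, "taxonomy.tsv"))
  truth <- generated$truth$motifs
  if (nrow(truth)) {
    flat <- truth
    flat$violators <- vapply(truth$violators, paste, character(1),
                             collapse = ",")
    utils::write.table(flat, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
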