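# Reference-set I/O: gapped FASTA + SILVA-style taxonomy TSV, primer
# tables, coordinate maps, and greedy dereplication.

#' Construct an aligned reference set
#'
#' A reference set is a tibble with one row per sequence and columns
#' `id`, `aligned_seq` (over A/C/G/T/-), `lineage` (semicolon-delimited,
#' domain first), `domain` and `phylum` (extracted from the lineage).
#' The alignment length is carried as an attribute.
#'
#' @param id Character vector of unique sequence ids.
#' @param aligned_seq Equal-length aligned sequences (gaps '-' or '.').
#' @param lineage Semicolon-delimited lineage strings (domain;phylum;...).
#' @return A `ref_set` tibble.
#' @export
ref_set <- function(id, aligned_seq, lineage) {
  stopifnot(length(id) == length(aligned_seq),
            length(id) == length(lineage))
  if (anyDuplicated(id)) {
    stop("duplicate sequence id: ", id[duplicated(id)][1], call. = FALSE)
  }
  id <- unname(as.character(id))
  aligned_seq <- unname(normalize_pattern(aligned_seq))
  lineage <- unname(as.character(lineage))
  lens <- nchar(aligned_seq)
  if (length(lens) && length(unique(lens)) > 1L) {
    ref_len <- lens[1]
    bad_i <- which(lens != ref_len)[1]
    stop(sprintf("ragged alignment: sequence '%s' has length %d, expected %d",
                 id[bad_i], lens[bad_i], ref_len), call. = FALSE)
  }
  ranks <- strsplit(lineage, ";", fixed = TRUE)
  out <- tibble::tibble(
    id = as.character(id),
    aligned_seq = aligned_seq,
    lineage = as.character(lineage),
    domain = vapply(ranks, function(r) trimws(r[1]), character(1)),
    phylum = vapply(ranks, function(r) {
      if (length(r) >= 2) trimws(r[2]) else NA_character_
    }, character(1))
  )
  attr(out, "alignment_length") <- if (length(lens)) lens[1] else 0L
  class(out) <- c("ref_set", class(out))
  out
}

#' @export
alignment_length <- function(refset) {
  len <- attr(refset, "alignment_length")
  if (is.null(len)) len <- unique(nchar(refset$aligned_seq))[1]
  len
}

# dplyr verbs drop attributes; re-derive after subsetting
as_ref_set <- function(df) {
  ref_set(df$id, df$aligned_seq, df$lineage)
}

#' Member ids of a taxonomic group
#'
#' A group name matches at the domain or phylum level of the lineage.
#'
#' @param refset A `ref_set`.
#' @param group Group name (e.g. "Archaea" or a phylum).
#' @return Character vector of sequence ids.
#' @export
group_ids <- function(refset, group) {
  hit <- refset$domain == group | (!is.na(refset$phylum) &
                                     refset$phylum == group)
  if (!any(hit)) stop(sprintf("group '%s' not present in reference set",
                              group), call. = FALSE)
  refset$id[hit]
}

#' Read an aligned FASTA plus taxonomy into a reference set
#'
#' Sequences are uppercased, U converted to T and '.' gaps to '-'.
#' Taxonomy is a two-column TSV (no header): id TAB semicolon-delimited
#' lineage. Ids present in the FASTA but absent from the taxonomy are
#' dropped with a warning listing them (attribute `unmatched_ids`).
#'
#' @param fasta_path Path to the aligned FASTA file.
#' @param taxonomy_path Path to the taxonomy TSV.
#' @return A `ref_set` tibble.
#' @export
read_aligned_fasta <- function(fasta_path, taxonomy_path) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path, call. = FALSE)
  }
  seqs <- Biostrings::readBStringSet(fasta_path)
  if (length(seqs) == 0L) {
    stop("empty FASTA file: ", fasta_path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  aligned <- normalize_pattern(as.character(seqs))
  lens <- nchar(aligned)
  if (length(unique(lens)) > 1L) {
    ref_len <- lens[1]
    stop(sprintf(
      "ragged alignment in %s: sequence '%s' has length %d, expected %d",
      fasta_path, ids[lens != ref_len][1], lens[lens != ref_len][1], ref_len
    ), call. = FALSE)
  }
  tax <- read_taxonomy(taxonomy_path)
  lineage <- tax$lineage[match(ids, tax$id)]
  unmatched <- ids[is.na(lineage)]
  if (length(unmatched)) {
    warning(sprintf("%d sequence id(s) missing from taxonomy, dropped: %s",
                    length(unmatched),
                    paste(utils::head(unmatched, 5), collapse = ", ")),
            call. = FALSE)
  }
  keep <- !is.na(lineage)
  out <- ref_set(ids[keep], aligned[keep], lineage[keep])
  if (length(unmatched)) attr(out, "unmatched_ids") <- unname(unmatched)
  out
}

#' Read a SILVA-style taxonomy TSV
#'
#' @param path Two-column TSV, no header: id TAB lineage.
#' @return Tibble with columns `id`, `lineage`.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          quote = "", comment.char = "")
  if (ncol(df) < 2L) stop("taxonomy file must have two tab-separated columns",
                          call. = FALSE)
  tibble::tibble(id = df[[1]], lineage = df[[2]])
}

#' Write a reference set as aligned FASTA + taxonomy TSV
#'
#' @param refset A `ref_set`.
#' @param fasta_path,taxonomy_path Output paths.
#' @return `refset`, invisibly.
#' @export
write_aligned_fasta <- function(refset, fasta_path, taxonomy_path) {
  seqs <- Biostrings::BStringSet(refset$aligned_seq)
  names(seqs) <- refset$id
  Biostrings::writeXStringSet(seqs, fasta_path, width = 80L)
  utils::write.table(refset[, c("id", "lineage")], taxonomy_path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(refset)
}

#' Strip gaps from aligned sequences
#' @param x Character vector of aligned sequences.
#' @return Character vector of ungapped sequences.
#' @export
ungap <- function(x) gsub("-", "", normalize_pattern(x), fixed = TRUE)

#' Map between ungapped positions and alignment columns
#'
#' @param aligned_seq One aligned sequence.
#' @return Tibble with `ungapped` (1-based position in the gap-free
#'   sequence) and `column` (0-based alignment column); one row per
#'   non-gap character. An all-gap sequence yields zero rows.
#' @export
position_map <- function(aligned_seq) {
  chars <- strsplit(normalize_pattern(aligned_seq), "", fixed = TRUE)[[1]]
  non_gap <- which(chars != "-")
  tibble::tibble(ungapped = seq_along(non_gap), column = non_gap - 1L)
}

#' Alignment column of an ungapped position (0-based)
#' @export
#' @rdname position_map
#' @param pos Ungapped 1-based position(s).
ungapped_to_column <- function(aligned_seq, pos) {
  pm <- position_map(aligned_seq)
  pm$column[match(pos, pm$ungapped)]
}

#' Greedy centroid dereplication of a group
#'
#' References in the group are processed in decreasing ungapped-length
#' order (ties by id); each sequence joins the first existing
#' representative to which its global-alignment identity (matching
#' columns over the ungapped length of the shorter sequence, the
#' vsearch-style definition) reaches the threshold, else becomes a new
#' representative.
#'
#' @param refset A `ref_set`.
#' @param group Group name.
#' @param identity_threshold Fraction in (0, 1].
#' @return Character vector of representative ids, in processing order.
#' @export
dereplicate <- function(refset, group, identity_threshold) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  ids <- group_ids(refset, group)
  seqs <- ungap(refset$aligned_seq[match(ids, refset$id)])
  ord <- order(-nchar(seqs), ids)
  ids <- ids[ord]; seqs <- seqs[ord]
  reps <- character(0)
  rep_seqs <- character(0)
  for (k in seq_along(ids)) {
    assigned <- FALSE
    for (r in seq_along(reps)) {
      aln <- nw_align(seqs[k], rep_seqs[r])
      idn <- aln$matches / min(nchar(seqs[k]), nchar(rep_seqs[r]))
      if (idn >= identity_threshold) { assigned <- TRUE; break }
    }
    if (!assigned) {
      reps <- c(reps, ids[k])
      rep_seqs <- c(rep_seqs, seqs[k])
    }
  }
  reps
}

PRIMER_TABLE_COLS <- c("name", "position", "sequence", "orientation",
                       "target_group", "reference")

#' Read a primer table
#'
#' TSV with header exactly `name, position, sequence, orientation,
#' target_group, reference`. Reverse primers are stored as synthesized
#' (5'->3' on the minus strand). Sequences are normalized (uppercase,
#' U->T, inosine->N).
#'
#' @param path Path to the TSV.
#' @return A tibble of primer records.
#' @export
read_primer_table <- function(path) {
  if (!file.exists(path)) stop("primer table not found: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, colClasses = "character", quote = "")
  if (!identical(names(df), PRIMER_TABLE_COLS)) {
    stop("primer table header must be exactly: ",
         paste(PRIMER_TABLE_COLS, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    return(tibble::tibble(name = character(), position = integer(),
                          sequence = character(), orientation = character(),
                          target_group = character(), reference = character()))
  }
  pos <- suppressWarnings(as.integer(df$position))
  bad <- which(is.na(pos) | pos < 1L | !df$orientation %in% c("fwd", "rev"))
  if (length(bad)) {
    stop(sprintf("malformed primer table row at line %d of %s",
                 bad[1] + 1L, path), call. = FALSE)
  }
  seqs <- normalize_pattern(df$sequence)
  for (k in seq_along(seqs)) encode_pattern(seqs[k], what = df$name[k])
  tibble::tibble(name = df$name, position = pos, sequence = seqs,
                 orientation = df$orientation,
                 target_group = df$target_group, reference = df$reference)
}

#' @rdname read_primer_table
#' @param primers Tibble of primer records.
#' @export
write_primer_table <- function(primers, path) {
  stopifnot(all(PRIMER_TABLE_COLS %in% names(primers)))
  utils::write.table(primers[, PRIMER_TABLE_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(primers)
}
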