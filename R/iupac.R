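# IUPAC nucleotide algebra: bitmask encoding A=1, C=2, G=4, T=8.
# Gap characters ('-', '.') encode to 0 so they can never match anything.

IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L,
  `-` = 0L, `.` = 0L
)

# bitmask -> minimal IUPAC code (index = bitmask value)
BITS_TO_CODE <- character(15L)
for (.code in c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                "B", "D", "H", "V", "N")) {
  BITS_TO_CODE[IUPAC_BITS[[.code]]] <- .code
}
rm(.code)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N",
  `-` = "-", `.` = "."
)

BASES_PER_CODE <- vapply(IUPAC_BITS, function(b) {
  sum(bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L)
}, integer(1))

#' Normalize a nucleotide pattern string
#'
#' Uppercases, converts U to T (RNA input), '.' gaps to '-', and inosine
#' (I) to N, since inosine pairs with all four standard bases.
#'
#' @param x Character vector of sequence/pattern strings.
#' @return Character vector of the same length.
#' @export
normalize_pattern <- function(x) {
  chartr(".UI", "-TN", toupper(x))
}

# Validate and encode one pattern to an integer bitmask vector.
# allow_gaps: permit '-' (encoded 0); what: label for error messages.
encode_pattern <- function(pattern, allow_gaps = FALSE, what = "pattern") {
  stopifnot(is.character(pattern), length(pattern) == 1L, !is.na(pattern))
  pattern <- normalize_pattern(pattern)
  if (nchar(pattern) < 1L) {
    stop(sprintf("%s must have length >= 1", what), call. = FALSE)
  }
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  bits <- unname(IUPAC_BITS[chars])
  bad <- which(is.na(bits) | (!allow_gaps & bits == 0L))
  if (length(bad)) {
    stop(sprintf(
      "invalid IUPAC character '%s' at position %d of %s",
      chars[bad[1]], bad[1], what
    ), call. = FALSE)
  }
  bits
}

#' Do two IUPAC codes match?
#'
#' Two codes match when their base sets intersect (optimistic degenerate
#' matching, as used by TestPrime-style in-silico PCR tools). The relation
#' is symmetric.
#'
#' @param code_a,code_b Single IUPAC characters (vectors are recycled
#'   elementwise).
#' @return Logical vector.
#' @examples
#' iupac_match("R", "A") # TRUE: A is in \{A,G\}
#' iupac_match("Y", "G") # FALSE
#' @export
iupac_match <- function(code_a, code_b) {
  a <- normalize_pattern(as.character(code_a))
  b <- normalize_pattern(as.character(code_b))
  bits_a <- IUPAC_BITS[a]
  bits_b <- IUPAC_BITS[b]
  if (anyNA(bits_a)) {
    i <- which(is.na(bits_a))[1]
    stop(sprintf("invalid IUPAC character '%s' at position %d", a[i], i),
         call. = FALSE)
  }
  if (anyNA(bits_b)) {
    i <- which(is.na(bits_b))[1]
    stop(sprintf("invalid IUPAC character '%s' at position %d", b[i], i),
         call. = FALSE)
  }
  unname(bitwAnd(bits_a, bits_b) > 0L)
}

#' Degeneracy of an IUPAC pattern
#'
#' The number of distinct plain A/C/G/T sequences the pattern represents:
#' the product of per-position base-set sizes.
#'
#' @param pattern Pattern string.
#' @return A numeric scalar (may exceed integer range for long patterns).
#' @export
iupac_degeneracy <- function(pattern) {
  bits <- encode_pattern(pattern)
  prod(BASES_PER_CODE[match(bits, IUPAC_BITS)])
}

#' Expand a degenerate pattern into its plain sequences
#'
#' @param pattern Pattern string.
#' @param max_degeneracy Enumeration cap; patterns above it raise an error
#'   (use the enumeration-free operations instead).
#' @return Character vector of plain A/C/G/T sequences, lexicographically
#'   sorted; length equals the degeneracy.
#' @export
iupac_expand <- function(pattern, max_degeneracy = 65536) {
  bits <- encode_pattern(pattern)
  deg <- prod(BASES_PER_CODE[match(bits, IUPAC_BITS)])
  if (deg > max_degeneracy) {
    stop(sprintf(
      paste0("degeneracy %.0f exceeds cap %.0f; use enumeration-free ",
             "operations (count_mismatches, oligo_physchem) instead"),
      deg, max_degeneracy
    ), call. = FALSE)
  }
  sets <- lapply(bits, function(b) {
    c("A", "C", "G", "T")[bitwAnd(b, c(1L, 2L, 4L, 8L)) > 0L]
  })
  grid <- do.call(expand.grid, c(rev(sets), stringsAsFactors = FALSE))
  out <- do.call(paste0, rev(grid))
  sort(out)
}

#' Reverse complement of an IUPAC pattern
#'
#' Complements ambiguity codes correctly (R-Y, K-M, B-V, D-H; S, W and N
#' are self-complementary) and reverses. Applying it twice returns the
#' input.
#'
#' @param pattern Pattern string (gaps allowed and preserved).
#' @return Reverse-complemented pattern string.
#' @examples
#' iupac_revcomp("GTCGTMACAAGGTANCCG") # "CGGNTACCTTGTKACGAC"
#' @export
iupac_revcomp <- function(pattern) {
  pattern <- normalize_pattern(pattern)
  encode_pattern(pattern, allow_gaps = TRUE) # validation only
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
}

# Internal vectorized mismatch counter.
# pattern_bits: encoded primer (plus-strand orientation as compared);
# windows: character vector of equal-length target windows (gaps allowed
#   when allow_gaps; a gap never matches);
# three_prime: which end of the compared pattern is the primer's 3' end
#   ("right" for a forward primer, "left" for the reverse complement of a
#   reverse primer compared on the plus strand).
mismatch_counts <- function(pattern_bits, windows, terminal_zone = 2L,
                            three_prime = c("right", "left"),
                            allow_gaps = FALSE) {
  three_prime <- match.arg(three_prime)
  n <- length(windows)
  L <- length(pattern_bits)
  if (n == 0L) {
    return(tibble::tibble(total = integer(), terminal = integer()))
  }
  if (any(nchar(windows) != L)) {
    stop("target window length must equal primer length", call. = FALSE)
  }
  mat <- matrix(unlist(strsplit(normalize_pattern(windows), "",
                                fixed = TRUE), use.names = FALSE),
                nrow = L)
  tb <- matrix(IUPAC_BITS[mat], nrow = L)
  if (anyNA(tb)) stop("invalid character in target window", call. = FALSE)
  if (!allow_gaps && any(tb == 0L)) {
    stop("target window contains gap characters", call. = FALSE)
  }
  if (!allow_gaps && any(!tb %in% c(1L, 2L, 4L, 8L))) {
    stop("target window must contain only A/C/G/T", call. = FALSE)
  }
  mm <- bitwAnd(tb, pattern_bits) == 0L # recycles pattern down columns
  dim(mm) <- dim(tb)
  zone <- min(terminal_zone, L)
  zone_rows <- if (three_prime == "right") seq_len(zone) + L - zone
               else seq_len(zone)
  tibble::tibble(
    total = as.integer(colSums(mm)),
    terminal = if (zone > 0L) {
      as.integer(colSums(mm[zone_rows, , drop = FALSE]))
    } else {
      integer(n)
    }
  )
}

#' Count primer-target mismatches with 3'-terminal weighting
#'
#' A primer position mismatches its target base when the IUPAC base sets
#' do not intersect. The terminal count covers the `terminal_zone`
#' positions at the primer's 3' end: the rightmost positions for a primer
#' compared in its own orientation (`three_prime = "right"`), or the
#' leftmost positions when a reverse-orientation primer has been
#' reverse-complemented onto the plus strand (`three_prime = "left"`).
#'
#' @param primer Degenerate pattern string.
#' @param target_window Character vector of plain A/C/G/T windows, each the
#'   same length as the primer.
#' @param terminal_zone Width of the 3'-terminal zone (default 2).
#' @param three_prime Which end of the compared pattern is the 3' end.
#' @return A tibble with one row per target window and integer columns
#'   `total` and `terminal` (`terminal <= total`).
#' @export
count_mismatches <- function(primer, target_window, terminal_zone = 2L,
                             three_prime = c("right", "left")) {
  bits <- encode_pattern(primer, what = "primer")
  mismatch_counts(bits, target_window, terminal_zone,
                  match.arg(three_prime), allow_gaps = FALSE)
}

# Unified nearest-neighbor parameters (SantaLucia 1998), kcal/mol and
# cal/(mol K). Keys are 5'->3' dinucleotides on one strand.
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
           CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)

tm_basic <- function(n_gc, len) {
  64.9 + 41 * (n_gc - 16.4) / len
}

tm_nearest_neighbor <- function(seqs, primer_conc = 5e-7, na_conc = 0.05) {
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    din <- paste0(ch[-length(ch)], ch[-1])
    dh <- sum(NN_DH[din])
    ds <- sum(NN_DS[din])
    # initiation with terminal A/T vs G/C penalties
    for (term in ch[c(1, length(ch))]) {
      if (term %in% c("G", "C")) {
        dh <- dh + 0.1; ds <- ds + (-2.8)
      } else {
        dh <- dh + 2.3; ds <- ds + 4.1
      }
    }
    tm <- dh * 1000 / (ds + 1.987 * log(primer_conc / 4)) - 273.15
    tm + 16.6 * log10(na_conc)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Physicochemical summary of a degenerate oligo
#'
#' GC-content extremes are computed without enumeration from per-position
#' set membership: a position contributes 1 to the minimum GC count only
#' if its whole base set is \{G,C\}-only, and to the maximum if the set
#' contains G or C. The mean GC is exact (each position contributes the
#' fraction of its set members that are G/C, uniform over expansions).
#' Melting temperatures: "basic" is Tm = 64.9 + 41 (nG+nC-16.4)/L, a
#' linear function of GC count, so its min/mean/max are exact without
#' enumeration; "nearest_neighbor" (unified NN parameters, 50 mM Na+,
#' 0.5 uM oligo) enumerates expansions (capped).
#'
#' @param pattern Degenerate pattern string.
#' @param tm_method `"basic"` (default) or `"nearest_neighbor"`.
#' @param max_degeneracy Enumeration cap for the nearest-neighbor method.
#' @return A tibble with one row: `gc_min`, `gc_mean`, `gc_max` (fractions),
#'   `tm_min`, `tm_mean`, `tm_max` (degrees Celsius), `degenerate_fraction`,
#'   and `degeneracy`.
#' @export
oligo_physchem <- function(pattern, tm_method = c("basic", "nearest_neighbor"),
                           max_degeneracy = 65536) {
  tm_method <- match.arg(tm_method)
  bits <- encode_pattern(pattern)
  L <- length(bits)
  set_size <- BASES_PER_CODE[match(bits, IUPAC_BITS)]
  gc_size <- vapply(bits, function(b) {
    sum(bitwAnd(b, c(2L, 4L)) > 0L) # C and G bits
  }, integer(1))
  gc_min_n <- sum(gc_size == set_size) # all members are G/C
  gc_max_n <- sum(gc_size > 0L)
  gc_mean_n <- sum(gc_size / set_size)
  if (tm_method == "basic") {
    tms <- tm_basic(c(gc_min_n, gc_mean_n, gc_max_n), L)
  } else {
    seqs <- iupac_expand(pattern, max_degeneracy)
    all_tm <- tm_nearest_neighbor(seqs)
    tms <- c(min(all_tm), mean(all_tm), max(all_tm))
  }
  tibble::tibble(
    gc_min = gc_min_n / L, gc_mean = gc_mean_n / L, gc_max = gc_max_n / L,
    tm_min = tms[1], tm_mean = tms[2], tm_max = tms[3],
    degenerate_fraction = mean(set_size > 1L),
    degeneracy = prod(set_size)
  )
}
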