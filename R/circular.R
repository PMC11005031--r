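#' Circular DNA sequence
#'
#' Constructs a circular DNA molecule. The sequence is stored linearly
#' with an implicit origin; all coordinate arithmetic elsewhere in the
#' package is modulo `length`, so extractions may wrap across the origin
#' and no caller ever needs to rotate the molecule physically.
#'
#' Internally every interval is 0-based half-open; all report output
#' (TSV catalogs, nesting tables) is converted to 1-based inclusive.
#'
#' @param seq character scalar over {A,C,G,T,N} (lowercase accepted,
#'   uppercased on construction).
#' @param id label for the molecule.
#' @return an object of class `circular_sequence` with fields `id`,
#'   `seq` and `length`.
#' @examples
#' circular_sequence("ACGTAC", id = "toy")
#' @export
circular_sequence <- function(seq, id = "seq") {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) == 0L) stop("empty sequence for record '", id, "'", call. = FALSE)
  .assert_dna(seq, id)
  structure(list(id = id, seq = seq, length = nchar(seq)),
            class = "circular_sequence")
}

#' @export
print.circular_sequence <- function(x, ...) {
  head <- substr(x$seq, 1L, 24L)
  cat(sprintf("<circular_sequence> %s: %s bp  [%s%s]\n",
              x$id, format(x$length, big.mark = ","), head,
              if (x$length > 24L) "..." else ""))
  invisible(x)
}

#' @export
length.circular_sequence <- function(x) x$length

#' Extract a (possibly wrapping) subsequence from a circular molecule
#'
#' Coordinates are 0-based half-open; `end0` may exceed the molecule
#' length to denote a span crossing the origin. `strand = "-"` returns
#' the reverse complement of the extracted segment.
#'
#' @param x a [circular_sequence()].
#' @param start0,end0 0-based half-open span, `end0 > start0`.
#' @param strand `"+"` or `"-"`.
#' @return character scalar of length `end0 - start0`.
#' @examples
#' circ_extract(circular_sequence("ACGTAC"), 4, 8)   # "ACAC", wraps
#' @export
circ_extract <- function(x, start0, end0, strand = "+") {
  stopifnot(inherits(x, "circular_sequence"))
  len <- end0 - start0
  if (len <= 0) stop("end0 must exceed start0", call. = FALSE)
  if (len > x$length) {
    stop("requested span (", len, " bp) exceeds molecule length (",
         x$length, " bp)", call. = FALSE)
  }
  s0 <- start0 %% x$length
  out <- if (s0 + len <= x$length) {
    substr(x$seq, s0 + 1L, s0 + len)
  } else {
    paste0(substr(x$seq, s0 + 1L, x$length),
           substr(x$seq, 1L, s0 + len - x$length))
  }
  if (strand == "-") out <- revcomp(out) else if (strand != "+")
    stop("strand must be '+' or '-'", call. = FALSE)
  out
}

# Lexicographically least rotation of a string, by iterative candidate
# refinement on the byte vector (fast on non-periodic sequences; falls
# back to the first surviving candidate on full periodicity, where all
# survivors are identical rotations).
.least_rotation <- function(seq) {
  n <- nchar(seq)
  if (n == 1L) return(seq)
  b <- as.integer(charToRaw(seq))
  b2 <- c(b, b)
  cand <- which(b == min(b))
  d <- 1L
  while (length(cand) > 1L && d < n) {
    v <- b2[cand + d]
    cand <- cand[v == min(v)]
    d <- d + 1L
  }
  i <- cand[1L]
  rawToChar(as.raw(b2[i:(i + n - 1L)]))
}

# Byte-wise comparison avoids locale-dependent collation.
.str_min <- function(a, b) {
  if (a == b) return(a)
  ra <- charToRaw(a); rb <- charToRaw(b)
  k <- which(ra != rb)[1L]
  if (is.na(k)) return(if (length(ra) <= length(rb)) a else b)
  if (ra[k] < rb[k]) a else b
}

#' Canonical form of a circular molecule
#'
#' The lexicographically minimal string over all rotations of the
#' sequence and all rotations of its reverse complement. Two circular
#' molecules represent the same physical DNA circle iff their canonical
#' forms are identical, which is how isomeric genome forms are
#' de-duplicated throughout the package.
#'
#' @param x a [circular_sequence()] or a plain character scalar.
#' @return character scalar.
#' @examples
#' canonical_form("AAC")            # "AAC"
#' canonical_form("CAA")            # also "AAC": same circle
#' @export
canonical_form <- function(x) {
  seq <- if (inherits(x, "circular_sequence")) x$seq else toupper(x)
  .str_min(.least_rotation(seq), .least_rotation(revcomp(seq)))
}

# Canonical key of a set of circles (multiset equality of molecules).
.form_key <- function(seqs) {
  paste(sort(vapply(seqs, canonical_form, character(1))), collapse = "|")
}

#' Summary statistics of an assembled circular genome
#'
#' Length, GC content (percent, over non-N bases) and the number of
#' dispersed repeat families at the given detection settings. Intended
#' for checking an assembly (e.g. a downloaded organelle genome) against
#' its published description.
#'
#' @param genome a [circular_sequence()].
#' @param min_len,min_identity passed to [find_dispersed_repeats()].
#' @return list with `length_bp`, `gc_percent`, `n_repeat_families`,
#'   `n_repeat_copies`.
#' @export
genome_stats <- function(genome, min_len = 50L, min_identity = 1.0) {
  stopifnot(inherits(genome, "circular_sequence"))
  counts <- table(strsplit(genome$seq, "", fixed = TRUE)[[1]])
  acgt <- sum(counts[intersect(names(counts), c("A", "C", "G", "T"))])
  gc <- sum(counts[intersect(names(counts), c("G", "C"))]) / acgt * 100
  cat_ <- find_dispersed_repeats(genome, min_len = min_len,
                                 min_identity = min_identity)
  list(length_bp = genome$length,
       gc_percent = round_half_up(gc, 2L),
       n_repeat_families = length(cat_$families),
       n_repeat_copies = sum(vapply(cat_$families,
                                    function(f) nrow(f$copies), integer(1))))
}
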