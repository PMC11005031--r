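# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero, the
#' convention used for the printed support-rate tables (base `round()`
#' uses round-half-even).
#'
#' @param x numeric vector.
#' @param digits integer, decimal places.
#' @return numeric vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

.assert_dna <- function(seq, id = "<sequence>") {
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop("record '", id, "' contains characters outside {A,C,G,T,N}",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Reverse complement of a DNA string
#'
#' @param seq character scalar over {A,C,G,T,N}.
#' @return character scalar.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Vectorised reverse complement for many reads.
revcomp_many <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

# 0-based modular position -> 1-based index into a linear string.
.mod1 <- function(pos0, n) (pos0 %% n) + 1L

# Random DNA of length n with given GC content.
random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Merge 1-based closed integer intervals given as a 2-column matrix;
# returns total covered length.
.covered_length <- function(starts, ends) {
  if (length(starts) == 0L) return(0L)
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  tot <- 0L
  cs <- starts[1L]; ce <- ends[1L]
  for (i in seq_along(starts)[-1L]) {
    if (starts[i] <= ce + 1L) {
      ce <- max(ce, ends[i])
    } else {
      tot <- tot + (ce - cs + 1L)
      cs <- starts[i]; ce <- ends[i]
    }
  }
  tot + (ce - cs + 1L)
}
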