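# Junction references and read-support classification for one repeat
# pair: the four flank+repeat+flank sequences (two reproducing the
# genome, two representing the recombinant configurations), and the
# dual-flank overlap rule that decides whether a read supports any of
# them.

#' Build the four junction references for a repeat pair
#'
#' Extracts `flank_len` bp upstream and downstream of each copy (after
#' orienting each copy's context so the repeat reads forward: for the
#' minus-strand copy of an IR pair the context is reverse-complemented)
#' and assembles the four candidate isomer sequences:
#' `ref_a = Ua+R+Da`, `ref_b = Ub+R+Db` (the configurations present in
#' the genome) and `alt_ab = Ua+R+Db`, `alt_ba = Ub+R+Da` (the
#' recombinant configurations). Flanks wrap across the origin as needed.
#'
#' If a flank overlaps the partner copy of the same pair a warning about
#' junction ambiguity is raised; if a flank fully contains the partner
#' copy the junction set is refused.
#'
#' @param genome a [circular_sequence()].
#' @param pair resolved pair as returned by `.resolve_pair()` /
#'   [catalog_pairs()] row resolved against the catalog, or any list
#'   with `copy1`, `copy2` (each `start0`, `end0`, `strand`), `len`,
#'   `class`, and optionally `name`.
#' @param flank_len flank length in bp (default 3000).
#' @return object of class `junction_set`: `refs` (named character
#'   vector of the 4 references), `pair_name`, `pair_class`,
#'   `repeat_len`, `flank_len`.
#' @export
build_junctions <- function(genome, pair, flank_len = 3000L) {
  stopifnot(inherits(genome, "circular_sequence"))
  flank_len <- as.integer(flank_len)
  if (flank_len < 1L) stop("flank_len must be >= 1", call. = FALSE)
  rep_len <- pair$copy1$end0 - pair$copy1$start0
  if (2L * flank_len + rep_len > genome$length) {
    stop("genome too small for 2*flank_len + repeat length", call. = FALSE)
  }
  n <- genome$length

  flanks <- function(cp, other) {
    # oriented context: upstream/downstream in the copy's reading frame
    if (cp$strand == "+") {
      u_iv <- c(cp$start0 - flank_len, cp$start0)
      d_iv <- c(cp$end0, cp$end0 + flank_len)
      u <- circ_extract(genome, u_iv[1L], u_iv[2L], "+")
      d <- circ_extract(genome, d_iv[1L], d_iv[2L], "+")
    } else {
      u_iv <- c(cp$end0, cp$end0 + flank_len)
      d_iv <- c(cp$start0 - flank_len, cp$start0)
      u <- circ_extract(genome, u_iv[1L], u_iv[2L], "-")
      d <- circ_extract(genome, d_iv[1L], d_iv[2L], "-")
    }
    for (iv in list(u_iv, d_iv)) {
      ov <- .circ_overlap_len(iv[1L], iv[2L], other$start0, other$end0, n)
      if (ov >= other$end0 - other$start0) {
        stop("flank fully contains the partner repeat copy; junction ",
             "references would be uninformative", call. = FALSE)
      }
      if (ov > 0L) {
        warning("flank overlaps the partner repeat copy by ", ov,
                " bp: junction may be ambiguous", call. = FALSE)
      }
    }
    list(u = u, d = d)
  }
  # repeat in + orientation as presented by copy1's frame
  R <- circ_extract(genome, pair$copy1$start0, pair$copy1$end0,
                    pair$copy1$strand)
  fa <- flanks(pair$copy1, pair$copy2)
  fb <- flanks(pair$copy2, pair$copy1)
  refs <- c(ref_a = paste0(fa$u, R, fa$d),
            ref_b = paste0(fb$u, R, fb$d),
            alt_ab = paste0(fa$u, R, fb$d),
            alt_ba = paste0(fb$u, R, fa$d))
  structure(list(refs = refs,
                 pair_name = if (!is.null(pair$name)) pair$name else "pair",
                 pair_class = pair$class,
                 repeat_len = rep_len,
                 flank_len = flank_len),
            class = "junction_set")
}

# overlap length of circular intervals [s1,e1) and [s2,e2) (0-based,
# e may exceed n)
.circ_overlap_len <- function(s1, e1, s2, e2, n) {
  s1 <- ((s1 %% n) + n) %% n; s2 <- ((s2 %% n) + n) %% n
  l1 <- e1 - s1; l2 <- e2 - s2
  ov <- 0L
  for (sh in c(0L, n)) { # unwrap both candidate placements
    a1 <- s1 + sh
    for (sh2 in c(0L, n)) {
      a2 <- s2 + sh2
      ov <- max(ov, min(a1 + l1, a2 + l2) - max(a1, a2))
    }
  }
  max(0L, ov)
}

#' @export
print.junction_set <- function(x, ...) {
  cat(sprintf("<junction_set> %s (%s, %d bp repeat, %d bp flanks)\n",
              x$pair_name, x$pair_class, x$repeat_len, x$flank_len))
  for (nm in names(x$refs)) {
    cat(sprintf("  %-6s %6d bp\n", nm, nchar(x$refs[[nm]])))
  }
  invisible(x)
}

#' Write the four junction references of a pair to FASTA
#'
#' @param jset a [build_junctions()] result.
#' @param path output FASTA.
#' @export
write_junctions_fasta <- function(jset, path) {
  seqs <- as.list(jset$refs)
  names(seqs) <- paste0(jset$pair_name, "|", names(jset$refs))
  write_fasta(seqs, path)
}

#' Classify a read alignment against a junction set
#'
#' A read supports a configuration only if its primary alignment covers
#' at least `min_flank_overlap` bases of the upstream flank AND at least
#' `min_flank_overlap` bases of the downstream flank of that junction
#' reference; anything else is `unassigned`. The threshold must exceed
#' the span of any repeat nested in the flanks for the assignment to be
#' informative (with 3,000 bp flanks the default 1,800 bp clears a
#' 1,467 bp covering repeat).
#'
#' @param aln a `read_alignment` computed against `kmer_index(jset$refs)`.
#' @param jset the [build_junctions()] result the alignment used.
#' @param min_flank_overlap minimum overlap into each flank (default 1800).
#' @return one of `"ref_a"`, `"ref_b"`, `"alt_ab"`, `"alt_ba"`,
#'   `"unassigned"`.
#' @export
classify_read <- function(aln, jset, min_flank_overlap = 1800L) {
  stopifnot(inherits(jset, "junction_set"))
  if (min_flank_overlap > jset$flank_len) {
    stop("min_flank_overlap exceeds flank_len", call. = FALSE)
  }
  if (is.na(aln$ref) || !(aln$ref %in% names(jset$refs))) return("unassigned")
  fl <- jset$flank_len
  up_cov <- min(aln$rend, fl) - aln$rstart + 1L
  down_start <- fl + jset$repeat_len + 1L
  down_cov <- aln$rend - max(aln$rstart, down_start) + 1L
  if (up_cov >= min_flank_overlap && down_cov >= min_flank_overlap) {
    aln$ref
  } else {
    "unassigned"
  }
}

#' Classify a set of reads against one junction set
#'
#' Aligns each read against the four junction references (primary =
#' best-scoring collinear chain over references and strands) and applies
#' the dual-flank rule of [classify_read()].
#'
#' @param reads data.frame with `id` and `seq` columns (see
#'   [read_reads()] / [simulate_reads()]).
#' @param jset a [build_junctions()] result.
#' @param min_flank_overlap see [classify_read()].
#' @param k,stride anchor parameters passed to the aligner.
#' @return data.frame with columns `id`, `label`.
#' @export
classify_reads <- function(reads, jset, min_flank_overlap = 1800L,
                           k = 15L, stride = 5L) {
  idx <- kmer_index(jset$refs, k = k)
  min_read <- 2L * min_flank_overlap
  labels <- character(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    if (nchar(reads$seq[i]) < min_read) { # unclassifiable by length
      labels[i] <- "unassigned"
      next
    }
    aln <- align_read(reads$seq[i], idx, stride = stride,
                      read_id = reads$id[i])
    labels[i] <- classify_read(aln, jset, min_flank_overlap)
  }
  data.frame(id = reads$id, label = labels, stringsAsFactors = FALSE)
}

#' Per-pair support counts and rearrangement rates
#'
#' Pools `ref_a`+`ref_b` into the reference configuration count and
#' `alt_ab`+`alt_ba` into the alternative, and reports 2-decimal
#' percentages (rounded half away from zero); percentages are blank when
#' no read is assigned.
#'
#' @param labels_per_pair named list: pair name -> label vector (or the
#'   data.frame from [classify_reads()]).
#' @param pair_meta optional data.frame with `pair_name`, `pair_class`,
#'   `length` giving the report's repeat metadata columns.
#' @return object of class `support_table`: data.frame with columns
#'   `pair`, `class`, `length`, `pct_reference`, `n_reference`,
#'   `pct_alternative`, `n_alternative`.
#' @export
support_rates <- function(labels_per_pair, pair_meta = NULL) {
  if (is.data.frame(labels_per_pair)) {
    labels_per_pair <- list(pair = labels_per_pair$label)
  }
  rows <- lapply(names(labels_per_pair), function(nm) {
    lab <- labels_per_pair[[nm]]
    if (is.data.frame(lab)) lab <- lab$label
    n_ref <- sum(lab %in% c("ref_a", "ref_b"))
    n_alt <- sum(lab %in% c("alt_ab", "alt_ba"))
    tot <- n_ref + n_alt
    meta <- if (!is.null(pair_meta) && nm %in% pair_meta$pair_name) {
      pair_meta[match(nm, pair_meta$pair_name), ]
    } else {
      data.frame(pair_class = NA_character_, length = NA_integer_)
    }
    data.frame(pair = nm,
               class = meta$pair_class,
               length = meta$length,
               pct_reference = if (tot) round_half_up(n_ref / tot * 100, 2L)
                               else NA_real_,
               n_reference = n_ref,
               pct_alternative = if (tot) round_half_up(n_alt / tot * 100, 2L)
                                 else NA_real_,
               n_alternative = n_alt,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("support_table", "data.frame"))
}

#' Support rates from pre-tabulated counts
#'
#' Computes the percentage columns of a support table directly from
#' reference/alternative supporting-read counts (e.g. a published table
#' re-checked by arithmetic).
#'
#' @param counts data.frame with columns `pair`, `n_reference`,
#'   `n_alternative` and optionally `class`, `length`.
#' @return a `support_table`.
#' @export
support_rates_from_counts <- function(counts) {
  stopifnot(all(c("pair", "n_reference", "n_alternative") %in% names(counts)))
  tot <- counts$n_reference + counts$n_alternative
  out <- data.frame(
    pair = counts$pair,
    class = if ("class" %in% names(counts)) counts$class else NA_character_,
    length = if ("length" %in% names(counts)) counts$length else NA_integer_,
    pct_reference = ifelse(tot > 0,
                           round_half_up(counts$n_reference / tot * 100, 2L),
                           NA_real_),
    n_reference = counts$n_reference,
    pct_alternative = ifelse(tot > 0,
                             round_half_up(counts$n_alternative / tot * 100, 2L),
                             NA_real_),
    n_alternative = counts$n_alternative,
    stringsAsFactors = FALSE)
  structure(out, class = c("support_table", "data.frame"))
}

#' @export
print.support_table <- function(x, ...) {
  cat("Rates of rearrangement mediated by repeat pairs\n")
  df <- as.data.frame(x)
  df$`%reference` <- ifelse(is.na(df$pct_reference), "",
                            sprintf("%.2f (%d)", df$pct_reference,
                                    df$n_reference))
  df$`%alternative` <- ifelse(is.na(df$pct_alternative), "",
                              sprintf("%.2f (%d)", df$pct_alternative,
                                      df$n_alternative))
  print.data.frame(df[, c("pair", "class", "length",
                          "%reference", "%alternative")],
                   row.names = FALSE)
  invisible(x)
}

#' Write a support table to TSV
#'
#' @param x a `support_table`.
#' @param path output TSV.
#' @export
write_support_tsv <- function(x, path) {
  write_tsv_report(as.data.frame(x), path,
                   meta = "percentages pooled over ref_a+ref_b vs alt_ab+alt_ba")
}
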