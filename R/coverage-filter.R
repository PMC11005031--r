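# Read-set curation: organelle read extraction by query coverage,
# duplex-like artifact removal, and full-length linear accounting of
# reads against the master circle and one alternative form.

# Index of a circular reference: the doubled sequence, so a single
# collinear chain can cross the origin.
.circular_index <- function(circles, k = 15L) {
  seqs <- vapply(circles, function(cc) {
    if (inherits(cc, "circular_sequence")) paste0(cc$seq, cc$seq) else
      paste0(cc, cc)
  }, character(1))
  ids <- vapply(circles, function(cc)
    if (inherits(cc, "circular_sequence")) cc$id else "circle", character(1))
  names(seqs) <- make.unique(ids)
  kmer_index(seqs, k = k)
}

#' Partition reads into organelle compartments by query coverage
#'
#' Each read is assigned to the compartment (e.g. mitochondrial,
#' nuclear, plastid) where its best alignment lies; it is retained as
#' mitochondrial only if its total query coverage on the mitochondrial
#' reference -- non-overlapping query spans pooled over all alignments
#' to that compartment -- reaches `min_query_coverage`. Reads below the
#' bar for every compartment land in `unassigned`.
#'
#' @param reads data.frame with `id`, `seq` columns.
#' @param refs named list of compartment references (each a
#'   [circular_sequence()], a character sequence, or a list of circles);
#'   must contain an entry named `mito`.
#' @param min_query_coverage coverage threshold for the mitochondrial
#'   bin (default 0.70).
#' @param k,stride anchor parameters.
#' @return named list of data.frames, one per compartment plus
#'   `unassigned`.
#' @export
extract_organelle_reads <- function(reads, refs, min_query_coverage = 0.70,
                                    k = 15L, stride = 5L) {
  stopifnot("mito" %in% names(refs))
  idxs <- lapply(refs, function(r) {
    circles <- if (inherits(r, "circular_sequence") || is.character(r))
      list(r) else r
    .circular_index(circles, k = k)
  })
  comps <- names(refs)
  cov <- matrix(0, nrow = nrow(reads), ncol = length(comps),
                dimnames = list(NULL, comps))
  for (i in seq_len(nrow(reads))) {
    for (cmp in comps) {
      cov[i, cmp] <- .query_coverage(reads$seq[i], idxs[[cmp]], stride = stride)
    }
  }
  best_i <- max.col(cov, ties.method = "first")
  best <- comps[best_i]
  best_cov <- cov[cbind(seq_len(nrow(reads)), best_i)]
  assigned <- ifelse(best == "mito" & cov[, "mito"] >= min_query_coverage,
                     "mito",
                     ifelse(best != "mito" & best_cov > 0, best, "unassigned"))
  out <- lapply(c(comps, "unassigned"), function(cmp)
    reads[assigned == cmp, , drop = FALSE])
  names(out) <- c(comps, "unassigned")
  out
}

#' Remove duplex-like read artifacts
#'
#' A duplex-like read is a sequencing artifact whose two halves are
#' reverse complements of each other: both halves map to the same
#' reference region on opposite strands, so the read cannot be aligned
#' linearly. A read is removed when its two halves align to reference
#' spans with reciprocal overlap of at least `min_reciprocal_overlap`
#' on opposite strands.
#'
#' @param reads data.frame with `id`, `seq` columns.
#' @param reference a [circular_sequence()] (or list of circles).
#' @param min_reciprocal_overlap reciprocal overlap fraction of the two
#'   half alignments (default 0.8; not stated by the upstream protocol,
#'   exposed as a flag).
#' @param k,stride anchor parameters.
#' @return list with `kept` and `removed` data.frames.
#' @export
remove_duplex_like <- function(reads, reference, min_reciprocal_overlap = 0.8,
                               k = 15L, stride = 5L) {
  circles <- if (inherits(reference, "circular_sequence") ||
                 is.character(reference)) list(reference) else reference
  idx <- .circular_index(circles, k = k)
  circ_len <- idx$ref_len %/% 2L # references are doubled circles
  dup <- logical(nrow(reads))
  for (i in seq_len(nrow(reads))) {
    s <- reads$seq[i]
    n <- nchar(s)
    if (n < 4L * k) next
    half <- n %/% 2L
    c1 <- .align_candidates(substr(s, 1L, half), idx, stride = stride)
    c2 <- .align_candidates(substr(s, half + 1L, n), idx, stride = stride)
    if (!nrow(c1) || !nrow(c2)) next
    a1 <- c1[order(-c1$score, c1$ri, c1$strand)[1L], ]
    # among near-best placements of the second half (a repeat copy or
    # the doubled reference makes placement ambiguous), take the one
    # most consistent with an opposite-strand duplex fold-back
    c2 <- c2[c2$score >= 0.8 * max(c2$score) & c2$ri == a1$ri &
               c2$strand != a1$strand, , drop = FALSE]
    if (!nrow(c2)) next
    nmod <- circ_len[a1$ri]
    best_ov <- 0; l2best <- 1L
    for (j in seq_len(nrow(c2))) {
      shift <- round((c2$rs[j] - a1$rs) / nmod) * nmod
      ov <- min(a1$re, c2$re[j] - shift) - max(a1$rs, c2$rs[j] - shift) + 1L
      if (ov > best_ov) { best_ov <- ov; l2best <- c2$re[j] - c2$rs[j] + 1L }
    }
    l1 <- a1$re - a1$rs + 1L
    if (best_ov >= min_reciprocal_overlap * l1 &&
        best_ov >= min_reciprocal_overlap * l2best)
      dup[i] <- TRUE
  }
  list(kept = reads[!dup, , drop = FALSE],
       removed = reads[dup, , drop = FALSE])
}

#' Full-length linear read accounting against MC1 and an alternative form
#'
#' A read is counted as explained by the master circle when a single
#' collinear alignment chain (one strand, monotone coordinates; the
#' circular reference is doubled internally so chains may cross the
#' origin) covers at least `threshold` of its bases; reads failing that
#' are tested the same way against the alternative form's circle(s), and
#' the rest are unexplained. When both references satisfy the rule the
#' read counts for the master circle (the test is ordered).
#'
#' @param reads data.frame with `id`, `seq` columns.
#' @param mc1 the master circle ([circular_sequence()]).
#' @param alt_form the alternative form: a `genome_form`, a list of
#'   circles, or a single [circular_sequence()].
#' @param threshold fraction of read bases that must align linearly
#'   (default 0.95).
#' @param k,stride,bandwidth anchor parameters.
#' @return object of class `full_length_report`: list with `n_total`,
#'   `n_mc1_full`, `n_alt_full`, `n_unexplained`, `fraction_explained`,
#'   and per-read `assignment` data.frame.
#' @export
full_length_accounting <- function(reads, mc1, alt_form, threshold = 0.95,
                                   k = 15L, stride = 5L, bandwidth = 100L) {
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  alt_circles <- if (inherits(alt_form, "genome_form")) alt_form$circles
    else if (inherits(alt_form, "circular_sequence")) list(alt_form)
    else alt_form
  idx_mc1 <- .circular_index(list(mc1), k = k)
  idx_alt <- .circular_index(alt_circles, k = k)
  lab <- character(nrow(reads))
  full <- function(read, idx) {
    aln <- align_read(read, idx, stride = stride, bandwidth = bandwidth,
                      refine = FALSE)
    !is.na(aln$ref) && (aln$qend - aln$qstart + 1L) >= threshold * nchar(read)
  }
  for (i in seq_len(nrow(reads))) {
    lab[i] <- if (full(reads$seq[i], idx_mc1)) "mc1_full"
      else if (full(reads$seq[i], idx_alt)) "alt_full"
      else "unexplained"
  }
  n_mc1 <- sum(lab == "mc1_full"); n_alt <- sum(lab == "alt_full")
  structure(list(n_total = nrow(reads),
                 n_mc1_full = n_mc1,
                 n_alt_full = n_alt,
                 n_unexplained = nrow(reads) - n_mc1 - n_alt,
                 fraction_explained = if (nrow(reads))
                   (n_mc1 + n_alt) / nrow(reads) else NA_real_,
                 assignment = data.frame(id = reads$id, label = lab,
                                         stringsAsFactors = FALSE)),
            class = "full_length_report")
}

#' @export
print.full_length_report <- function(x, ...) {
  cat(sprintf(paste0("<full_length_report> %d reads: %d full on MC1, ",
                     "%d full on alternative, %d unexplained ",
                     "(%.1f%% explained)\n"),
              x$n_total, x$n_mc1_full, x$n_alt_full, x$n_unexplained,
              100 * x$fraction_explained))
  invisible(x)
}

#' Write a full-length accounting report to TSV
#'
#' @param x a `full_length_report`.
#' @param path output TSV.
#' @export
write_full_length_tsv <- function(x, path) {
  df <- data.frame(n_total = x$n_total, n_mc1_full = x$n_mc1_full,
                   n_alt_full = x$n_alt_full,
                   n_unexplained = x$n_unexplained,
                   fraction_explained = x$fraction_explained)
  write_tsv_report(df, path)
}
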