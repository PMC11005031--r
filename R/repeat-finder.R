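# Dispersed-repeat discovery on a circular genome.
#
# Strategy: exact k-mer seeds over the doubled sequence (so wrapped
# copies are seen), seed pairs chained along diagonals into candidate
# matches, maximal extension with modular arithmetic, de-duplication of
# circularly equivalent hits, then union-find over copies to assemble
# repeat families. N never matches anything, so seeds and extensions
# stop at N runs.

#' Find dispersed repeat families on a circular genome
#'
#' Detects all maximal repeated segment pairs of length `>= min_len`,
#' both direct (same strand) and inverted (opposite strands), wrapping
#' across the origin where needed, and groups copies into families.
#' Families are numbered by descending length (family 1 = longest, ties
#' broken by first copy position) and copies are lettered a, b, c, ...
#' by ascending genome position. Pairs whose two copies overlap on the
#' circle (tandem arrangements) are outside this package's scope and
#' are dropped.
#'
#' `min_identity = 1` (the default) reports exact repeats, the
#' substrates of clean homologous recombination. Values below 1 relax
#' the extension to tolerate mismatches while the running identity stays
#' at or above the threshold (substitutions only, no indels; intended
#' range 0.99-1).
#'
#' @param genome a [circular_sequence()].
#' @param min_len minimum repeat length in bp (must be >= 20; k-mer
#'   seeds shorter than that are unreliable on genome-scale input).
#' @param min_identity minimum identity fraction of a reported copy pair.
#' @return an object of class `repeat_catalog`: list with `genome_id`,
#'   `genome_length`, and `families`, each family holding `family_id`,
#'   `length`, `seq` (the repeat sequence oriented as copy a) and a
#'   `copies` data.frame (`label`, `start0`, `end0`, `strand`; 0-based
#'   half-open, `end0` may exceed the genome length to denote an
#'   origin-crossing copy).
#' @seealso [detect_nesting()], [pairs_for_family()], [catalog_pairs()]
#' @export
find_dispersed_repeats <- function(genome, min_len = 50L, min_identity = 1.0) {
  stopifnot(inherits(genome, "circular_sequence"))
  min_len <- as.integer(min_len)
  if (min_len < 20L) stop("min_len below 20 bp is refused: seeds that short ",
                          "are not reliable", call. = FALSE)
  n <- genome$length
  if (n < 2L * min_len) stop("genome (", n, " bp) shorter than 2*min_len",
                             call. = FALSE)
  if (min_identity <= 0 || min_identity > 1)
    stop("min_identity must be in (0, 1]", call. = FALSE)
  relaxed <- min_identity < 1
  k <- if (relaxed) 20L else min(min_len, 64L)

  S <- genome$seq
  bS <- charToRaw(S)
  D <- paste0(S, S)
  kmF <- substring(D, 1:n, (1:n) + k - 1L)
  okF <- which(!grepl("N", kmF, fixed = TRUE))

  R <- revcomp(S)
  bR <- charToRaw(R)
  RD <- paste0(R, R)
  kmR <- substring(RD, 1:n, (1:n) + k - 1L)
  okR <- which(!grepl("N", kmR, fixed = TRUE))

  ff <- .seed_pairs_within(okF, kmF)
  fr <- .seed_pairs_between(okF, kmF, okR, kmR)

  hits <- list()
  if (nrow(ff)) {
    runs <- .diag_runs(ff$i, ff$j, if (relaxed) 2L * k else 0L)
    for (r in seq_len(nrow(runs))) {
      m <- .extend_match(bS, bS, runs$i0[r] - 1L, runs$j0[r] - 1L,
                         runs$len[r] + k - 1L, n, relaxed, min_identity)
      if (!is.null(m)) hits[[length(hits) + 1L]] <- c(m, list(class = "DR"))
    }
  }
  if (nrow(fr)) {
    runs <- .diag_runs(fr$i, fr$j, if (relaxed) 2L * k else 0L)
    for (r in seq_len(nrow(runs))) {
      m <- .extend_match(bS, bR, runs$i0[r] - 1L, runs$j0[r] - 1L,
                         runs$len[r] + k - 1L, n, relaxed, min_identity)
      if (!is.null(m)) hits[[length(hits) + 1L]] <- c(m, list(class = "IR"))
    }
  }

  pairs <- .normalize_hits(hits, n, min_len)
  .assemble_catalog(genome, pairs, n)
}

# all (i < j) position pairs sharing a k-mer
.seed_pairs_within <- function(pos, km) {
  grp <- split(pos, km[pos])
  grp <- grp[lengths(grp) >= 2L]
  if (!length(grp)) return(data.frame(i = integer(), j = integer()))
  npair <- sum(lengths(grp) * (lengths(grp) - 1) / 2)
  if (npair > 5e6) stop("genome too repetitive / low-complexity: ",
                        npair, " seed pairs", call. = FALSE)
  il <- vector("list", length(grp)); jl <- vector("list", length(grp))
  for (g in seq_along(grp)) {
    p <- grp[[g]]
    if (length(p) == 2L) { il[[g]] <- p[1L]; jl[[g]] <- p[2L] }
    else {
      cb <- utils::combn(p, 2L)
      il[[g]] <- cb[1L, ]; jl[[g]] <- cb[2L, ]
    }
  }
  data.frame(i = unlist(il, use.names = FALSE),
             j = unlist(jl, use.names = FALSE))
}

# all (i in A, j in B) cross pairs sharing a k-mer
.seed_pairs_between <- function(posA, kmA, posB, kmB) {
  grpA <- split(posA, kmA[posA])
  grpB <- split(posB, kmB[posB])
  common <- intersect(names(grpA), names(grpB))
  if (!length(common)) return(data.frame(i = integer(), j = integer()))
  grpA <- grpA[common]; grpB <- grpB[common]
  npair <- sum(lengths(grpA) * lengths(grpB))
  if (npair > 5e6) stop("genome too repetitive / low-complexity: ",
                        npair, " seed pairs", call. = FALSE)
  il <- vector("list", length(common)); jl <- vector("list", length(common))
  for (g in seq_along(common)) {
    a <- grpA[[g]]; b <- grpB[[g]]
    il[[g]] <- rep(a, each = length(b)); jl[[g]] <- rep(b, length(a))
  }
  data.frame(i = unlist(il, use.names = FALSE),
             j = unlist(jl, use.names = FALSE))
}

# Collapse seed pairs on one diagonal into runs of consecutive seeds.
# gap > 0 additionally merges runs on the same diagonal separated by at
# most `gap` bases (used in relaxed-identity mode, where mismatches
# break seed runs).
.diag_runs <- function(i, j, gap = 0L) {
  d <- j - i
  o <- order(d, i)
  i <- i[o]; d <- d[o]
  step <- diff(i)
  brk <- c(TRUE, diff(d) != 0L | step < 1L | step > (1L + gap))
  id <- cumsum(brk)
  i0 <- as.integer(tapply(i, id, min))
  iN <- as.integer(tapply(i, id, max))
  data.frame(i0 = i0, j0 = i0 + as.integer(tapply(d, id, min)),
             len = iN - i0 + 1L)
}

# Maximal extension of a candidate match. a0/b0 are 0-based starts into
# byte sequences bA/bB (each length n, circular); L is the seeded match
# length in bases. Returns list(a0, b0, len, ident) or NULL.
.extend_match <- function(bA, bB, a0, b0, L, n, relaxed, min_identity) {
  bNv <- as.raw(78L) # 'N'
  mism <- 0L
  if (relaxed) { # seeded region may itself contain mismatches
    av <- bA[((a0 + 0:(L - 1L)) %% n) + 1L]
    bv <- bB[((b0 + 0:(L - 1L)) %% n) + 1L]
    mism <- sum(av != bv | av == bNv)
  }
  max_run_mm <- if (relaxed) 10L else 0L
  ext_side <- function(dir) { # dir = -1 left, +1 right
    t <- 0L; add_mm <- 0L; run_mm <- 0L
    best_t <- 0L; best_mm <- 0L
    while (L + t < n) {
      t <- t + 1L
      pa <- if (dir < 0) a0 - t else a0 + L - 1L + t
      pb <- if (dir < 0) b0 - t else b0 + L - 1L + t
      ca <- bA[(pa %% n) + 1L]; cb <- bB[(pb %% n) + 1L]
      if ((ca == cb) && ca != bNv) {
        run_mm <- 0L
        # accept the extension up to t if identity still holds there
        if ((L + t - (mism + add_mm)) / (L + t) >= min_identity) {
          best_t <- t; best_mm <- add_mm
        } else break
      } else {
        if (!relaxed) break
        run_mm <- run_mm + 1L
        add_mm <- add_mm + 1L
        if (run_mm > max_run_mm) break
      }
    }
    list(t = best_t, mm = best_mm)
  }
  lext <- ext_side(-1L)
  mism <- mism + lext$mm
  a0 <- a0 - lext$t; b0 <- b0 - lext$t; L <- L + lext$t
  rext <- ext_side(1L)
  mism <- mism + rext$mm
  L <- L + rext$t
  ident <- (L - mism) / L
  if (ident < min_identity) return(NULL)
  list(a0 = ((a0 %% n) + n) %% n, b0 = ((b0 %% n) + n) %% n,
       len = L, ident = ident)
}

# Map hits to genome-coordinate copy pairs, drop short/overlapping/
# duplicate hits. Each pair: starts s1, s2 in [0, n), length len,
# class DR/IR.
.normalize_hits <- function(hits, n, min_len) {
  out <- list()
  seen <- new.env(parent = emptyenv())
  for (h in hits) {
    if (h$len < min_len || h$len >= n) next
    s1 <- h$a0
    s2 <- if (h$class == "DR") h$b0 else ((n - h$b0 - h$len) %% n + n) %% n
    # circular overlap of the two copies => tandem-like, out of scope
    if (((s2 - s1) %% n) < h$len || ((s1 - s2) %% n) < h$len) next
    key <- paste(min(s1, s2), max(s1, s2), h$len, h$class, sep = ":")
    if (!is.null(seen[[key]])) next
    assign(key, TRUE, envir = seen)
    out[[length(out) + 1L]] <- list(s1 = s1, s2 = s2, len = h$len,
                                    class = h$class, ident = h$ident)
  }
  out
}

# Union-find copies into families, assign strands by BFS from the
# positionally first copy of each family, order and label everything.
.assemble_catalog <- function(genome, pairs, n) {
  copies <- unique(do.call(rbind, c(list(
    data.frame(start0 = integer(), len = integer())),
    lapply(pairs, function(p)
      data.frame(start0 = c(p$s1, p$s2), len = p$len)))))
  fams <- list()
  if (nrow(copies)) {
    key <- paste(copies$start0, copies$len, sep = ":")
    idx <- seq_len(nrow(copies)); names(idx) <- key
    parent <- idx
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    edges <- lapply(pairs, function(p) {
      c(idx[[paste(p$s1, p$len, sep = ":")]],
        idx[[paste(p$s2, p$len, sep = ":")]])
    })
    for (e in edges) {
      ra <- find(e[1L]); rb <- find(e[2L])
      if (ra != rb) parent[rb] <- ra
    }
    root <- vapply(idx, find, integer(1))
    comp <- split(seq_len(nrow(copies)), root)
    pair_class <- vapply(pairs, function(p) p$class, character(1))

    for (cp in comp) {
      sub <- copies[cp, , drop = FALSE]
      o <- order(sub$start0)
      sub <- sub[o, , drop = FALSE]
      cp <- cp[o]
      # relative-orientation graph -> absolute strands, first copy "+"
      strand <- rep(NA_character_, length(cp))
      strand[1L] <- "+"
      repeat {
        changed <- FALSE
        for (ei in seq_along(edges)) {
          e <- edges[[ei]]
          ia <- match(e[1L], cp); ib <- match(e[2L], cp)
          if (is.na(ia) || is.na(ib)) next
          same <- pair_class[ei] == "DR"
          for (pr in list(c(ia, ib), c(ib, ia))) {
            if (!is.na(strand[pr[1L]]) && is.na(strand[pr[2L]])) {
              s <- strand[pr[1L]]
              strand[pr[2L]] <- if (same) s else if (s == "+") "-" else "+"
              changed <- TRUE
            }
          }
        }
        if (!changed) break
      }
      strand[is.na(strand)] <- "+"
      len <- max(sub$len)
      first <- which.max(sub$len == len)
      seq_a <- circ_extract(genome, sub$start0[first],
                            sub$start0[first] + len, strand[first])
      fams[[length(fams) + 1L]] <- list(
        length = len,
        seq = seq_a,
        copies = data.frame(
          label = letters[seq_along(cp)],
          start0 = sub$start0,
          end0 = sub$start0 + sub$len,
          strand = strand,
          stringsAsFactors = FALSE))
    }
    o <- order(-vapply(fams, `[[`, integer(1), "length"),
               vapply(fams, function(f) f$copies$start0[1L], integer(1)))
    fams <- fams[o]
    for (i in seq_along(fams)) fams[[i]]$family_id <- i
  }
  structure(list(genome_id = genome$id, genome_length = n,
                 families = fams),
            class = "repeat_catalog")
}

#' @export
print.repeat_catalog <- function(x, ...) {
  cat(sprintf("<repeat_catalog> %s (%s bp): %d dispersed repeat famil%s\n",
              x$genome_id, format(x$genome_length, big.mark = ","),
              length(x$families),
              if (length(x$families) == 1L) "y" else "ies"))
  for (f in x$families) {
    cat(sprintf("  repeat-%d  %5d bp  copies: %s\n", f$family_id, f$length,
                paste(sprintf("%s:%s%s", f$copies$label,
                              format(f$copies$start0 + 1L, big.mark = ","),
                              f$copies$strand), collapse = "  ")))
  }
  invisible(x)
}

#' Flatten a repeat catalog to a copy table
#'
#' @param x a `repeat_catalog`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with 1-based inclusive `start`/`end` report
#'   coordinates (`end` may exceed the genome length for origin-crossing
#'   copies).
#' @export
as.data.frame.repeat_catalog <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  rows <- lapply(x$families, function(f)
    data.frame(family_id = f$family_id,
               copy_label = f$copies$label,
               start = f$copies$start0 + 1L,
               end = f$copies$end0,
               strand = f$copies$strand,
               length = f$length,
               stringsAsFactors = FALSE))
  do.call(rbind, c(list(data.frame()), rows))
}

#' Detect nesting relations between repeat copies
#'
#' Reports every containment of a copy of one family strictly inside a
#' copy of a longer family, with the inner segment's 1-based inclusive
#' span within the outer copy (measured along the outer copy's own
#' orientation).
#'
#' @param catalog a `repeat_catalog`.
#' @return data.frame with columns `inner_family`, `inner_copy`,
#'   `outer_family`, `outer_copy`, `offset_start`, `offset_end`,
#'   `inner_length`.
#' @export
detect_nesting <- function(catalog) {
  stopifnot(inherits(catalog, "repeat_catalog"))
  n <- catalog$genome_length
  out <- list()
  for (fi in catalog$families) for (fo in catalog$families) {
    if (fi$length >= fo$length) next
    for (ci in seq_len(nrow(fi$copies))) for (co in seq_len(nrow(fo$copies))) {
      xs <- fi$copies$start0[ci]; xl <- fi$copies$end0[ci] - xs
      ys <- fo$copies$start0[co]; ye <- fo$copies$end0[co]
      s <- NA_integer_
      for (cand in c(xs, xs + n)) {
        if (cand >= ys && cand + xl <= ye) { s <- cand; break }
      }
      if (is.na(s)) next
      off0 <- if (fo$copies$strand[co] == "+") s - ys else ye - (s + xl)
      out[[length(out) + 1L]] <- data.frame(
        inner_family = fi$family_id, inner_copy = fi$copies$label[ci],
        outer_family = fo$family_id, outer_copy = fo$copies$label[co],
        offset_start = off0 + 1L, offset_end = off0 + xl,
        inner_length = xl, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(list(data.frame()), out))
}

#' Enumerate the copy pairs of a repeat family
#'
#' For families with three or more copies, a pair is flagged *shadowed*
#' when both of its copies are nested inside copies of one longer
#' family: junction evidence for such a pair is indistinguishable from
#' the outer family's, so downstream read-support reporting skips it
#' (e.g. a nested family lists a_c and b_c but not a_b).
#'
#' @param catalog a `repeat_catalog`.
#' @param family_id family to enumerate (default: all families).
#' @return data.frame with columns `family_id`, `copy1`, `copy2`,
#'   `pair_name` (e.g. `"Repeat-5a_c"`), `pair_class` (`DR`/`IR`),
#'   `length`, `shadowed`.
#' @export
pairs_for_family <- function(catalog, family_id = NULL) {
  stopifnot(inherits(catalog, "repeat_catalog"))
  nest <- detect_nesting(catalog)
  fams <- catalog$families
  if (!is.null(family_id)) {
    fams <- fams[vapply(fams, `[[`, integer(1), "family_id") %in% family_id]
  }
  out <- list()
  for (f in fams) {
    nc <- nrow(f$copies)
    if (nc < 2L) next
    cb <- utils::combn(nc, 2L)
    for (p in seq_len(ncol(cb))) {
      i <- cb[1L, p]; j <- cb[2L, p]
      cls <- if (f$copies$strand[i] == f$copies$strand[j]) "DR" else "IR"
      shadowed <- FALSE
      if (nrow(nest)) {
        ni <- nest[nest$inner_family == f$family_id &
                     nest$inner_copy == f$copies$label[i], "outer_family"]
        nj <- nest[nest$inner_family == f$family_id &
                     nest$inner_copy == f$copies$label[j], "outer_family"]
        shadowed <- length(intersect(ni, nj)) > 0L
      }
      out[[length(out) + 1L]] <- data.frame(
        family_id = f$family_id,
        copy1 = f$copies$label[i], copy2 = f$copies$label[j],
        pair_name = sprintf("Repeat-%d%s_%s", f$family_id,
                            f$copies$label[i], f$copies$label[j]),
        pair_class = cls, length = f$length, shadowed = shadowed,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(list(data.frame()), out))
}

#' All repeat pairs of a catalog
#'
#' Convenience wrapper over [pairs_for_family()] for every family.
#'
#' @param catalog a `repeat_catalog`.
#' @param drop_shadowed drop pairs flagged as shadowed.
#' @return data.frame as in [pairs_for_family()].
#' @export
catalog_pairs <- function(catalog, drop_shadowed = FALSE) {
  p <- pairs_for_family(catalog)
  if (drop_shadowed && nrow(p)) p <- p[!p$shadowed, , drop = FALSE]
  p
}

#' Write a repeat catalog and its nesting relations to TSV
#'
#' @param catalog a `repeat_catalog`.
#' @param path catalog TSV path.
#' @param nesting_path optional nesting-relations TSV path.
#' @export
write_catalog_tsv <- function(catalog, path, nesting_path = NULL) {
  write_tsv_report(as.data.frame(catalog), path,
                   meta = c(paste0("genome=", catalog$genome_id),
                            paste0("genome_length=", catalog$genome_length),
                            "coordinates=1-based inclusive"))
  if (!is.null(nesting_path)) {
    write_tsv_report(detect_nesting(catalog), nesting_path,
                     meta = "offsets are 1-based inclusive within the outer copy")
  }
  invisible(path)
}

# Resolve a pair row (from pairs_for_family) to copy intervals on the
# catalog's genome. Returns list(copy1=list(start0,end0,strand), copy2=...,
# len, class, seq).
.resolve_pair <- function(catalog, pair_row) {
  f <- catalog$families[[pair_row$family_id]]
  stopifnot(f$family_id == pair_row$family_id)
  g <- function(lab) {
    i <- match(lab, f$copies$label)
    list(start0 = f$copies$start0[i], end0 = f$copies$end0[i],
         strand = f$copies$strand[i])
  }
  list(copy1 = g(pair_row$copy1), copy2 = g(pair_row$copy2),
       len = f$length, class = pair_row$pair_class, seq = f$seq,
       name = pair_row$pair_name)
}
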