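# Independent brute-force oracles. These deliberately use different
# algorithms from the package: canonical forms by full rotation
# enumeration, maximal repeats by run-length scans over every diagonal
# and anti-diagonal of the full self-comparison (no seeding, chaining
# or extension).

oracle_canonical <- function(s) {
  n <- nchar(s)
  d <- paste0(s, s)
  r <- revcomp(s)
  dr <- paste0(r, r)
  min(c(substring(d, 1:n, 1:n + n - 1L), substring(dr, 1:n, 1:n + n - 1L)))
}

# circular TRUE-run extraction: list of (start0, len), wrap-merged
.oracle_runs <- function(v) {
  n <- length(v)
  if (all(v)) return(list()) # fully periodic, degenerate
  if (!any(v)) return(list())
  r <- rle(v)
  starts <- cumsum(c(0L, utils::head(r$lengths, -1L)))
  runs <- Map(function(s, l) list(start0 = s, len = l),
              starts[r$values], r$lengths[r$values])
  if (r$values[1L] && r$values[length(r$values)]) { # merge across origin
    first <- runs[[1L]]
    last <- runs[[length(runs)]]
    runs[[length(runs)]] <- list(start0 = last$start0,
                                 len = last$len + first$len)
    runs <- runs[-1L]
  }
  runs
}

# all maximal repeated pairs (DR and IR) on a circular sequence, as a
# de-duplicated list of (s1, s2, len, class)
oracle_maximal_pairs <- function(seq, min_len) {
  n <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "X")
  out <- list()
  seen <- character()
  emit <- function(s1, s2, len, class) {
    if (len < min_len || len >= n) return()
    if (((s2 - s1) %% n) < len || ((s1 - s2) %% n) < len) return()
    key <- paste(min(s1, s2), max(s1, s2), len, class, sep = ":")
    if (key %in% seen) return()
    seen <<- c(seen, key)
    out[[length(out) + 1L]] <<- list(s1 = s1, s2 = s2, len = len,
                                     class = class)
  }
  for (d in 1:(n - 1L)) {
    v <- ch == ch[((seq_len(n) - 1L + d) %% n) + 1L] & ch != "N"
    for (r in .oracle_runs(v)) {
      emit(r$start0, (r$start0 + d) %% n, r$len, "DR")
    }
  }
  for (m in 0:(n - 1L)) {
    v <- ch == comp[ch[((m - (seq_len(n) - 1L)) %% n) + 1L]] & ch != "N"
    for (r in .oracle_runs(v)) {
      s2 <- (m - (r$start0 + r$len - 1L)) %% n
      emit(r$start0, s2, r$len, "IR")
    }
  }
  out
}

# assemble oracle pairs into a family table shaped like
# as.data.frame(repeat_catalog): same naming/ordering conventions,
# independent implementation
oracle_catalog_df <- function(seq, min_len) {
  n <- nchar(seq)
  prs <- oracle_maximal_pairs(seq, min_len)
  if (!length(prs)) {
    return(data.frame())
  }
  copies <- unique(do.call(rbind, lapply(prs, function(p)
    data.frame(start0 = c(p$s1, p$s2), len = p$len))))
  key <- paste(copies$start0, copies$len)
  grp <- as.list(seq_len(nrow(copies)))       # singleton groups
  gid <- seq_len(nrow(copies))                # group id per copy
  for (p in prs) {
    i <- gid[match(paste(p$s1, p$len), key)]
    j <- gid[match(paste(p$s2, p$len), key)]
    if (i != j) gid[gid == j] <- i
  }
  fams <- list()
  for (g in unique(gid)) {
    sub <- copies[gid == g, , drop = FALSE]
    sub <- sub[order(sub$start0), , drop = FALSE]
    # strands by propagation over the pair relations
    strand <- rep(NA_character_, nrow(sub))
    strand[1L] <- "+"
    skey <- paste(sub$start0, sub$len)
    repeat {
      moved <- FALSE
      for (p in prs) {
        a <- match(paste(p$s1, p$len), skey)
        b <- match(paste(p$s2, p$len), skey)
        if (is.na(a) || is.na(b)) next
        for (pr in list(c(a, b), c(b, a))) {
          if (!is.na(strand[pr[1L]]) && is.na(strand[pr[2L]])) {
            strand[pr[2L]] <- if (p$class == "DR") strand[pr[1L]]
              else c("+" = "-", "-" = "+")[[strand[pr[1L]]]]
            moved <- TRUE
          }
        }
      }
      if (!moved) break
    }
    fams[[length(fams) + 1L]] <- data.frame(
      copy_label = letters[seq_len(nrow(sub))],
      start = sub$start0 + 1L, end = sub$start0 + sub$len,
      strand = strand, length = max(sub$len), stringsAsFactors = FALSE)
  }
  o <- order(-vapply(fams, function(f) f$length[1L], integer(1)),
             vapply(fams, function(f) f$start[1L], integer(1)))
  fams <- fams[o]
  rows <- lapply(seq_along(fams), function(i)
    cbind(data.frame(family_id = i), fams[[i]]))
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df[, c("family_id", "copy_label", "start", "end", "strand", "length")]
}

# random circular DNA string
random_circle <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# toy circle with planted segments at fixed layout: returns list with
# genome and the planted pieces (P, R1, X, R2, Q concatenated)
toy_with_pair <- function(seg_lens, repeat_len, ir = FALSE) {
  P <- random_circle(seg_lens[1L])
  R <- random_circle(repeat_len)
  X <- random_circle(seg_lens[2L])
  Q <- random_circle(seg_lens[3L])
  R2 <- if (ir) revcomp(R) else R
  g <- circular_sequence(paste0(P, R, X, R2, Q), id = "toy")
  list(genome = g, P = P, R = R, X = X, Q = Q,
       copy1 = list(start0 = nchar(P), end0 = nchar(P) + repeat_len,
                    strand = "+"),
       copy2 = list(start0 = nchar(P) + repeat_len + nchar(X),
                    end0 = nchar(P) + repeat_len + nchar(X) + repeat_len,
                    strand = if (ir) "-" else "+"))
}
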