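# Homologous-recombination algebra on circular molecules.
#
# Products are defined at repeat-copy granularity: because the copies of
# an exact repeat pair are identical, every crossover point inside the
# repeat yields the same product sequence, so only the copy intervals
# matter. Inversion acts on the arc strictly between the two copies (the
# arc not containing the origin when neither copy wraps); equivalence of
# the complementary-arc choice is a whole-molecule reverse-complement,
# which canonical_form() identifies.

# Rotate a circular sequence string so that 0-based position p becomes
# the origin.
.rotate_to <- function(seq, p) {
  n <- nchar(seq)
  p <- p %% n
  if (p == 0L) return(seq)
  paste0(substr(seq, p + 1L, n), substr(seq, 1L, p))
}

# Normalize a pair of copy intervals on one circle: rotate the circle so
# copy1 starts at the origin; returns list(seq, L1, s2, L2, strand_rel)
# with copy2 now at [s2, s2 + L2) and nothing wrapping.
.orient_pair <- function(circle, copy1, copy2) {
  stopifnot(inherits(circle, "circular_sequence"))
  n <- circle$length
  s <- .rotate_to(circle$seq, copy1$start0)
  L1 <- copy1$end0 - copy1$start0
  L2 <- copy2$end0 - copy2$start0
  s2 <- ((copy2$start0 - copy1$start0) %% n)
  if (s2 < L1 || s2 + L2 > n) {
    stop("repeat copies overlap on the circle; recombination product ",
         "undefined", call. = FALSE)
  }
  list(seq = s, n = n, L1 = L1, s2 = s2, L2 = L2)
}

#' Invert the segment between an inverted-repeat pair (flip-flop)
#'
#' Models IR-mediated intramolecular recombination: the arc strictly
#' between the two repeat copies is reverse-complemented while both
#' copies stay intact; the molecule length is unchanged. Applying the
#' operation twice returns the original circle (up to rotation).
#'
#' @param circle a [circular_sequence()].
#' @param copy1,copy2 lists with `start0`, `end0`, `strand` (0-based
#'   half-open genome intervals of the two copies), e.g. from
#'   [find_dispersed_repeats()] via `.resolve_pair()` or built by hand.
#' @param id id for the product molecule.
#' @return a [circular_sequence()] of the same length.
#' @export
invert_at_ir <- function(circle, copy1, copy2, id = paste0(circle$id, "_inv")) {
  if (copy1$strand == copy2$strand) {
    stop("invert_at_ir requires an IR pair (copies on opposite strands)",
         call. = FALSE)
  }
  o <- .orient_pair(circle, copy1, copy2)
  mid <- substr(o$seq, o$L1 + 1L, o$s2)
  out <- paste0(substr(o$seq, 1L, o$L1),
                if (nchar(mid)) revcomp(mid) else "",
                substr(o$seq, o$s2 + 1L, o$n))
  # back to the caller's origin so both copies keep their coordinates
  out <- .rotate_to(out, (o$n - (copy1$start0 %% o$n)) %% o$n)
  circular_sequence(out, id = id)
}

#' Split one circle into two at a direct-repeat pair (fission)
#'
#' Models DR-mediated intramolecular recombination producing a
#' multipartite (two-circle) genome: subcircle 1 carries copy 1 plus the
#' arc up to copy 2; subcircle 2 carries copy 2 plus the remaining arc.
#' Each subcircle retains exactly one full repeat copy and the lengths
#' sum to the parent length.
#'
#' @inheritParams invert_at_ir
#' @param ids ids for the two product molecules.
#' @return list of two [circular_sequence()].
#' @export
split_at_dr <- function(circle, copy1, copy2,
                        ids = paste0(circle$id, c("_f1", "_f2"))) {
  if (copy1$strand != copy2$strand) {
    stop("split_at_dr requires a DR pair (copies on the same strand)",
         call. = FALSE)
  }
  o <- .orient_pair(circle, copy1, copy2)
  list(circular_sequence(substr(o$seq, 1L, o$s2), id = ids[1L]),
       circular_sequence(substr(o$seq, o$s2 + 1L, o$n), id = ids[2L]))
}

# Locate exact occurrences of a repeat sequence (given in + orientation)
# on a circle; returns data.frame(start0, end0, strand), de-duplicated
# and sorted by position.
locate_repeat <- function(circle, repeat_seq) {
  n <- circle$length
  L <- nchar(repeat_seq)
  hits <- list()
  scan <- function(pat, strand) {
    if (L > n) return()
    dbl <- paste0(circle$seq, substr(circle$seq, 1L, min(L - 1L, n)))
    m <- gregexpr(pat, dbl, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) return()
    for (p in as.integer(m)) {
      s0 <- (p - 1L) %% n
      hits[[length(hits) + 1L]] <<- data.frame(start0 = s0, end0 = s0 + L,
                                               strand = strand)
    }
  }
  scan(repeat_seq, "+")
  rc <- revcomp(repeat_seq)
  if (rc != repeat_seq) scan(rc, "-")
  if (!length(hits)) {
    return(data.frame(start0 = integer(), end0 = integer(),
                      strand = character()))
  }
  df <- unique(do.call(rbind, hits))
  df[order(df$start0), , drop = FALSE]
}

#' Fuse two circles at a shared repeat (the reverse of fission)
#'
#' Each input circle must carry exactly one copy of the repeat; the
#' circles are rotated (and reverse-complemented if the copy is on the
#' minus strand) so the repeat reads forward from the origin, then
#' concatenated. `split_at_dr()` of the product restores the inputs up
#' to canonical form.
#'
#' @param circle_a,circle_b [circular_sequence()] objects.
#' @param repeat_seq the shared repeat sequence (+ orientation).
#' @param id id for the fused molecule.
#' @return a [circular_sequence()] of length
#'   `length(circle_a) + length(circle_b)`.
#' @export
fuse <- function(circle_a, circle_b, repeat_seq,
                 id = paste0(circle_a$id, "+", circle_b$id)) {
  norm <- function(circle) {
    hit <- locate_repeat(circle, repeat_seq)
    if (nrow(hit) == 0L) {
      stop("repeat not found on circle '", circle$id, "'", call. = FALSE)
    }
    if (nrow(hit) > 1L) {
      stop("circle '", circle$id, "' carries ", nrow(hit),
           " copies of the repeat; fusion requires exactly one",
           call. = FALSE)
    }
    s <- if (hit$strand[1L] == "-") revcomp(circle$seq) else circle$seq
    h2 <- locate_repeat(circular_sequence(s, id = circle$id), repeat_seq)
    h2 <- h2[h2$strand == "+", , drop = FALSE]
    .rotate_to(s, h2$start0[1L])
  }
  circular_sequence(paste0(norm(circle_a), norm(circle_b)), id = id)
}

#' Enumerate isomeric genome forms reachable by recombination
#'
#' Breadth-first closure over recombination events (IR inversion, DR
#' fission, fusion of two circles sharing a repeat) at the active repeat
#' pairs, starting from the master circle, up to `max_events` events per
#' form. Forms are de-duplicated by the multiset of canonical forms of
#' their circles, so event orderings that commute collapse to one form.
#'
#' Naming follows the master-circle convention: the founding assembly is
#' MC1; inversion at repeat-1 gives MC2; each further event at repeat-k
#' appends `^k` (MC1^2, MC2^2), with copy letters appended for pairs of
#' families with three or more copies (MC2^5ac).
#'
#' @param master a [circular_sequence()] (the MC1 assembly).
#' @param catalog its `repeat_catalog` from [find_dispersed_repeats()].
#' @param active_pairs data.frame of pairs to recombine at (rows as
#'   returned by [catalog_pairs()]); defaults to all unshadowed pairs.
#' @param max_events maximum recombination events per form.
#' @param max_forms cap on the closure size (error if exceeded).
#' @return list of `genome_form` objects, each with `name`, `circles`
#'   (list of `circular_sequence`) and `provenance` (character vector of
#'   event descriptions).
#' @export
enumerate_forms <- function(master, catalog, active_pairs = NULL,
                            max_events = 2L, max_forms = 200L) {
  stopifnot(inherits(master, "circular_sequence"))
  if (is.null(active_pairs)) active_pairs <- catalog_pairs(catalog, drop_shadowed = TRUE)
  if (max_events < 0L) stop("max_events must be >= 0", call. = FALSE)

  fam_ids <- vapply(catalog$families, `[[`, integer(1), "family_id")
  fam_copies <- vapply(catalog$families, function(f) nrow(f$copies), integer(1))

  base <- .new_form("MC1", list(master), character())
  seen_keys <- .form_key(lapply(base$circles, `[[`, "seq"))
  out <- list(base)
  frontier <- list(base)
  depth <- 0L
  while (depth < max_events && length(frontier)) {
    depth <- depth + 1L
    nxt <- list()
    for (form in frontier) {
      for (pi in seq_len(nrow(active_pairs))) {
        pr <- active_pairs[pi, , drop = FALSE]
        fam <- catalog$families[[match(pr$family_id, fam_ids)]]
        lettered <- fam_copies[match(pr$family_id, fam_ids)] > 2L
        prods <- .apply_pair_events(form, fam$seq)
        for (prod in prods) {
          key <- .form_key(lapply(prod$circles, `[[`, "seq"))
          if (key %in% seen_keys) next
          seen_keys <- c(seen_keys, key)
          ev <- sprintf("%s@%s", prod$kind, pr$pair_name)
          newf <- .new_form(
            .derive_name(c(form$events, list(list(
              family = pr$family_id, kind = prod$kind,
              letters = if (lettered) paste0(pr$copy1, pr$copy2) else ""))),
              fam_ids),
            prod$circles, c(form$provenance, ev),
            events = c(form$events, list(list(
              family = pr$family_id, kind = prod$kind,
              letters = if (lettered) paste0(pr$copy1, pr$copy2) else ""))))
          out[[length(out) + 1L]] <- newf
          nxt[[length(nxt) + 1L]] <- newf
          if (length(out) > max_forms) {
            stop("form closure exceeded max_forms = ", max_forms,
                 call. = FALSE)
          }
        }
      }
    }
    frontier <- nxt
  }
  total0 <- master$length
  for (f in out) {
    tot <- sum(vapply(f$circles, `[[`, integer(1), "length"))
    stopifnot(tot == total0) # recombination conserves total length
  }
  out
}

.new_form <- function(name, circles, provenance, events = list()) {
  for (i in seq_along(circles)) {
    circles[[i]]$id <- sprintf("%s_c%d", name, i)
  }
  structure(list(name = name, circles = circles, provenance = provenance,
                 events = events),
            class = "genome_form")
}

# All single recombination events available to `form` at one repeat
# family (sequence fam_seq, + orientation). Returns list of
# list(kind, circles).
.apply_pair_events <- function(form, fam_seq) {
  prods <- list()
  hits_per_circle <- lapply(form$circles, locate_repeat, repeat_seq = fam_seq)
  # intramolecular events
  for (ci in seq_along(form$circles)) {
    h <- hits_per_circle[[ci]]
    if (nrow(h) < 2L) next
    cb <- utils::combn(nrow(h), 2L)
    for (p in seq_len(ncol(cb))) {
      c1 <- as.list(h[cb[1L, p], ]); c2 <- as.list(h[cb[2L, p], ])
      rest <- form$circles[-ci]
      if (c1$strand != c2$strand) {
        inv <- invert_at_ir(form$circles[[ci]], c1, c2)
        prods[[length(prods) + 1L]] <-
          list(kind = "inversion", circles = c(rest, list(inv)))
      } else {
        sp <- split_at_dr(form$circles[[ci]], c1, c2)
        prods[[length(prods) + 1L]] <-
          list(kind = "fission", circles = c(rest, sp))
      }
    }
  }
  # intermolecular fusion: two circles each with exactly one copy
  one <- which(vapply(hits_per_circle, nrow, integer(1)) == 1L)
  if (length(one) >= 2L) {
    cb <- utils::combn(one, 2L)
    for (p in seq_len(ncol(cb))) {
      a <- cb[1L, p]; b <- cb[2L, p]
      fu <- fuse(form$circles[[a]], form$circles[[b]], fam_seq)
      prods[[length(prods) + 1L]] <-
        list(kind = "fusion", circles = c(form$circles[-c(a, b)], list(fu)))
    }
  }
  prods
}

# MC naming rule from the event list.
.derive_name <- function(events, fam_ids) {
  n_r1_inv <- sum(vapply(events, function(e)
    e$family == 1L && e$kind == "inversion", logical(1)))
  base <- if (n_r1_inv %% 2L == 1L) "MC2" else "MC1"
  sup <- character()
  for (e in events) {
    if (e$family == 1L && e$kind == "inversion") next
    sup <- c(sup, paste0("^", e$family, e$letters))
  }
  paste0(base, paste(sup, collapse = ""))
}

#' @export
print.genome_form <- function(x, ...) {
  lens <- vapply(x$circles, `[[`, integer(1), "length")
  cat(sprintf("<genome_form> %s: %d circle%s (%s bp)%s\n", x$name,
              length(lens), if (length(lens) > 1L) "s" else "",
              paste(format(lens, big.mark = ","), collapse = " + "),
              if (length(x$provenance))
                paste0("  [", paste(x$provenance, collapse = " -> "), "]")
              else ""))
  invisible(x)
}

#' Write enumerated genome forms to FASTA plus a TSV manifest
#'
#' @param forms list of `genome_form` (from [enumerate_forms()]).
#' @param fasta_path output FASTA (record ids `<form>_c1`, `<form>_c2`).
#' @param manifest_path output TSV (form, n_circles, lengths, provenance).
#' @export
write_forms <- function(forms, fasta_path, manifest_path = NULL) {
  seqs <- list()
  for (f in forms) for (circ in f$circles) seqs[[circ$id]] <- circ
  write_fasta(seqs, fasta_path)
  if (!is.null(manifest_path)) {
    man <- do.call(rbind, lapply(forms, function(f)
      data.frame(form = f$name, n_circles = length(f$circles),
                 lengths = paste(vapply(f$circles, `[[`, integer(1), "length"),
                                 collapse = ","),
                 provenance = if (length(f$provenance))
                   paste(f$provenance, collapse = ";") else "founder",
                 stringsAsFactors = FALSE)))
    write_tsv_report(man, manifest_path)
  }
  invisible(fasta_path)
}
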