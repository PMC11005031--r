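# Planted-truth simulator: circular genomes with dispersed repeats
# written into random background, and long-read sets drawn from a
# mixture of isomeric genome forms, with per-read truth labels so every
# downstream stage can be scored against what was planted.

# Run code under a fixed seed without clobbering the caller's RNG state.
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a planted repeat family
#'
#' @param length repeat length in bp.
#' @param positions list of `c(pos, strand)` placements: `pos` is the
#'   0-based genome start, `strand` `"+"` or `"-"`. Two or three
#'   free-standing placements (may be empty for a family that exists
#'   only nested inside another).
#' @param nested_inside optional `list(outer = <index of the outer spec
#'   in the spec list>, offset = <1-based start of this repeat within
#'   the outer repeat's sequence>)`; the inner sequence is written into
#'   the outer family's sequence, so every outer copy carries it.
#' @return a `repeat_spec` list.
#' @export
repeat_spec <- function(length, positions = list(), nested_inside = NULL) {
  stopifnot(length >= 1L)
  for (p in positions) stopifnot(length(p) == 2L, p[[2L]] %in% c("+", "-"))
  if (!is.null(nested_inside)) {
    stopifnot(is.list(nested_inside),
              all(c("outer", "offset") %in% names(nested_inside)))
  }
  structure(list(length = as.integer(length), positions = positions,
                 nested_inside = nested_inside),
            class = "repeat_spec")
}

#' Generate a circular genome with planted dispersed repeats
#'
#' Background bases are i.i.d. (uniform by default; set `gc` to emulate
#' a genome's GC content) and each repeat family's randomly drawn
#' sequence is written in at its specified placements. The returned
#' truth catalog has exactly the structure [find_dispersed_repeats()]
#' must recover: families ordered by descending length, copies lettered
#' by ascending position, strands normalized so copy a is `+`.
#'
#' @param total_len genome length in bp.
#' @param repeat_specs list of [repeat_spec()].
#' @param seed RNG seed (mandatory: generation must be reproducible).
#' @param gc background GC fraction (default 0.5, i.e. uniform).
#' @param id genome id.
#' @return list with `genome` (a [circular_sequence()]) and `truth`
#'   (a `repeat_catalog`).
#' @export
make_genome <- function(total_len, repeat_specs = list(), seed, gc = 0.5,
                        id = "synthetic_mc1") {
  stopifnot(!missing(seed))
  total_len <- as.integer(total_len)
  .with_seed(seed, {
    fam_seqs <- lapply(repeat_specs, function(sp) random_dna(sp$length, gc))
    # embed nested family sequences into their outer family sequence
    for (i in seq_along(repeat_specs)) {
      ni <- repeat_specs[[i]]$nested_inside
      if (is.null(ni)) next
      Li <- repeat_specs[[i]]$length
      Lo <- repeat_specs[[ni$outer]]$length
      if (ni$offset < 1L || ni$offset + Li - 1L > Lo) {
        stop("nested repeat spec ", i, ": offset ", ni$offset, " + length ",
             Li, " exceeds outer length ", Lo, call. = FALSE)
      }
      outer <- fam_seqs[[ni$outer]]
      substr(outer, ni$offset, ni$offset + Li - 1L) <- fam_seqs[[i]]
      fam_seqs[[ni$outer]] <- outer
    }
    # collect free-standing placements and check feasibility
    plc <- list()
    for (i in seq_along(repeat_specs)) {
      sp <- repeat_specs[[i]]
      for (p in sp$positions) {
        s0 <- as.integer(p[[1L]])
        if (s0 < 0L || s0 + sp$length > total_len) {
          stop("placement of spec ", i, " at ", s0,
               " falls outside the genome", call. = FALSE)
        }
        plc[[length(plc) + 1L]] <- list(spec = i, start0 = s0,
                                        end0 = s0 + sp$length,
                                        strand = p[[2L]])
      }
    }
    if (length(plc) > 1L) {
      o <- order(vapply(plc, `[[`, integer(1), "start0"))
      for (j in seq_along(o)[-1L]) {
        a <- plc[[o[j - 1L]]]; b <- plc[[o[j]]]
        if (b$start0 < a$end0) {
          stop("placement conflict: spec ", a$spec, " [", a$start0, ",",
               a$end0, ") overlaps spec ", b$spec, " [", b$start0, ",",
               b$end0, ")", call. = FALSE)
        }
      }
    }
    chars <- strsplit(random_dna(total_len, gc), "", fixed = TRUE)[[1L]]
    for (p in plc) {
      s <- fam_seqs[[p$spec]]
      if (p$strand == "-") s <- revcomp(s)
      chars[(p$start0 + 1L):p$end0] <- strsplit(s, "", fixed = TRUE)[[1L]]
    }

    # per-spec copy tables: free placements plus copies derived from
    # nesting (one per outer placement)
    copies_per_spec <- lapply(seq_along(repeat_specs), function(i) {
      sp <- repeat_specs[[i]]
      copies <- list()
      for (p in plc) {
        if (p$spec == i) {
          copies[[length(copies) + 1L]] <-
            data.frame(start0 = p$start0, end0 = p$end0, strand = p$strand,
                       stringsAsFactors = FALSE)
        }
      }
      ni <- sp$nested_inside
      if (!is.null(ni)) {
        for (p in plc) {
          if (p$spec != ni$outer) next
          Lo <- repeat_specs[[ni$outer]]$length
          if (p$strand == "+") {
            s0 <- p$start0 + ni$offset - 1L
            st <- "+"
          } else {
            s0 <- p$start0 + Lo - (ni$offset - 1L) - sp$length
            st <- "-"
          }
          copies[[length(copies) + 1L]] <-
            data.frame(start0 = s0, end0 = s0 + sp$length, strand = st,
                       stringsAsFactors = FALSE)
        }
      }
      cdf <- do.call(rbind, copies)
      cdf[order(cdf$start0), , drop = FALSE]
    })

    # Boundary hardening: the planted repeat length is the truth, so no
    # copy pair may be extendable by chance-matching neighbor bases.
    # For each family and each oriented side, neighbor bases lying in
    # free background are reassigned until all copies' oriented
    # neighbors differ (bases inside other planted repeats, e.g. around
    # nested copies, are fixed).
    occ <- logical(total_len)
    for (p in plc) occ[(p$start0 + 1L):p$end0] <- TRUE
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    for (cdf in copies_per_spec) {
      if (nrow(cdf) < 2L) next
      for (side in c("up", "down")) {
        pos0 <- integer(nrow(cdf)); val <- character(nrow(cdf))
        for (j in seq_len(nrow(cdf))) {
          plus <- cdf$strand[j] == "+"
          before <- (side == "up") == plus
          pos0[j] <- if (before) (cdf$start0[j] - 1L) %% total_len
                     else cdf$end0[j] %% total_len
          v <- chars[pos0[j] + 1L]
          val[j] <- if (plus) v else comp[[v]]
        }
        for (j in seq_len(nrow(cdf))) {
          if (occ[pos0[j] + 1L]) next
          if (any(val[-j] == val[j])) {
            val[j] <- setdiff(c("A", "C", "G", "T"), val[-j])[1L]
            chars[pos0[j] + 1L] <- if (cdf$strand[j] == "+") val[j]
                                   else comp[[val[j]]]
          }
        }
      }
    }
    genome <- circular_sequence(paste(chars, collapse = ""), id = id)

    truth_fams <- list()
    for (i in seq_along(repeat_specs)) {
      sp <- repeat_specs[[i]]
      cdf <- copies_per_spec[[i]]
      # normalize strands: copy a reads "+"
      if (cdf$strand[1L] == "-") {
        cdf$strand <- ifelse(cdf$strand == "+", "-", "+")
        seq_a <- revcomp(fam_seqs[[i]])
      } else {
        seq_a <- fam_seqs[[i]]
      }
      cdf$label <- letters[seq_len(nrow(cdf))]
      truth_fams[[length(truth_fams) + 1L]] <-
        list(length = sp$length, seq = seq_a,
             copies = cdf[, c("label", "start0", "end0", "strand")])
    }
    o <- order(-vapply(truth_fams, `[[`, integer(1), "length"),
               vapply(truth_fams, function(f) f$copies$start0[1L], integer(1)))
    truth_fams <- truth_fams[o]
    for (i in seq_along(truth_fams)) truth_fams[[i]]$family_id <- i
    truth <- structure(list(genome_id = id, genome_length = total_len,
                            families = truth_fams),
                       class = "repeat_catalog")
    list(genome = genome, truth = truth)
  })
}

#' The package's reference synthetic genome preset
#'
#' A 100-kb circle carrying the repeat geometry the analysis is built
#' around: a large ~9-kb IR pair (family 1), a 1,467-bp DR pair
#' (family 2) with a 188-bp repeat nested at positions 1,173-1,360 of
#' the outer sequence plus a free-standing inverted third copy
#' (family 5), and three smaller pairs of 564, 317 and 161 bp
#' (families 3, 4 and 6; the 161-bp pair is direct, the others
#' inverted).
#'
#' @param seed RNG seed.
#' @param total_len genome length (default 100,000 bp).
#' @param gc background GC fraction.
#' @return list with `genome` and `truth` as in [make_genome()].
#' @export
preset_genome <- function(seed, total_len = 100000L, gc = 0.5) {
  specs <- list(
    repeat_spec(8986, list(list(5000L, "+"), list(20000L, "-"))),
    repeat_spec(1467, list(list(35000L, "+"), list(55000L, "+"))),
    repeat_spec(564, list(list(40000L, "+"), list(62000L, "-"))),
    repeat_spec(317, list(list(44000L, "+"), list(66000L, "-"))),
    repeat_spec(161, list(list(48000L, "+"), list(70000L, "+"))),
    repeat_spec(188, list(list(90000L, "-")),
                nested_inside = list(outer = 2L, offset = 1173L)))
  make_genome(total_len, specs, seed = seed, gc = gc)
}

#' Read-simulation settings
#'
#' Lengths are lognormal around `mean_len` (HiFi-like default: 15 kb,
#' truncated to 1-50 kb; an ONT-like preset would raise `mean_len` and
#' the error rates). Errors are i.i.d. per base; rates above 0.1 are
#' refused.
#'
#' @param n_reads number of reads.
#' @param seed RNG seed (mandatory).
#' @param mean_len mean read length in bp.
#' @param sdlog lognormal sigma (log scale).
#' @param min_len,max_len truncation bounds in bp.
#' @param sub_rate,ins_rate,del_rate per-base error rates in [0, 0.1].
#' @return a `read_sim_spec` list.
#' @export
read_sim_spec <- function(n_reads, seed, mean_len = 15000, sdlog = 0.35,
                          min_len = 1000, max_len = 50000,
                          sub_rate = 0, ins_rate = 0, del_rate = 0) {
  stopifnot(!missing(seed), n_reads >= 1)
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0 | rates > 0.1)) {
    stop("error rates must lie in [0, 0.1]", call. = FALSE)
  }
  structure(list(n_reads = as.integer(n_reads), seed = seed,
                 mean_len = mean_len, sdlog = sdlog,
                 min_len = min_len, max_len = max_len,
                 sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate),
            class = "read_sim_spec")
}

#' Simulate long reads from a mixture of genome forms
#'
#' Each read picks a form by the mixture proportions, a circle within
#' the form proportional to circle length, a uniform start on the
#' circle, a truncated-lognormal length (capped at the circle length), a
#' uniform strand, and then per-base errors. Deterministic given the
#' spec's seed.
#'
#' @param forms list of `genome_form` objects (see [enumerate_forms()]),
#'   or a named list of lists of [circular_sequence()].
#' @param mixture named numeric vector of form proportions (must sum
#'   to 1; every name must match a form).
#' @param sim a [read_sim_spec()].
#' @return list with `reads` (data.frame `id`, `seq`, `length`) and
#'   `truth` (data.frame `id`, `form`, `circle`, `start`, `strand`,
#'   `span`; `start` is 1-based on the source circle).
#' @export
simulate_reads <- function(forms, mixture, sim) {
  stopifnot(inherits(sim, "read_sim_spec"))
  form_names <- vapply(forms, function(f)
    if (inherits(f, "genome_form")) f$name else NA_character_, character(1))
  if (anyNA(form_names)) form_names <- names(forms)
  names(forms) <- form_names
  if (abs(sum(mixture) - 1) > 1e-6) {
    stop("mixture proportions must sum to 1", call. = FALSE)
  }
  if (!all(names(mixture) %in% form_names)) {
    stop("mixture names not all found among forms: ",
         paste(setdiff(names(mixture), form_names), collapse = ", "),
         call. = FALSE)
  }
  .with_seed(sim$seed, {
    n <- sim$n_reads
    meanlog <- log(sim$mean_len) - sim$sdlog^2 / 2
    lens <- round(stats::rlnorm(n, meanlog, sim$sdlog))
    lens <- pmin(pmax(lens, sim$min_len), sim$max_len)
    pick_form <- sample(names(mixture), n, replace = TRUE, prob = mixture)
    ids <- sprintf("read_%05d", seq_len(n))
    seqs <- character(n)
    circle_id <- character(n)
    starts <- integer(n)
    strands <- character(n)
    for (i in seq_len(n)) {
      f <- forms[[pick_form[i]]]
      circles <- if (inherits(f, "genome_form")) f$circles else f
      clens <- vapply(circles, `[[`, integer(1), "length")
      ci <- if (length(circles) == 1L) 1L
        else sample(seq_along(circles), 1L, prob = clens)
      circ <- circles[[ci]]
      L <- min(lens[i], circ$length)
      s0 <- sample.int(circ$length, 1L) - 1L
      strand <- sample(c("+", "-"), 1L)
      raw <- circ_extract(circ, s0, s0 + L, strand)
      seqs[i] <- .apply_read_errors(raw, sim$sub_rate, sim$ins_rate,
                                    sim$del_rate)
      circle_id[i] <- circ$id
      starts[i] <- s0 + 1L
      strands[i] <- strand
    }
    list(reads = data.frame(id = ids, seq = seqs, length = nchar(seqs),
                            stringsAsFactors = FALSE),
         truth = data.frame(id = ids, form = pick_form, circle = circle_id,
                            start = starts, strand = strands,
                            span = pmin(lens, nchar(seqs) + 0L),
                            stringsAsFactors = FALSE))
  })
}

# i.i.d. per-base substitutions, insertions and deletions.
.apply_read_errors <- function(seq, sub, ins, del) {
  if (sub == 0 && ins == 0 && del == 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (del > 0) v <- v[stats::runif(length(v)) >= del]
  if (sub > 0) {
    hit <- which(stats::runif(length(v)) < sub)
    if (length(hit)) {
      v[hit] <- vapply(v[hit], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    }
  }
  if (ins > 0) {
    extra <- stats::runif(length(v)) < ins
    if (any(extra)) {
      counts <- 1L + as.integer(extra)
      out <- character(sum(counts))
      at <- cumsum(counts)
      out[at] <- v
      out[-at] <- sample(c("A", "C", "G", "T"), sum(extra), replace = TRUE)
      v <- out
    }
  }
  paste(v, collapse = "")
}

#' Plant duplex-like chimeric artifacts into a read set
#'
#' Replaces a fraction of reads by `seg + revcomp(seg)` constructs (the
#' two halves reverse complements of each other), the artifact class
#' that [remove_duplex_like()] is designed to strip. Truth flags are
#' recorded in an `is_duplex` column.
#'
#' @param reads data.frame with `id`, `seq` columns.
#' @param fraction fraction of reads to replace, in [0, 0.5].
#' @param seed RNG seed.
#' @return the reads data.frame with modified sequences and an added
#'   logical `is_duplex` column.
#' @export
make_duplex_artifacts <- function(reads, fraction, seed) {
  if (fraction < 0 || fraction > 0.5) {
    stop("fraction must lie in [0, 0.5]", call. = FALSE)
  }
  reads$is_duplex <- FALSE
  n_art <- floor(fraction * nrow(reads))
  if (n_art == 0L) return(reads)
  .with_seed(seed, {
    idx <- sample.int(nrow(reads), n_art)
    for (i in idx) {
      seg <- substr(reads$seq[i], 1L, ceiling(nchar(reads$seq[i]) / 2))
      reads$seq[i] <- paste0(seg, revcomp(seg))
    }
    reads$length <- nchar(reads$seq)
    reads$is_duplex[idx] <- TRUE
    reads
  })
}
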