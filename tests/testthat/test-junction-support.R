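# Junction reference construction, read classification and support rates.

test_that("DR junction references are the definitional flank assemblies", {
  set.seed(41)
  t <- toy_with_pair(c(300L, 350L, 320L), 100L, ir = FALSE)
  fl <- 200L
  js <- build_junctions(t$genome, list(copy1 = t$copy1, copy2 = t$copy2,
                                       len = 100L, class = "DR"),
                        flank_len = fl)
  suffix <- function(s, k) substr(s, nchar(s) - k + 1L, nchar(s))
  expect_identical(js$refs[["ref_a"]],
                   paste0(suffix(t$P, fl), t$R, substr(t$X, 1L, fl)))
  expect_identical(js$refs[["ref_b"]],
                   paste0(suffix(t$X, fl), t$R, substr(t$Q, 1L, fl)))
  expect_identical(js$refs[["alt_ab"]],
                   paste0(suffix(t$P, fl), t$R, substr(t$Q, 1L, fl)))
  expect_identical(js$refs[["alt_ba"]],
                   paste0(suffix(t$X, fl), t$R, substr(t$X, 1L, fl)))
  expect_true(all(nchar(js$refs) == 2L * fl + 100L))
})

test_that("IR junction references reverse-complement copy b's context", {
  set.seed(42)
  t <- toy_with_pair(c(300L, 350L, 320L), 100L, ir = TRUE)
  fl <- 150L
  js <- build_junctions(t$genome, list(copy1 = t$copy1, copy2 = t$copy2,
                                       len = 100L, class = "IR"),
                        flank_len = fl)
  suffix <- function(s, k) substr(s, nchar(s) - k + 1L, nchar(s))
  # copy b presents the repeat in + orientation when read on the minus
  # strand: upstream flank = revcomp of the sequence after the copy
  expect_identical(js$refs[["ref_b"]],
                   paste0(revcomp(substr(t$Q, 1L, fl)), t$R,
                          revcomp(suffix(t$X, fl))))
  expect_identical(js$refs[["alt_ab"]],
                   paste0(suffix(t$P, fl), t$R, revcomp(suffix(t$X, fl))))
  # genuine genome subsequences for the two reference configurations
  expect_identical(js$refs[["ref_a"]],
                   circ_extract(t$genome, t$copy1$start0 - fl,
                                t$copy1$end0 + fl))
  expect_identical(js$refs[["ref_b"]],
                   circ_extract(t$genome, t$copy2$start0 - fl,
                                t$copy2$end0 + fl, "-"))
})

test_that("junctions built on the recombined genome swap ref and alt", {
  pg <- preset_genome(seed = 7)
  g <- pg$genome
  cat_ <- find_dispersed_repeats(g, min_len = 50)
  pairs <- catalog_pairs(cat_)
  for (nm in c("Repeat-1a_b", "Repeat-2a_b")) {
    pr <- circrecomb:::.resolve_pair(cat_, pairs[pairs$pair_name == nm, ])
    js <- build_junctions(g, pr)
    rec <- if (pr$class == "IR") {
      invert_at_ir(g, pr$copy1, pr$copy2)
    } else {
      # fission then refusion is involutive; instead compare against the
      # junctions of each fission subcircle via the read classifier below
      NULL
    }
    if (is.null(rec)) next
    cat2 <- find_dispersed_repeats(rec, min_len = 50)
    pr2 <- circrecomb:::.resolve_pair(
      cat2, catalog_pairs(cat2)[catalog_pairs(cat2)$family_id ==
                                  pairs$family_id[pairs$pair_name == nm], ][1L, ])
    js2 <- build_junctions(rec, pr2)
    expect_setequal(unname(js2$refs[c("ref_a", "ref_b")]),
                    unname(js$refs[c("alt_ab", "alt_ba")]))
    expect_setequal(unname(js2$refs[c("alt_ab", "alt_ba")]),
                    unname(js$refs[c("ref_a", "ref_b")]))
  }
})

test_that("flank geometry is validated", {
  set.seed(43)
  t <- toy_with_pair(c(300L, 100L, 300L), 80L, ir = FALSE)
  pr <- list(copy1 = t$copy1, copy2 = t$copy2, len = 80L, class = "DR")
  warns <- capture_warnings(build_junctions(t$genome, pr, flank_len = 150L))
  expect_true(all(grepl("ambiguous", warns)) && length(warns) >= 1L)
  expect_error(build_junctions(t$genome, pr, flank_len = 300L),
               "contains")
  expect_error(build_junctions(t$genome, pr, flank_len = 600L),
               "too small")
})

test_that("dual-flank overlap rule is boundary-exact", {
  jset <- structure(list(refs = c(ref_a = "", ref_b = "", alt_ab = "",
                                  alt_ba = ""),
                         pair_name = "toy", pair_class = "IR",
                         repeat_len = 500L, flank_len = 3000L),
                    class = "junction_set")
  aln <- function(rs, re) {
    structure(list(read_id = "r", ref = "ref_a", strand = "+",
                   qstart = 1L, qend = re - rs + 1L, rstart = rs,
                   rend = re, score = 10L,
                   aligned_bases = re - rs + 1L),
              class = "read_alignment")
  }
  fl <- 3000L; rl <- 500L
  expect_identical(classify_read(aln(fl - 1800L + 1L, fl + rl + 1800L), jset),
                   "ref_a")
  expect_identical(classify_read(aln(fl - 1799L + 1L, fl + rl + 1800L), jset),
                   "unassigned")
  expect_identical(classify_read(aln(fl - 1800L + 1L, fl + rl + 1799L), jset),
                   "unassigned")
  expect_identical(classify_read(aln(1L, fl + rl + 3000L), jset), "ref_a")
  unal <- structure(list(read_id = "r", ref = NA_character_),
                    class = "read_alignment")
  expect_identical(classify_read(unal, jset), "unassigned")
  expect_error(classify_read(aln(1L, 100L), jset, min_flank_overlap = 3500L),
               "exceeds flank_len")
})

test_that("aligner recovers reference, strand and span for clean reads", {
  pg <- preset_genome(seed = 8)
  cat_ <- find_dispersed_repeats(pg$genome, min_len = 50)
  pairs <- catalog_pairs(cat_)
  pr <- circrecomb:::.resolve_pair(cat_, pairs[pairs$pair_name == "Repeat-2a_b", ])
  js <- build_junctions(pg$genome, pr)
  idx <- kmer_index(js$refs)
  read <- substr(js$refs[["ref_a"]], 401L, 6400L)
  a <- align_read(read, idx)
  expect_identical(a$ref, "ref_a")
  expect_identical(a$strand, "+")
  expect_identical(c(a$rstart, a$rend), c(401L, 6400L))
  expect_identical(c(a$qstart, a$qend), c(1L, 6000L))
  arc <- align_read(revcomp(read), idx)
  expect_identical(arc$ref, "ref_a")
  expect_identical(arc$strand, "-")
  expect_identical(c(arc$rstart, arc$rend), c(401L, 6400L))
  # no shared k-mers: unaligned, not an error
  expect_true(is.na(align_read(strrep("A", 100L), idx)$ref))
})

test_that("primary-reference choice survives 1% substitution noise", {
  pg <- preset_genome(seed = 9)
  cat_ <- find_dispersed_repeats(pg$genome, min_len = 50)
  pr <- circrecomb:::.resolve_pair(
    cat_, catalog_pairs(cat_)[catalog_pairs(cat_)$pair_name == "Repeat-2a_b", ])
  js <- build_junctions(pg$genome, pr)
  idx <- kmer_index(js$refs)
  set.seed(91)
  n_per <- 75L
  hits <- 0L; total <- 0L
  for (ref in names(js$refs)) {
    L <- nchar(js$refs[[ref]])
    for (i in seq_len(n_per)) {
      s0 <- sample.int(L - 3000L, 1L)
      read <- substr(js$refs[[ref]], s0, s0 + 2999L)
      read <- circrecomb:::.apply_read_errors(read, 0.01, 0, 0)
      a <- align_read(read, idx)
      # flank-only or repeat-only reads are legitimately ambiguous
      # between references sharing that sequence; score the
      # junction-informative ones (those covering parts of both flanks)
      informative <- s0 < 3000L && s0 + 2999L > 3000L + js$repeat_len
      if (!informative) next
      total <- total + 1L
      if (identical(a$ref, ref)) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.99)
})

test_that("support rates reproduce printed-table arithmetic exactly", {
  st <- support_rates_from_counts(data.frame(
    pair = c("Repeat-1a_b", "Repeat-2a_b", "none"),
    n_reference = c(104L, 174L, 0L),
    n_alternative = c(100L, 613L, 5L)))
  expect_identical(st$pct_reference, c(50.98, 22.11, 0))
  expect_identical(st$pct_alternative, c(49.02, 77.89, 100))
  # percentages always complement to 100 up to rounding
  set.seed(44)
  a <- sample.int(2000L, 50L); b <- sample.int(2000L, 50L)
  st2 <- support_rates_from_counts(data.frame(pair = paste0("p", 1:50),
                                              n_reference = a,
                                              n_alternative = b))
  expect_true(all(abs(st2$pct_reference + st2$pct_alternative - 100) <= 0.01))
})

test_that("relabelling reference and alternative swaps the columns", {
  labs <- c(rep("ref_a", 30L), rep("ref_b", 11L), rep("alt_ab", 55L),
            rep("alt_ba", 4L), rep("unassigned", 7L))
  st <- support_rates(list(p = labs))
  swap <- c(ref_a = "alt_ab", ref_b = "alt_ba", alt_ab = "ref_a",
            alt_ba = "ref_b", unassigned = "unassigned")
  st2 <- support_rates(list(p = unname(swap[labs])))
  expect_identical(st$pct_reference, st2$pct_alternative)
  expect_identical(st$n_reference, st2$n_alternative)
})

test_that("reads touching only repeat-shared sequence are never assigned", {
  pg <- preset_genome(seed = 10)
  cat_ <- find_dispersed_repeats(pg$genome, min_len = 50)
  pairs <- catalog_pairs(cat_)
  pr5 <- circrecomb:::.resolve_pair(cat_,
                                    pairs[pairs$pair_name == "Repeat-5a_c", ])
  js5 <- build_junctions(pg$genome, pr5)
  # adversarial reads drawn entirely from the covering 1,467-bp repeat
  f2 <- cat_$families[[2L]]
  reads <- data.frame(
    id = c("full", "mid", "edge"),
    seq = c(f2$seq,
            substr(f2$seq, 400L, 1400L),
            substr(f2$seq, 1L, 1300L)))
  reads$length <- nchar(reads$seq)
  cls <- classify_reads(reads, js5)
  expect_true(all(cls$label == "unassigned"))
})
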