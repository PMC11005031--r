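# Recombination algebra: inversion, fission/fusion, enumeration.

test_that("IR inversion reverse-complements exactly the enclosed arc", {
  set.seed(31)
  t <- toy_with_pair(c(120L, 150L, 130L), 60L, ir = TRUE)
  out <- invert_at_ir(t$genome, t$copy1, t$copy2)
  expect_identical(out$seq,
                   paste0(t$P, t$R, revcomp(t$X), revcomp(t$R), t$Q))
  expect_identical(out$length, t$genome$length)
  expect_error(invert_at_ir(t$genome, t$copy1,
                            within(t$copy2, strand <- "+")),
               "IR pair")
})

test_that("DR fission produces the two definitional subcircles", {
  set.seed(32)
  t <- toy_with_pair(c(100L, 140L, 110L), 50L, ir = FALSE)
  halves <- split_at_dr(t$genome, t$copy1, t$copy2)
  expect_identical(halves[[1L]]$seq, paste0(t$R, t$X))
  expect_identical(halves[[2L]]$seq, paste0(t$R, t$Q, t$P))
  expect_identical(halves[[1L]]$length + halves[[2L]]$length,
                   t$genome$length)
  expect_error(split_at_dr(t$genome, t$copy1,
                           within(t$copy2, strand <- "-")),
               "DR pair")
})

test_that("inversion is an involution and split/fuse are mutual inverses
           on random toys", {
  set.seed(33)
  for (i in 1:100) {
    lens <- sample(40:120, 3L, replace = TRUE)
    rl <- sample(25:60, 1L)
    ir <- i %% 2L == 1L
    t <- toy_with_pair(lens, rl, ir = ir)
    cf0 <- canonical_form(t$genome)
    if (ir) {
      once <- invert_at_ir(t$genome, t$copy1, t$copy2)
      expect_identical(canonical_form(invert_at_ir(once, t$copy1, t$copy2)),
                       cf0)
      # inverting the complementary arc gives the same molecule class
      alt <- invert_at_ir(t$genome, t$copy2,
                          within(t$copy1, {
                            start0 <- start0 + t$genome$length
                            end0 <- end0 + t$genome$length
                          }))
      expect_identical(canonical_form(alt), canonical_form(once))
    } else {
      halves <- split_at_dr(t$genome, t$copy1, t$copy2)
      expect_identical(halves[[1L]]$length + halves[[2L]]$length,
                       t$genome$length)
      refused <- fuse(halves[[1L]], halves[[2L]], t$R)
      expect_identical(canonical_form(refused), cf0)
      # and fuse-then-split restores the halves
      back <- split_at_dr(refused,
                          list(start0 = 0L, end0 = rl, strand = "+"),
                          list(start0 = halves[[1L]]$length,
                               end0 = halves[[1L]]$length + rl,
                               strand = "+"))
      expect_setequal(vapply(back, canonical_form, character(1)),
                      vapply(halves, canonical_form, character(1)))
    }
  }
})

test_that("base composition is conserved by every event", {
  set.seed(34)
  comp_multiset <- function(seqs) {
    tab <- table(factor(unlist(strsplit(seqs, "", fixed = TRUE)),
                        levels = c("A", "C", "G", "T")))
    # a base and its complement are interchangeable under revcomp
    c(tab[["A"]] + tab[["T"]], tab[["C"]] + tab[["G"]])
  }
  t <- toy_with_pair(c(90L, 80L, 70L), 40L, ir = TRUE)
  before <- comp_multiset(t$genome$seq)
  inv <- invert_at_ir(t$genome, t$copy1, t$copy2)
  expect_identical(comp_multiset(inv$seq), before)
  t2 <- toy_with_pair(c(90L, 80L, 70L), 40L, ir = FALSE)
  halves <- split_at_dr(t2$genome, t2$copy1, t2$copy2)
  expect_identical(comp_multiset(c(halves[[1L]]$seq, halves[[2L]]$seq)),
                   comp_multiset(t2$genome$seq))
})

test_that("enumeration finds the four major isomeric forms and no more", {
  pg <- preset_genome(seed = 6)
  cat_ <- find_dispersed_repeats(pg$genome, min_len = 50)
  pairs <- catalog_pairs(cat_, drop_shadowed = TRUE)
  big <- pairs[pairs$family_id %in% c(1L, 2L), ]
  forms <- enumerate_forms(pg$genome, cat_, active_pairs = big,
                           max_events = 2L)
  expect_length(forms, 4L)
  expect_setequal(vapply(forms, `[[`, character(1), "name"),
                  c("MC1", "MC2", "MC1^2", "MC2^2"))
  lens <- lapply(forms, function(f)
    vapply(f$circles, `[[`, integer(1), "length"))
  expect_true(all(vapply(lens, sum, integer(1)) == pg$genome$length))
  # with no active pairs only the founder exists
  none <- enumerate_forms(pg$genome, cat_, active_pairs = big[0L, ],
                          max_events = 2L)
  expect_length(none, 1L)
  expect_identical(none[[1L]]$name, "MC1")
  # untouched repeat content survives recombination
  mc2 <- forms[[match("MC2", vapply(forms, `[[`, character(1), "name"))]]
  cat2 <- find_dispersed_repeats(mc2$circles[[1L]], min_len = 50)
  expect_identical(vapply(cat2$families, `[[`, integer(1), "length"),
                   vapply(cat_$families, `[[`, integer(1), "length"))
})

test_that("closure equals exhaustive event-sequence enumeration on a
           three-repeat toy", {
  set.seed(36)
  # toy circle with one IR pair, one DR pair and a second DR pair
  mg <- make_genome(4000L, list(
    repeat_spec(80, list(list(200L, "+"), list(1500L, "-"))),
    repeat_spec(60, list(list(700L, "+"), list(2500L, "+"))),
    repeat_spec(50, list(list(1100L, "+"), list(3200L, "+")))), seed = 36)
  cat_ <- find_dispersed_repeats(mg$genome, min_len = 30)
  pairs <- catalog_pairs(cat_)
  forms <- enumerate_forms(mg$genome, cat_, active_pairs = pairs,
                           max_events = 2L)
  # oracle: depth-first over all event sequences, de-duplicated at the end
  fam_seqs <- lapply(cat_$families, `[[`, "seq")
  all_products <- function(circles) {
    out <- list()
    for (fs in fam_seqs) {
      hits <- lapply(circles, locate_repeat, repeat_seq = fs)
      for (ci in seq_along(circles)) {
        h <- hits[[ci]]
        if (nrow(h) < 2L) next
        cb <- utils::combn(nrow(h), 2L)
        for (p in seq_len(ncol(cb))) {
          c1 <- as.list(h[cb[1L, p], ]); c2 <- as.list(h[cb[2L, p], ])
          prod <- if (c1$strand != c2$strand) {
            c(circles[-ci], list(invert_at_ir(circles[[ci]], c1, c2)))
          } else {
            c(circles[-ci], split_at_dr(circles[[ci]], c1, c2))
          }
          out[[length(out) + 1L]] <- prod
        }
      }
      ones <- which(vapply(hits, nrow, integer(1)) == 1L)
      if (length(ones) >= 2L) {
        cb <- utils::combn(ones, 2L)
        for (p in seq_len(ncol(cb))) {
          out[[length(out) + 1L]] <-
            c(circles[-cb[, p]],
              list(fuse(circles[[cb[1L, p]]], circles[[cb[2L, p]]], fs)))
        }
      }
    }
    out
  }
  key_of <- function(circles)
    paste(sort(vapply(circles, canonical_form, character(1))),
          collapse = "|")
  keys <- key_of(list(mg$genome))
  level <- list(list(mg$genome))
  for (d in 1:2) {
    nxt <- list()
    for (st in level) for (pr in all_products(st)) {
      keys <- c(keys, key_of(pr))
      nxt[[length(nxt) + 1L]] <- pr
    }
    level <- nxt
  }
  expect_setequal(
    vapply(forms, function(f)
      key_of(f$circles), character(1)),
    unique(keys))
})

test_that("fusion validates its preconditions", {
  set.seed(37)
  t <- toy_with_pair(c(100L, 120L, 90L), 50L, ir = FALSE)
  halves <- split_at_dr(t$genome, t$copy1, t$copy2)
  expect_error(fuse(halves[[1L]], halves[[2L]], random_circle(50L)),
               "not found")
})
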