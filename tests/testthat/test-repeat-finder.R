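# Dispersed-repeat detection against planted truth and the brute-force
# diagonal-scan oracle.

test_that("planted direct and inverted pairs are classified correctly", {
  set.seed(11)
  for (ir in c(FALSE, TRUE)) {
    # boundary-hardened planting via the generator
    spec <- list(repeat_spec(500, list(list(300L, "+"),
                                       list(1800L, if (ir) "-" else "+"))))
    mg <- make_genome(3000L, spec, seed = 11 + ir)
    cat_ <- find_dispersed_repeats(mg$genome, min_len = 50)
    expect_length(cat_$families, 1L)
    f <- cat_$families[[1L]]
    expect_identical(f$length, 500L)
    p <- pairs_for_family(cat_, 1L)
    expect_identical(p$pair_class, if (ir) "IR" else "DR")
    expect_false(p$shadowed)
  }
})

test_that("catalog equals the brute-force maximal-repeat oracle", {
  layouts <- list(
    list(n = 900L, specs = list()),
    list(n = 1000L, specs = list(
      repeat_spec(60, list(list(100L, "+"), list(400L, "+"))))),
    list(n = 1200L, specs = list(
      repeat_spec(80, list(list(50L, "+"), list(600L, "-"))),
      repeat_spec(40, list(list(300L, "+"), list(900L, "+"))))),
    list(n = 1500L, specs = list(
      repeat_spec(120, list(list(100L, "+"), list(700L, "+"),
                            list(1200L, "-"))),
      repeat_spec(45, list(list(400L, "-"), list(1000L, "+")))))
  )
  for (seed in c(2, 3)) {
    for (ly in layouts) {
      mg <- make_genome(ly$n, ly$specs, seed = seed)
      impl <- as.data.frame(find_dispersed_repeats(mg$genome, min_len = 25))
      orac <- oracle_catalog_df(mg$genome$seq, 25L)
      rownames(impl) <- NULL
      expect_equal(impl, orac, ignore_attr = TRUE,
                   label = sprintf("seed %d, n %d", seed, ly$n))
    }
  }
})

test_that("catalog is invariant under genome rotation", {
  mg <- make_genome(2000L, list(
    repeat_spec(90, list(list(200L, "+"), list(1100L, "-"))),
    repeat_spec(50, list(list(600L, "+"), list(1600L, "+")))), seed = 5)
  base <- as.data.frame(find_dispersed_repeats(mg$genome, min_len = 30))
  n <- mg$genome$length
  # coordinate normalization: map starts back, then reassign copy
  # letters by mapped position and re-anchor strands on the new copy a
  renorm <- function(df) {
    out <- lapply(split(df, df$family_id), function(f) {
      f <- f[order(f$start), , drop = FALSE]
      f$copy_label <- letters[seq_len(nrow(f))]
      if (f$strand[1L] == "-") {
        f$strand <- ifelse(f$strand == "+", "-", "+")
      }
      f
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
  }
  for (k in c(137L, 955L, 1999L)) {
    rot <- circular_sequence(circ_extract(mg$genome, k, k + n), id = "rot")
    df <- as.data.frame(find_dispersed_repeats(rot, min_len = 30))
    df$start <- (df$start - 1L + k) %% n + 1L
    df$end <- df$start + df$length - 1L
    expect_equal(renorm(df), renorm(base), ignore_attr = TRUE)
  }
})

test_that("origin-spanning repeat copies are found with wrapped intervals", {
  set.seed(21)
  R <- random_circle(200L)
  bg <- random_circle(1800L)
  # copy b straddles the origin: last 120 bp at the end, first 80 bp at
  # the start of the linear representation
  g <- circular_sequence(paste0(substr(R, 121L, 200L), substr(bg, 81L, 900L),
                                R, substr(bg, 901L, 1800L),
                                substr(R, 1L, 120L)))
  cat_ <- find_dispersed_repeats(g, min_len = 50)
  expect_length(cat_$families, 1L)
  f <- cat_$families[[1L]]
  expect_identical(f$length, 200L)
  expect_true(any(f$copies$end0 > g$length)) # wrapped interval
})

test_that("input validation refuses unreliable settings", {
  g <- circular_sequence(random_circle(500L))
  expect_error(find_dispersed_repeats(g, min_len = 19), "refused")
  expect_error(find_dispersed_repeats(g, min_len = 300), "shorter")
  expect_error(find_dispersed_repeats(g, min_identity = 0), "min_identity")
})

test_that("nesting relations match brute-force interval inclusion", {
  pg <- preset_genome(seed = 1)
  cat_ <- find_dispersed_repeats(pg$genome, min_len = 50)
  nest <- detect_nesting(cat_)
  # the planted nested copy occupies positions 1,173-1,360 of the outer
  expect_identical(nest$offset_start, c(1173L, 1173L))
  expect_identical(nest$offset_end, c(1360L, 1360L))
  expect_identical(nest$inner_length, c(188L, 188L))
  # brute-force: every cross-family containment and nothing else
  df <- as.data.frame(cat_)
  n <- cat_$genome_length
  found <- 0L
  for (i in seq_len(nrow(df))) for (j in seq_len(nrow(df))) {
    if (df$family_id[i] == df$family_id[j]) next
    if (df$length[i] >= df$length[j]) next
    contained <- any(vapply(c(0L, n), function(sh)
      df$start[i] + sh >= df$start[j] &&
        df$end[i] + sh <= df$end[j], logical(1)))
    if (contained) {
      found <- found + 1L
      expect_true(any(nest$inner_family == df$family_id[i] &
                        nest$inner_copy == df$copy_label[i] &
                        nest$outer_family == df$family_id[j] &
                        nest$outer_copy == df$copy_label[j]))
    }
  }
  expect_identical(nrow(nest), found)
  # catalog without containments
  mg <- make_genome(1000L, list(
    repeat_spec(60, list(list(100L, "+"), list(500L, "+")))), seed = 3)
  expect_identical(nrow(detect_nesting(
    find_dispersed_repeats(mg$genome, min_len = 30))), 0L)
})

test_that("pair listing shadows nested-only pairs like the report does", {
  pg <- preset_genome(seed = 4)
  cat_ <- find_dispersed_repeats(pg$genome, min_len = 50)
  p5 <- pairs_for_family(cat_, 5L)
  expect_identical(p5$pair_name,
                   c("Repeat-5a_b", "Repeat-5a_c", "Repeat-5b_c"))
  expect_identical(p5$shadowed, c(TRUE, FALSE, FALSE))
  expect_identical(p5$pair_class, c("DR", "IR", "IR"))
  # 2-copy family: single unshadowed pair
  p6 <- pairs_for_family(cat_, 6L)
  expect_identical(nrow(p6), 1L)
  expect_false(p6$shadowed)
  # shadowing decision equals the direct containment check
  nest <- detect_nesting(cat_)
  for (r in seq_len(nrow(p5))) {
    o1 <- nest$outer_family[nest$inner_family == 5L &
                              nest$inner_copy == p5$copy1[r]]
    o2 <- nest$outer_family[nest$inner_family == 5L &
                              nest$inner_copy == p5$copy2[r]]
    expect_identical(p5$shadowed[r], length(intersect(o1, o2)) > 0L)
  }
})
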