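test_that("find_repeats handles textbook cases", {
  # tandem duplication
  p <- find_repeats("ACGTACGT", min_len = 4, min_identity = 1)
  expect_equal(nrow(p), 1L)
  expect_equal(unlist(p[1, 1:4], use.names = FALSE), c(0, 4, 4, 8))
  expect_identical(p$strand, "same")

  # planted 300 bp inverted copy in 2 kb of random sequence
  set.seed(42)
  s <- rand_dna(2000)
  unit <- substr(s, 301, 600)
  s <- paste0(substr(s, 1, 1400), str_rc(unit), substring(s, 1701))
  p <- find_repeats(s, min_len = 100, min_identity = 1)
  expect_equal(nrow(p), 1L)
  expect_identical(p$strand, "inverted")
  # maximal runs may extend a base or two past the planted copy by chance
  expect_lte(p$a_start, 300); expect_gte(p$a_end, 600)
  expect_lte(p$b_start, 1400); expect_gte(p$b_end, 1700)
  expect_lte(p$length, 306L)
  expect_identical(pair_key(p), pair_key(oracle_repeats(s, 100)))

  expect_error(find_repeats("ACGTNNNNNNNNACGTAA", min_len = 8),
               "non-ACGT")
})

test_that("find_repeats matches the O(n^2) oracle on planted sequences", {
  set.seed(7)
  for (rep_i in 1:8) {
    n <- sample(500:1500, 1)
    s <- rand_dna(n)
    u <- sample(60:150, 1)
    src <- sample(n - 3 * u, 1)
    unit <- substr(s, src, src + u - 1)
    dst <- src + u + sample(10:(n - src - 2 * u - 10), 1)
    copy <- if (rep_i %% 2 == 0) str_rc(unit) else unit
    s <- paste0(substr(s, 1, dst - 1), copy, substring(s, dst + u))
    got <- find_repeats(s, min_len = 50, min_identity = 1, k = 21)
    expect_identical(pair_key(got), pair_key(oracle_repeats(s, 50)))
  }
})

test_that("find_repeats is invariant under reverse complement", {
  set.seed(11)
  s <- rand_dna(800)
  unit <- substr(s, 101, 200)
  s <- paste0(substr(s, 1, 500), unit, substring(s, 601))  # direct copy
  s <- paste0(substr(s, 1, 700), str_rc(substr(s, 301, 360)),
              substring(s, 761))                           # inverted copy
  n <- nchar(s)
  p_f <- find_repeats(s, min_len = 50, min_identity = 1)
  p_r <- find_repeats(str_rc(s), min_len = 50, min_identity = 1)
  # map reverse-complement coordinates back: [s,e) -> [n-e, n-s)
  mapped <- data.frame(a_start = n - p_r$b_end, a_end = n - p_r$b_start,
                       b_start = n - p_r$a_end, b_end = n - p_r$a_start,
                       strand = p_r$strand)
  swap <- mapped$a_start > mapped$b_start
  mapped[swap, ] <- mapped[swap, c(3, 4, 1, 2, 5)]
  expect_identical(pair_key(p_f), pair_key(mapped))
})

test_that("circular genomes find repeats crossing the origin", {
  set.seed(13)
  core <- rand_dna(1500)
  unit <- substr(core, 400, 549)
  # second copy wraps: last 75 bp of the genome + first 75 bp
  s <- paste0(substr(unit, 76, 150), substr(core, 1, 1350),
              substr(unit, 1, 75))
  got_lin <- find_repeats(s, min_len = 140, min_identity = 1,
                          circular = FALSE)
  got_circ <- find_repeats(s, min_len = 140, min_identity = 1,
                           circular = TRUE)
  expect_equal(nrow(got_lin), 0L)
  expect_equal(nrow(got_circ), 1L)
  expect_gte(got_circ$length, 150L)
  expect_lte(got_circ$length, 156L)
})

test_that("raising min_len never adds repeat pairs", {
  set.seed(17)
  s <- rand_dna(1000)
  unit <- substr(s, 101, 400)
  s <- paste0(substr(s, 1, 600), unit, substring(s, 901))
  prev <- NULL
  for (ml in c(50, 100, 200, 350)) {
    p <- find_repeats(s, min_len = ml, min_identity = 1, k = 21)
    if (!is.null(prev)) expect_lte(nrow(p), nrow(prev))
    m <- build_mask(p, nchar(s))
    if (!is.null(prev)) {
      expect_lte(masked_fraction(m),
                 masked_fraction(build_mask(prev, nchar(s))))
    }
    prev <- p
  }
})

test_that("build_mask merges intervals like a per-base boolean array", {
  p <- data.frame(a_start = 0L, a_end = 4L, b_start = 2L, b_end = 8L,
                  strand = "same", length = 4L, identity = 1)
  m <- build_mask(p, 10)
  expect_equal(m$intervals, data.frame(start = 0L, end = 8L))

  no_pairs <- data.frame(a_start = integer(), a_end = integer(),
                         b_start = integer(), b_end = integer())
  expect_equal(masked_fraction(build_mask(no_pairs, 10)), 0)

  set.seed(19)
  starts <- sample(0:900, 50, replace = TRUE)
  widths <- sample(1:80, 50, replace = TRUE)
  ends <- pmin(starts + widths, 1000L)
  pairs <- data.frame(a_start = starts[1:25], a_end = ends[1:25],
                      b_start = starts[26:50], b_end = ends[26:50])
  m <- build_mask(pairs, 1000)
  covered <- logical(1000)
  for (i in seq_along(starts)) {
    if (ends[i] > starts[i]) covered[(starts[i] + 1):ends[i]] <- TRUE
  }
  expect_equal(sum(m$intervals$end - m$intervals$start), sum(covered))
  # sorted and disjoint
  expect_true(all(diff(m$intervals$start) > 0))
  expect_true(all(m$intervals$start[-1] > head(m$intervals$end, -1)))
})

test_that("filter_variants applies the any-overlap rule", {
  mask <- build_mask(data.frame(a_start = 0L, a_end = 4L, b_start = 0L,
                                b_end = 4L), 1000)
  v <- data.frame(pos = 5L, ref = "A")
  v$alts <- I(list("G"))
  expect_equal(nrow(filter_variants(v, mask)), 1L)  # half-open boundary

  # deletion whose REF span reaches into the mask is removed
  d <- data.frame(pos = 3L, ref = "TTTT")
  d$alts <- I(list("T"))
  expect_equal(nrow(filter_variants(d, mask)), 0L)

  expect_error(filter_variants(data.frame(pos = 999L, ref = "AAA"), mask),
               "outside")

  set.seed(23)
  ms <- sort(sample(0:950, 10))
  mask2 <- build_mask(data.frame(a_start = ms[1:5], a_end = ms[1:5] + 20L,
                                 b_start = ms[6:10],
                                 b_end = ms[6:10] + 20L), 1000)
  pos <- sample(1:970, 100)
  refs <- vapply(sample(1:5, 100, replace = TRUE),
                 function(w) rand_dna(w), character(1))
  vv <- data.frame(pos = pos, ref = refs)
  kept <- filter_variants(vv, mask2)
  # per-variant brute force
  covered <- logical(1000)
  for (i in seq_len(nrow(mask2$intervals))) {
    covered[(mask2$intervals$start[i] + 1):mask2$intervals$end[i]] <- TRUE
  }
  manual <- vv[!vapply(seq_len(nrow(vv)), function(i) {
    any(covered[vv$pos[i]:(vv$pos[i] + nchar(vv$ref[i]) - 1L)])
  }, logical(1)), , drop = FALSE]
  expect_equal(kept$pos, manual$pos)
  # order preserved
  expect_identical(kept$pos, vv$pos[vv$pos %in% kept$pos])
})

test_that("masked fraction of a planted-repeat genome matches truth", {
  gen <- generate_reference(12000, repeat_spec(2, 1500, 1, 0.5), seed = 21)
  pr <- find_repeats(gen$genome$seq, min_len = 100, min_identity = 0.95,
                     circular = TRUE)
  truth_frac <- masked_fraction(build_mask(gen$repeats, 12000))
  got_frac <- masked_fraction(build_mask(pr, 12000))
  expect_lt(abs(got_frac - truth_frac), 100 / 12000 * 4)
})
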