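#' Detect repeat pairs in an organelle genome by self-comparison
#'
#' Finds pairs of near-identical regions (direct or inverted) of length at
#' least `min_len` and ungapped identity at least `min_identity`. Matching is
#' seeded on exact k-mer hits and extended along the diagonal by chaining
#' exact match runs while the running identity stays above the floor — a
#' deterministic, parameter-transparent stand-in for a blastn self-search.
#' For circular genomes the sequence is doubled so matches crossing the
#' origin are found, and shifted duplicates are collapsed.
#'
#' @param seq Nucleotide string over \{A,C,G,T\} (Ns tolerated, never match).
#' @param min_len Minimum repeat unit length in bp (>= 2; values below ~8
#'   are only sensible on toy sequences).
#' @param min_identity Minimum fraction of matching bases in \[0,1\].
#' @param circular Is the genome circular?
#' @param k Seed word size; defaults to `min(21, min_len)`.
#' @param ambiguity_budget Maximum tolerated fraction of non-ACGT characters.
#' @return A data.frame with one row per repeat pair: `a_start`, `a_end`,
#'   `b_start`, `b_end` (0-based half-open; on circular genomes `*_end` may
#'   exceed the genome length when the copy crosses the origin), `strand`
#'   (`"same"` or `"inverted"`), `length`, `identity`. Pairs are canonically
#'   ordered with interval A lexicographically before interval B; the
#'   trivial self-match is never reported.
#' @examples
#' find_repeats("ACGTACGT", min_len = 4, min_identity = 1)
#' @export
find_repeats <- function(seq, min_len = 100, min_identity = 0.95,
                         circular = FALSE, k = NULL,
                         ambiguity_budget = 0.01) {
  stopifnot(min_len >= 2, min_identity > 0, min_identity <= 1)
  seq <- check_dna(seq, ambiguity_budget)
  n <- nchar(seq)
  if (is.null(k)) k <- min(21L, as.integer(min_len))
  k <- as.integer(k)
  s <- if (circular) paste0(seq, seq) else seq
  L <- nchar(s)
  if (L < 2L * k) return(empty_pairs())

  x <- utf8ToInt(s)
  x[x == utf8ToInt("N")] <- -1L  # sentinel: never matches anything
  xr <- utf8ToInt(revcomp(s))
  xr[xr == utf8ToInt("N")] <- -2L

  kmer_pos <- function(str) {
    starts <- seq_len(nchar(str) - k + 1L)
    words <- substring(str, starts, starts + k - 1L)
    keep <- !grepl("N", words, fixed = TRUE)
    split(starts[keep], words[keep])
  }
  km_f <- kmer_pos(s)

  res <- list()

  # --- direct repeats: diagonals with >=2 occurrences of a k-mer ---
  diags <- unique(unlist(lapply(km_f[lengths(km_f) > 1L], function(p) {
    d <- as.vector(outer(p, p, "-"))
    d[d > 0L]
  }), use.names = FALSE))
  for (d in sort(diags)) {
    m <- x[seq_len(L - d)] == x[seq_len(L - d) + d]
    segs <- chain_segments(m, k, min_len, min_identity)
    if (nrow(segs)) {
      res[[length(res) + 1L]] <- data.frame(
        a_start = segs$start - 1L, a_end = segs$end,
        b_start = segs$start - 1L + d, b_end = segs$end + d,
        strand = "same", length = segs$end - segs$start + 1L,
        identity = segs$identity)
    }
  }

  # --- inverted repeats: compare s against its reverse complement ---
  rc <- revcomp(s)
  km_r <- kmer_pos(rc)
  shared <- intersect(names(km_f), names(km_r))
  diags <- unique(unlist(lapply(shared, function(w) {
    as.vector(outer(km_r[[w]], km_f[[w]], "-"))
  }), use.names = FALSE))
  for (d in sort(diags)) {
    i <- seq.int(max(1L, 1L - d), min(L, L - d))
    m <- x[i] == xr[i + d]
    segs <- chain_segments(m, k, min_len, min_identity)
    if (nrow(segs)) {
      i0 <- i[1] + segs$start - 1L
      i1 <- i[1] + segs$end - 1L
      j0 <- i0 + d
      j1 <- i1 + d
      # rc position j maps to forward position L - j + 1
      res[[length(res) + 1L]] <- data.frame(
        a_start = i0 - 1L, a_end = i1,
        b_start = L - j1, b_end = L - j0 + 1L,
        strand = "inverted", length = segs$end - segs$start + 1L,
        identity = segs$identity)
    }
  }

  pairs <- if (length(res)) do.call(rbind, res) else empty_pairs()
  canonicalize_pairs(pairs, n, circular)
}

empty_pairs <- function() {
  data.frame(a_start = integer(), a_end = integer(), b_start = integer(),
             b_end = integer(), strand = character(), length = integer(),
             identity = numeric())
}

# Segments of one diagonal's match vector with identity >= min_identity,
# length >= min_len, containing an exact run of >= k (the seed), starting
# and ending on a match. At min_identity = 1 these are exactly the maximal
# exact-match runs (so results agree with a brute-force oracle); below 1,
# seeds are extended in both directions by an X-drop walk with mismatch
# penalty mu = min_identity / (1 - min_identity), which makes any segment
# ending at the running score maximum satisfy the identity floor by
# construction. Returns 1-based inclusive coordinates along the diagonal.
chain_segments <- function(m, k, min_len, min_identity) {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  seeds <- which(r$values & r$lengths >= k)
  if (!length(seeds)) {
    return(data.frame(start = integer(), end = integer(),
                      identity = numeric()))
  }
  if (min_identity >= 1) {
    keep <- seeds[r$lengths[seeds] >= min_len]
    return(data.frame(start = starts[keep], end = ends[keep],
                      identity = rep(1, length(keep))))
  }
  mu <- min_identity / (1 - min_identity)
  xdrop <- 5 * mu + 10  # cross local mismatch clusters, stop in random flank
  score <- ifelse(m, 1, -mu)
  extend <- function(from, step, limit) {
    # walk from `from` (exclusive) towards `limit`, return offset of the
    # best prefix (running-max position), stopping on an X-drop
    best <- 0; cum <- 0; best_at <- from
    i <- from + step
    while (i >= 1L && i <= limit) {
      cum <- cum + score[i]
      if (cum > best) { best <- cum; best_at <- i }
      if (cum < best - xdrop) break
      i <- i + step
    }
    best_at
  }
  out_s <- integer(); out_e <- integer(); out_id <- numeric()
  last_end <- 0L
  for (sd in seeds) {
    if (starts[sd] <= last_end) next  # already inside a reported segment
    s0 <- extend(starts[sd], -1L, length(m))
    e0 <- extend(ends[sd], +1L, length(m))
    last_end <- e0
    len <- e0 - s0 + 1L
    if (len >= min_len) {
      out_s <- c(out_s, s0); out_e <- c(out_e, e0)
      out_id <- c(out_id, sum(m[s0:e0]) / len)
    }
  }
  data.frame(start = out_s, end = out_e, identity = out_id)
}

# Canonical ordering, removal of trivial/mirror/shifted duplicates.
canonicalize_pairs <- function(pairs, n, circular) {
  if (!nrow(pairs)) return(pairs)
  # drop the trivial self-match (identical intervals)
  keep <- !(pairs$a_start == pairs$b_start & pairs$a_end == pairs$b_end)
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs)) return(empty_pairs())
  # order so interval A is lexicographically <= interval B
  swap <- pairs$a_start > pairs$b_start |
    (pairs$a_start == pairs$b_start & pairs$a_end > pairs$b_end)
  tmp <- pairs[swap, c("b_start", "b_end", "a_start", "a_end")]
  pairs[swap, c("a_start", "a_end", "b_start", "b_end")] <- tmp
  if (circular) {
    pairs <- pairs[pairs$length <= n, , drop = FALSE]
    # diagonal n of the doubled sequence is the genome matching itself
    triv <- pairs$strand == "same" &
      (pairs$b_start - pairs$a_start) %% n == 0
    pairs <- pairs[!triv, , drop = FALSE]
    # collapse copies shifted by the doubling: normalize A to start in [0,n)
    sh <- (pairs$a_start %/% n) * n
    pairs$a_start <- pairs$a_start - sh; pairs$a_end <- pairs$a_end - sh
    pairs$b_start <- pairs$b_start - sh; pairs$b_end <- pairs$b_end - sh
    pairs <- pairs[pairs$b_start >= 0 & pairs$b_end <= 2L * n, , drop = FALSE]
    key <- paste(pairs$a_start %% n, pairs$b_start %% n, pairs$strand,
                 pairs$length)
    pairs <- pairs[!duplicated(key), , drop = FALSE]
    # the same circular pair can surface with roles swapped; dedup on an
    # orientation-free key
    key2 <- apply(cbind(pmin(pairs$a_start %% n, pairs$b_start %% n),
                        pmax(pairs$a_start %% n, pairs$b_start %% n)), 1,
                  paste, collapse = ":")
    key2 <- paste(key2, pairs$strand, pairs$length)
    pairs <- pairs[!duplicated(key2), , drop = FALSE]
  } else {
    key <- paste(pairs$a_start, pairs$a_end, pairs$b_start, pairs$b_end,
                 pairs$strand)
    pairs <- pairs[!duplicated(key), , drop = FALSE]
  }
  pairs <- pairs[order(pairs$a_start, pairs$a_end, pairs$b_start,
                       pairs$b_end, pairs$strand), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Merge repeat pairs into a genome mask
#'
#' Takes the union of all repeat intervals (both members of every pair),
#' merged and sorted. Intervals extending past the genome end (circular
#' origin-crossing copies) are wrapped.
#'
#' @param pairs A data.frame as returned by [find_repeats()].
#' @param genome_length Genome length in bp.
#' @return An object of class `"organelle_mask"`: a list with `intervals`
#'   (data.frame `start`, `end`, 0-based half-open, sorted, disjoint) and
#'   `genome_length`.
#' @export
build_mask <- function(pairs, genome_length) {
  stopifnot(genome_length >= 1)
  n <- as.integer(genome_length)
  starts <- c(pairs$a_start, pairs$b_start)
  ends <- c(pairs$a_end, pairs$b_end)
  # intervals on the doubled circular coordinate system: shift copies that
  # lie entirely past the origin, then wrap the ones that cross it
  shift <- (starts %/% n) * n
  starts <- starts - shift
  ends <- ends - shift
  wrap <- ends > n
  if (any(wrap)) {
    starts <- c(starts, rep(0L, sum(wrap)))
    ends <- c(ends, ends[wrap] - n)
    ends[wrap] <- n
  }
  ir <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, end = ends))
  out <- list(intervals = data.frame(start = IRanges::start(ir) - 1L,
                                     end = IRanges::end(ir)),
              genome_length = n)
  class(out) <- "organelle_mask"
  out
}

#' Fraction of the genome covered by a mask
#'
#' @param mask An `"organelle_mask"` from [build_mask()].
#' @return Total masked length / genome length, in \[0,1\].
#' @export
masked_fraction <- function(mask) {
  stopifnot(inherits(mask, "organelle_mask"))
  sum(mask$intervals$end - mask$intervals$start) / mask$genome_length
}

#' Remove variants falling in masked (duplicated) regions
#'
#' A variant is removed iff its reference allele span (1-based `pos` ..
#' `pos + nchar(ref) - 1`) intersects any mask interval; any overlap counts.
#' Input order is preserved.
#'
#' @param variants A data.frame with at least `pos` (1-based) and `ref`
#'   columns (a sites table from [read_organelle_vcf()] works).
#' @param mask An `"organelle_mask"`.
#' @return The retained rows of `variants`.
#' @export
filter_variants <- function(variants, mask) {
  stopifnot(inherits(mask, "organelle_mask"))
  if (!nrow(variants)) return(variants)
  span_end <- variants$pos + nchar(variants$ref) - 1L
  if (any(variants$pos < 1L) || any(span_end > mask$genome_length)) {
    stop("variant reference span outside [1, genome_length]", call. = FALSE)
  }
  if (!nrow(mask$intervals)) return(variants)
  q <- IRanges::IRanges(start = variants$pos, end = span_end)
  subj <- IRanges::IRanges(start = mask$intervals$start + 1L,
                           end = mask$intervals$end)
  hit <- IRanges::overlapsAny(q, subj)
  out <- variants[!hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write repeat pairs or a mask as BED
#'
#' BED uses 0-based half-open coordinates, matching the internal convention.
#'
#' @param x A pairs data.frame from [find_repeats()] or an
#'   `"organelle_mask"`.
#' @param contig Contig name for the BED lines.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, contig, path) {
  if (inherits(x, "organelle_mask")) {
    df <- data.frame(contig, x$intervals$start, x$intervals$end)
  } else {
    df <- data.frame(contig, c(x$a_start, x$b_start), c(x$a_end, x$b_end),
                     name = rep(paste0("pair", seq_len(nrow(x)), "_",
                                       x$strand), 2))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
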