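# Independent brute-force oracles used to pin down expected values.
# These deliberately avoid the package's own code paths.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

str_rc <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# O(n^2) exact-repeat finder: scans every diagonal of the self-comparison
# (and of the comparison against the reverse complement) and reports all
# maximal exact match runs of length >= min_len, canonically ordered.
oracle_repeats <- function(seq, min_len) {
  n <- nchar(seq)
  x <- utf8ToInt(seq)
  out <- list()
  runs_on <- function(m) {
    r <- rle(m)
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    keep <- r$values & r$lengths >= min_len
    cbind(s[keep], e[keep])
  }
  for (d in seq_len(n - 1L)) {
    m <- x[seq_len(n - d)] == x[seq_len(n - d) + d]
    segs <- runs_on(m)
    for (row in seq_len(nrow(segs))) {
      out[[length(out) + 1L]] <- c(segs[row, 1] - 1L, segs[row, 2],
                                   segs[row, 1] - 1L + d, segs[row, 2] + d,
                                   0L)
    }
  }
  y <- utf8ToInt(str_rc(seq))
  for (d in seq.int(1L - n, n - 1L)) {
    i <- seq.int(max(1L, 1L - d), min(n, n - d))
    m <- x[i] == y[i + d]
    segs <- runs_on(m)
    for (row in seq_len(nrow(segs))) {
      i0 <- i[1] + segs[row, 1] - 1L
      i1 <- i[1] + segs[row, 2] - 1L
      j0 <- i0 + d; j1 <- i1 + d
      a <- c(i0 - 1L, i1)
      b <- c(n - j1, n - j0 + 1L)
      if (identical(a, b)) next  # palindromic self-match
      p <- if (a[1] < b[1] || (a[1] == b[1] && a[2] <= b[2])) c(a, b)
           else c(b, a)
      out[[length(out) + 1L]] <- c(p, 1L)
    }
  }
  if (!length(out)) {
    return(data.frame(a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer(),
                      strand = character()))
  }
  m <- unique(do.call(rbind, out))
  df <- data.frame(a_start = m[, 1], a_end = m[, 2], b_start = m[, 3],
                   b_end = m[, 4],
                   strand = c("same", "inverted")[m[, 5] + 1L])
  df[order(df$a_start, df$a_end, df$b_start, df$b_end, df$strand), ]
}

pair_key <- function(df) {
  sort(paste(df$a_start, df$a_end, df$b_start, df$b_end, df$strand))
}

# brute-force perfect-linkage closure: pairwise bijection check through a
# contingency table, then transitive closure by boolean matrix powers.
oracle_linkage_groups <- function(calls) {
  S <- ncol(calls)
  linked <- diag(TRUE, S)
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      if (i == j) next
      ok <- !is.na(calls[, i]) & !is.na(calls[, j])
      if (sum(ok) < 2L) next
      tab <- table(calls[ok, i], calls[ok, j])
      linked[i, j] <- all(rowSums(tab > 0) == 1L) &&
        all(colSums(tab > 0) == 1L)
    }
  }
  repeat {
    nxt <- (linked %*% linked) > 0
    if (identical(nxt, linked)) break
    linked <- nxt
  }
  # group label = smallest member index
  apply(linked, 1, function(r) min(which(r)))
}

# exhaustive minimum spanning tree weight by enumerating all spanning
# edge subsets (only feasible for tiny n)
oracle_mst_exhaustive <- function(d) {
  n <- nrow(d)
  ij <- which(upper.tri(d), arr.ind = TRUE)
  ne <- nrow(ij)
  best <- Inf
  for (comb in utils::combn(ne, n - 1L, simplify = FALSE)) {
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    ok <- TRUE
    for (e in comb) {
      ri <- find(ij[e, 1]); rj <- find(ij[e, 2])
      if (ri == rj) { ok <- FALSE; break }
      parent[ri] <- rj
    }
    if (ok) best <- min(best, sum(d[ij[comb, , drop = FALSE]]))
  }
  best
}

# full-protein translation-diff oracle for coding effect calls on a
# single-CDS plus- or minus-strand gene with phase 0
oracle_effect <- function(pos, ref, alt, gene, seq, code = "1") {
  gc_tab <- Biostrings::getGeneticCode(code)
  tr <- function(s) {
    n <- 3L * (nchar(s) %/% 3L)
    if (n == 0L) return("")
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(s, 1L, n)),
      genetic.code = gc_tab, no.init.codon = TRUE, if.fuzzy.codon = "X"))
  }
  span_end <- pos + nchar(ref) - 1L
  cds_ref <- substr(seq, gene$start, gene$end)
  cds_alt <- paste0(substr(seq, gene$start, pos - 1L), alt,
                    substring(seq, span_end + 1L, gene$end))
  if (gene$strand == "-") {
    cds_ref <- str_rc(cds_ref); cds_alt <- str_rc(cds_alt)
  }
  dlen <- nchar(alt) - nchar(ref)
  if (dlen %% 3L != 0L) return("frameshift")
  p_ref <- tr(cds_ref); p_alt <- tr(cds_alt)
  first_stop <- function(p) {
    s <- regexpr("*", p, fixed = TRUE)
    if (s < 0) Inf else s
  }
  if (!startsWith(cds_alt, "ATG")) return("nonsense")
  if (dlen == 0L) {
    if (p_ref == p_alt) return("synonymous")
    if (first_stop(p_alt) != first_stop(p_ref)) return("nonsense")
    return("missense")
  }
  if (first_stop(p_alt) < nchar(p_alt)) return("nonsense")
  if (first_stop(p_ref) <= nchar(p_ref) &&
      first_stop(p_alt) > nchar(p_alt)) {
    return("nonsense")
  }
  "inframe_indel"
}

# build a small panel + VCF on disk; returns paths and truth
make_demo_panel <- function(n = 80, n_hap = 4, n_sites = 10, seed = 1,
                            genome_len = 5000, het_sites = NULL,
                            missing_rate = 0, mean_depth = 60,
                            error_rate = 0) {
  gen <- generate_reference(genome_len, repeat_spec(0), gene_density = 0,
                            seed = seed)
  rh <- random_haplotypes(n_hap, n_sites, seed = seed)
  sp <- panel_spec(n, rh$hap_alleles, rh$freqs,
                   species_of_haplotype = rep(c("cultivated", "wild"),
                                              length.out = n_hap),
                   het_sites = het_sites, mean_depth = mean_depth,
                   missing_rate = missing_rate, error_rate = error_rate,
                   seed = seed)
  set.seed(derive_seed(seed, "demo_pos"))
  pos <- sort(sample(seq_len(genome_len), n_sites))
  truth <- simulate_panel(sp, pos, gen$genome)
  vcf <- tempfile(fileext = ".vcf")
  em <- emit_vcf(truth, vcf)
  list(truth = truth, vcf = vcf, emitted = em, genome = gen$genome,
       freqs = rh$freqs)
}
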