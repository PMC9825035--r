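test_that("linkage_partition groups sites by partition identity", {
  # same partition under different allele labels -> one group
  m <- cbind(c(0L, 0L, 1L, 1L), c(1L, 1L, 0L, 0L))
  ts <- linkage_partition(m)
  expect_length(ts$groups, 1)
  # crossing partitions -> two groups
  m2 <- cbind(c(0L, 0L, 1L, 1L), c(0L, 1L, 0L, 1L))
  expect_length(linkage_partition(m2)$groups, 2)
  # a site observed in <2 accessions is excluded with a warning
  m3 <- cbind(c(0L, 0L, 1L, 1L), c(0L, NA, NA, NA))
  expect_warning(ts3 <- linkage_partition(m3), "<2 accessions")
  expect_equal(ts3$excluded, 2L)
  # monomorphic column dropped
  m4 <- cbind(c(0L, 0L, 1L, 1L), c(0L, 0L, 0L, 0L))
  expect_warning(ts4 <- linkage_partition(m4), "monomorphic")
  expect_length(ts4$groups, 1)
})

test_that("linkage_partition equals the brute-force closure oracle", {
  set.seed(47)
  for (rep_i in 1:25) {
    n <- sample(10:30, 1); S <- sample(4:12, 1)
    base <- matrix(sample(0:2, n * S, replace = TRUE, prob = c(.5, .35, .15)),
                   n, S)
    # plant some perfectly linked column pairs via relabeling
    for (d in seq_len(sample(0:3, 1))) {
      i <- sample(S, 2)
      perm <- sample(0:3)
      base[, i[2]] <- perm[base[, i[1]] + 1L]
    }
    if (sample(c(TRUE, FALSE), 1)) {
      base[sample(length(base), round(0.05 * length(base)))] <- NA
    }
    poly <- apply(base, 2, function(x) length(unique(x[!is.na(x)])) >= 2) &
      colSums(!is.na(base)) >= 2
    if (!any(poly)) next
    got <- suppressWarnings(linkage_partition(base))
    keep <- which(poly)
    want <- oracle_linkage_groups(base[, keep, drop = FALSE])
    # compare as partitions of the kept sites
    got_lab <- integer(length(keep))
    for (gi in seq_along(got$groups)) {
      got_lab[match(got$groups[[gi]], keep)] <- gi
    }
    # same partition iff the label pairing is a bijection
    expect_equal(length(unique(paste(got_lab, want))),
                 length(unique(got_lab)))
    expect_equal(length(unique(got_lab)), length(unique(want)))
  }
})

test_that("tags prefer the leftmost biallelic SNP in each group", {
  sites <- data.frame(pos = c(10L, 20L, 30L), ref = c("AT", "C", "G"))
  sites$alts <- I(list("A", "T", "A"))   # site 1 is an indel
  m <- cbind(c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L), c(0L, 0L, 1L, 1L))
  ts <- linkage_partition(m, sites)
  expect_length(ts$groups, 1)
  expect_equal(ts$tag_of_group, 2L)  # leftmost biallelic SNP, not the indel
})

test_that("assign_haplotypes maps complete accessions and reports missing", {
  m <- rbind(a1 = c(0L, 0L), a2 = c(0L, 0L), a3 = c(1L, 0L),
             a4 = c(1L, NA))
  ht <- assign_haplotypes(m, tags = c(1L, 2L))
  expect_equal(nrow(ht$haplotypes), 2)
  expect_equal(ht$unassigned, "a4")
  expect_true(is.na(ht$assignment["a4"]))
  expect_equal(unname(ht$assignment["a1"]), unname(ht$assignment["a2"]))
  # all identical -> one haplotype
  ht1 <- assign_haplotypes(matrix(1L, 5, 3), tags = 1:3)
  expect_equal(nrow(ht1$haplotypes), 1)
})

test_that("name_haplotypes ranks by naming population with stated ties", {
  m <- rbind(matrix(0L, 500, 2),
             matrix(rep(c(1L, 0L), each = 300), 300, 2),
             matrix(rep(c(1L, 1L), 1), 1, 2))
  rownames(m) <- sprintf("a%03d", seq_len(nrow(m)))
  ht <- assign_haplotypes(m, tags = c(1L, 2L))
  ht <- name_haplotypes(ht, "CT")
  expect_equal(ht$counts$haplotype, c("CT1", "CT2", "CT3"))
  expect_equal(ht$counts$n, c(500L, 300L, 1L))

  # tie in the naming population broken by full-panel count
  m2 <- rbind(matrix(0L, 12, 1), matrix(1L, 10, 1))
  rownames(m2) <- sprintf("b%02d", seq_len(22))
  pop <- c(sprintf("b%02d", 1:10), sprintf("b%02d", 13:22))  # 10 vs 10
  ht2 <- name_haplotypes(assign_haplotypes(m2, 1L), "CT",
                         naming_population = pop)
  expect_equal(ht2$counts$n_naming, c(10L, 10L))
  expect_equal(ht2$counts$n, c(12L, 10L))  # 12 ranks first

  # permutation invariance of naming
  set.seed(53)
  d <- make_demo_panel(n = 60, n_hap = 5, n_sites = 8, seed = 54)
  vd <- read_organelle_vcf(d$vcf)
  calls <- genotype_calls(vd)
  base <- NULL
  for (sh in 1:20) {
    perm <- sample(nrow(calls))
    ht <- suppressWarnings(
      assign_haplotypes(calls[perm, ], linkage_partition(calls[perm, ],
                                                         vd$sites)))
    ht <- name_haplotypes(ht, "CT")
    asg <- ht$assignment[sort(names(ht$assignment))]
    if (is.null(base)) base <- asg else expect_identical(asg, base)
  }
})

test_that("hamming distance is a count of differing sites and symmetric", {
  expect_equal(hamming(c(0L, 1L, 2L), c(0L, 1L, 2L)), 0)
  a <- rep(0L, 27); b <- a; b[c(3, 9, 20)] <- 1L
  expect_equal(hamming(a, b), 3)
  set.seed(59)
  for (i in 1:20) {
    x <- sample(0:3, 15, replace = TRUE)
    y <- sample(0:3, 15, replace = TRUE)
    expect_identical(hamming(x, y), hamming(y, x))
  }
  expect_error(hamming(c(0L, NA), c(0L, 1L)))
})

test_that("build_network is a minimum spanning network", {
  # triangle of equal distances (one triallelic site):
  # 2 primary edges + the third retained as alternative
  calls <- matrix(c(0L, 0L, 0L, 1L, 1L, 2L), ncol = 1)
  rownames(calls) <- sprintf("a%d", 1:6)
  ht <- name_haplotypes(assign_haplotypes(calls, 1L), "CT")
  net <- build_network(ht)
  expect_equal(nrow(net$edges), 2)
  expect_equal(sum(net$edges$steps), 2)
  expect_equal(nrow(net$alternative_edges), 1)
  expect_equal(net$alternative_edges$steps, 1L)

  # single haplotype: one node, no edges
  ht1 <- name_haplotypes(assign_haplotypes(matrix(0L, 4, 2), 1:2), "CT")
  net1 <- build_network(ht1)
  expect_equal(nrow(net1$nodes), 1)
  expect_equal(nrow(net1$edges), 0)

  # primary weight equals igraph's MST weight on random instances
  skip_if_not_installed("igraph")
  set.seed(61)
  for (rep_i in 1:10) {
    H <- sample(4:12, 1)
    hap <- matrix(sample(0:1, H * 10, replace = TRUE), H, 10)
    hap <- unique(hap)
    idx <- sample(nrow(hap), 40, replace = TRUE)
    calls <- hap[idx, , drop = FALSE]
    rownames(calls) <- sprintf("a%02d", seq_len(40))
    ht <- suppressWarnings(
      name_haplotypes(assign_haplotypes(calls,
                                        seq_len(ncol(calls))), "CT"))
    net <- build_network(ht)
    d <- as.matrix(stats::dist(ht$haplotypes, method = "manhattan"))
    gr <- igraph::graph_from_adjacency_matrix(d, weighted = TRUE,
                                              mode = "undirected")
    w_or <- sum(igraph::E(igraph::mst(gr))$weight)
    expect_equal(sum(net$edges$steps), w_or)
    # every alternative edge ties the max edge on its tree path
    expect_true(all(net$alternative_edges$steps >= 1))
  }
})

test_that("cluster_groups recovers planted clusters and labels by size", {
  # two tight clusters far apart
  hap <- rbind(c(rep(0L, 12)), c(1L, rep(0L, 11)),
               c(rep(1L, 12)), c(0L, rep(1L, 11)))
  calls <- hap[c(1, 1, 1, 1, 2, 3, 3, 4), ]
  rownames(calls) <- sprintf("a%d", 1:8)
  ht <- name_haplotypes(assign_haplotypes(calls, 1:12), "CT")
  g <- cluster_groups(ht, 2)
  expect_equal(length(unique(g)), 2)
  # haplotypes 1-2 (5 accessions) together, 3-4 (3 accessions) together
  expect_equal(unname(g[ht$assignment["a1"]]),
               unname(g[ht$assignment["a5"]]))
  expect_equal(unname(g[ht$assignment["a6"]]),
               unname(g[ht$assignment["a8"]]))
  expect_equal(unname(g[ht$assignment["a1"]]), "CTG1")  # bigger group

  expect_equal(length(unique(cluster_groups(ht, nrow(ht$haplotypes)))),
               nrow(ht$haplotypes))
  expect_equal(unname(unique(cluster_groups(ht, 1))), "CTG1")
  expect_error(cluster_groups(ht, 0), "k must be")
  expect_error(cluster_groups(ht, 99), "exceeds")
})

test_that("tag sites preserve the accession partition of all sites", {
  set.seed(67)
  for (rep_i in 1:5) {
    d <- make_demo_panel(n = 80, n_hap = 6, n_sites = 12,
                         seed = 70 + rep_i)
    vd <- read_organelle_vcf(d$vcf)
    calls <- genotype_calls(vd)
    ts <- suppressWarnings(linkage_partition(calls, vd$sites))
    full_part <- apply(calls[, ts$site_index, drop = FALSE], 1,
                       paste, collapse = "|")
    tag_part <- apply(calls[, ts$tag_of_group, drop = FALSE], 1,
                      paste, collapse = "|")
    # identical accession partitions (label pairing is a bijection)
    expect_equal(length(unique(paste(full_part, tag_part))),
                 length(unique(full_part)))
    expect_equal(length(unique(full_part)), length(unique(tag_part)))
    # counts conservation
    ht <- name_haplotypes(assign_haplotypes(calls, ts), "CT")
    expect_equal(sum(ht$counts$n) + length(ht$unassigned), nrow(calls))
    # planted recovery: assignments equal generator truth up to naming
    truth_hap <- d$truth$accessions$haplotype
    expect_equal(length(unique(paste(ht$assignment, truth_hap))),
                 length(unique(truth_hap)))
    expect_equal(length(unique(ht$assignment)),
                 length(unique(truth_hap)))
  }
})
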