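#' Partition polymorphic sites into perfect-linkage groups and pick tags
#'
#' Two sites are perfectly linked when, over all accessions where both are
#' observed, they induce the same partition of accessions (allele labels are
#' irrelevant, i.e. r-squared 1 on complete pairs). The relation is closed
#' transitively; each group is represented by a tag site: its leftmost
#' biallelic SNP, or the leftmost site when the group contains none.
#' Sites observed in fewer than two accessions are excluded with a warning.
#'
#' @param calls Integer accessions x sites matrix of allele indices
#'   (NA = missing). Monomorphic columns are dropped with a warning.
#' @param sites Optional sites data.frame (`pos`, `ref`, `alts`) aligned to
#'   the columns of `calls`; used for tag preference and positions. Without
#'   it, column index stands in for position and every site counts as a
#'   biallelic SNP candidate.
#' @return A `"tag_set"` list: `groups` (list of integer site-index
#'   vectors), `tag_of_group` (integer vector), `site_index` (the columns
#'   kept), `excluded` (dropped columns).
#' @export
linkage_partition <- function(calls, sites = NULL) {
  S_all <- ncol(calls)
  if (S_all < 1L) stop("need at least one site", call. = FALSE)
  n_obs <- colSums(!is.na(calls))
  n_lev <- apply(calls, 2, function(x) length(unique(x[!is.na(x)])))
  drop_few <- n_obs < 2L
  drop_mono <- !drop_few & n_lev < 2L
  if (any(drop_few)) {
    warning(sum(drop_few), " site(s) observed in <2 accessions excluded")
  }
  if (any(drop_mono)) {
    warning(sum(drop_mono), " monomorphic site(s) excluded")
  }
  keep <- which(!(drop_few | drop_mono))
  if (!length(keep)) stop("no usable polymorphic sites", call. = FALSE)
  m <- calls[, keep, drop = FALSE]
  S <- ncol(m)

  # union-find over pairwise perfect-linkage checks
  parent <- seq_len(S)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(S - 1L)) {
    for (j in (i + 1L):S) {
      if (find(i) == find(j)) next
      if (perfectly_linked(m[, i], m[, j])) {
        parent[find(j)] <- find(i)
      }
    }
  }
  root <- vapply(seq_len(S), find, integer(1))
  groups <- split(seq_len(S), root)
  names(groups) <- NULL

  pos <- if (is.null(sites)) seq_len(S_all) else sites$pos
  is_bi_snp <- if (is.null(sites)) rep(TRUE, S_all) else
    vapply(seq_len(nrow(sites)), function(i) {
      length(sites$alts[[i]]) == 1L && nchar(sites$ref[i]) == 1L &&
        nchar(sites$alts[[i]][1]) == 1L
    }, logical(1))

  ord <- order(vapply(groups, function(g) min(pos[keep[g]]), numeric(1)))
  groups <- groups[ord]
  tags <- vapply(groups, function(g) {
    gi <- keep[g]
    cand <- gi[is_bi_snp[gi]]
    if (!length(cand)) cand <- gi
    cand[which.min(pos[cand])]
  }, integer(1))
  groups <- lapply(groups, function(g) keep[g])
  structure(list(groups = groups, tag_of_group = tags, site_index = keep,
                 excluded = which(drop_few | drop_mono)),
            class = "tag_set")
}

# partitions identical over jointly observed accessions: the allele->allele
# mapping must be a bijection in both directions
perfectly_linked <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2L) return(FALSE)
  a <- a[ok]; b <- b[ok]
  length(unique(a)) == length(unique(b)) &&
    length(unique(a)) == length(unique(paste(a, b)))
}

#' Assign each accession its haplotype over the tag sites
#'
#' An accession with complete calls at all tag sites is assigned the
#' distinct allele vector it carries; any missing tag call makes it
#' unassigned (reported, never imputed).
#'
#' @param calls Integer accessions x sites matrix (rownames = accession
#'   ids).
#' @param tags A `"tag_set"` from [linkage_partition()], or an integer
#'   vector of tag column indices.
#' @return A `"haplotype_table"` list: `haplotypes` (matrix haplotype x tag
#'   site allele indices; rownames are names once [name_haplotypes()] has
#'   run), `assignment` (character per accession, NA = unassigned),
#'   `tag_sites` (column indices), `accessions`, `unassigned` (ids).
#'   Haplotype row order is the order of first appearance; naming fixes it.
#' @export
assign_haplotypes <- function(calls, tags) {
  tag_idx <- if (inherits(tags, "tag_set")) tags$tag_of_group else
    as.integer(tags)
  tm <- calls[, tag_idx, drop = FALSE]
  complete <- !apply(tm, 1, anyNA)
  keys <- rep(NA_character_, nrow(tm))
  keys[complete] <- apply(tm[complete, , drop = FALSE], 1, allele_key)
  uniq <- unique(keys[complete])
  hap <- matrix(0L, length(uniq), length(tag_idx),
                dimnames = list(uniq, NULL))
  for (i in seq_along(uniq)) {
    hap[i, ] <- tm[match(uniq[i], keys), ]
  }
  acc <- rownames(calls) %||% sprintf("acc%d", seq_len(nrow(calls)))
  structure(list(haplotypes = hap, assignment = setNames(keys, acc),
                 tag_sites = tag_idx, accessions = acc,
                 unassigned = acc[!complete]),
            class = "haplotype_table")
}

#' Name haplotypes by frequency rank
#'
#' Ranks haplotypes by carrier count within a naming population
#' (descending); ties are broken by count in the full panel, then by
#' lexicographic order of the allele vector. Names are `prefix + rank`
#' (CT1, CT2, ... / MT1, ...).
#'
#' @param ht A `"haplotype_table"`.
#' @param prefix Name prefix, e.g. `"CT"` or `"MT"`.
#' @param naming_population Accession ids whose counts define the ranking;
#'   defaults to all accessions.
#' @return The table with `haplotypes` rows renamed and reordered by rank,
#'   `assignment` mapped to the new names, and a `counts` data.frame
#'   (`haplotype`, `n`, `n_naming`).
#' @export
name_haplotypes <- function(ht, prefix = "CT", naming_population = NULL) {
  stopifnot(inherits(ht, "haplotype_table"))
  keys <- rownames(ht$haplotypes)
  asg <- ht$assignment
  if (is.null(naming_population)) naming_population <- ht$accessions
  in_pop <- names(asg) %in% naming_population
  cnt_pop <- vapply(keys, function(k) sum(asg[in_pop] == k, na.rm = TRUE),
                    integer(1))
  cnt_all <- vapply(keys, function(k) sum(asg == k, na.rm = TRUE),
                    integer(1))
  ord <- order(-cnt_pop, -cnt_all, keys)
  new_names <- paste0(prefix, seq_along(keys))
  hap <- ht$haplotypes[ord, , drop = FALSE]
  rownames(hap) <- new_names
  remap <- setNames(new_names, keys[ord])
  ht$haplotypes <- hap
  ht$assignment <- setNames(unname(remap[asg]), names(asg))
  ht$counts <- data.frame(haplotype = new_names,
                          n = unname(cnt_all[ord]),
                          n_naming = unname(cnt_pop[ord]))
  ht$prefix <- prefix
  ht
}

#' Hamming distance between allele vectors
#'
#' @param a,b Equal-length integer vectors without missing values.
#' @return Number of positions with differing allele indices.
#' @export
hamming <- function(a, b) {
  stopifnot(length(a) == length(b), !anyNA(a), !anyNA(b))
  sum(a != b)
}

hamming_matrix <- function(hap) {
  H <- nrow(hap)
  d <- matrix(0L, H, H, dimnames = list(rownames(hap), rownames(hap)))
  if (H > 1L) {
    for (i in seq_len(H - 1L)) {
      for (j in (i + 1L):H) {
        d[i, j] <- d[j, i] <- hamming(hap[i, ], hap[j, ])
      }
    }
  }
  d
}

#' Build the minimum spanning haplotype network
#'
#' Kruskal's algorithm over pairwise hamming distances with a fully
#' deterministic tie-break (edges sorted by length, then by the frequency
#' ranks of their endpoints) gives the primary edges — a minimum spanning
#' tree. Every non-tree edge whose length equals the maximum edge length on
#' the tree path between its endpoints is retained as an alternative edge
#' (it belongs to some equally minimal spanning tree).
#'
#' @param ht A named `"haplotype_table"` (run [name_haplotypes()] first).
#' @return A `"haplotype_network"` list: `nodes` (data.frame `haplotype`,
#'   `n`), `edges` (data.frame `from`, `to`, `steps`), `alternative_edges`
#'   (same shape).
#' @export
build_network <- function(ht) {
  stopifnot(inherits(ht, "haplotype_table"),
            !is.null(ht$counts))
  hap <- ht$haplotypes
  H <- nrow(hap)
  nm <- rownames(hap)
  d <- hamming_matrix(hap)
  nodes <- data.frame(haplotype = nm,
                      n = ht$counts$n[match(nm, ht$counts$haplotype)])
  if (H <= 1L) {
    e <- data.frame(from = character(), to = character(), steps = integer())
    return(structure(list(nodes = nodes, edges = e, alternative_edges = e),
                     class = "haplotype_network"))
  }
  ij <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[ij], ij[, 1], ij[, 2])
  ij <- ij[ord, , drop = FALSE]
  w <- d[ij]

  parent <- seq_len(H)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  in_tree <- logical(nrow(ij))
  for (e in seq_len(nrow(ij))) {
    ri <- find(ij[e, 1]); rj <- find(ij[e, 2])
    if (ri != rj) { parent[ri] <- rj; in_tree[e] <- TRUE }
  }

  # adjacency of the tree for path-max queries (H is small)
  adj <- vector("list", H)
  for (e in which(in_tree)) {
    i <- ij[e, 1]; j <- ij[e, 2]
    adj[[i]] <- rbind(adj[[i]], c(j, w[e]))
    adj[[j]] <- rbind(adj[[j]], c(i, w[e]))
  }
  path_max <- function(a, b) {
    # DFS from a to b, tracking the max edge weight
    seen <- logical(H)
    stack <- list(list(node = a, mx = 0L))
    seen[a] <- TRUE
    while (length(stack)) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (cur$node == b) return(cur$mx)
      for (r in seq_len(NROW(adj[[cur$node]]))) {
        nb <- adj[[cur$node]][r, 1]
        if (!seen[nb]) {
          seen[nb] <- TRUE
          stack[[length(stack) + 1L]] <-
            list(node = nb, mx = max(cur$mx, adj[[cur$node]][r, 2]))
        }
      }
    }
    stop("tree not connected")  # cannot happen
  }
  alt <- !in_tree & vapply(seq_len(nrow(ij)), function(e) {
    !in_tree[e] && w[e] == path_max(ij[e, 1], ij[e, 2])
  }, logical(1))

  mk <- function(sel) data.frame(from = nm[ij[sel, 1]], to = nm[ij[sel, 2]],
                                 steps = w[sel])
  structure(list(nodes = nodes, edges = mk(in_tree),
                 alternative_edges = mk(alt)),
            class = "haplotype_network")
}

#' Cluster haplotypes into groups
#'
#' Average-linkage agglomerative clustering of the hamming distance matrix,
#' cut at `k` clusters. Groups are labeled `prefix + "G" + rank` by
#' descending total accession count (the group carrying the most accessions
#' is group 1; ties by smallest member rank).
#'
#' @param ht A named `"haplotype_table"`.
#' @param k Number of groups (1 <= k <= number of haplotypes).
#' @param prefix Label prefix; defaults to the table's naming prefix.
#' @return A named character vector: haplotype name -> group label.
#' @export
cluster_groups <- function(ht, k, prefix = NULL) {
  stopifnot(inherits(ht, "haplotype_table"), !is.null(ht$counts))
  H <- nrow(ht$haplotypes)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k > H) stop("k exceeds number of haplotypes", call. = FALSE)
  prefix <- prefix %||% paste0(ht$prefix %||% "CT", "G")
  nm <- rownames(ht$haplotypes)
  if (H == 1L) return(setNames(paste0(prefix, 1L), nm))
  d <- hamming_matrix(ht$haplotypes)
  cl <- cutree(hclust(as.dist(d), method = "average"), k = k)
  cnt <- ht$counts$n[match(nm, ht$counts$haplotype)]
  tot <- tapply(cnt, cl, sum)
  first <- tapply(seq_len(H), cl, min)
  rank <- order(-as.vector(tot), as.vector(first))
  lab <- integer(length(tot))
  lab[rank] <- seq_along(tot)
  setNames(paste0(prefix, lab[match(cl, as.integer(names(tot)))]), nm)
}

#' Write the haplotype definition and network tables
#'
#' @param ht A named `"haplotype_table"`.
#' @param sites Sites data.frame aligned with the call matrix columns.
#' @param path Output TSV path (haplotype x tag-site allele, REF/ALT
#'   rendered as allele strings).
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(ht, sites, path) {
  tag <- ht$tag_sites
  cols <- paste0("p.", sites$pos[tag])
  alle <- vapply(seq_along(tag), function(j) {
    s <- tag[j]
    all_alleles <- c(sites$ref[s], sites$alts[[s]])
    all_alleles[ht$haplotypes[, j] + 1L]
  }, character(nrow(ht$haplotypes)))
  alle <- matrix(alle, nrow = nrow(ht$haplotypes))
  df <- data.frame(haplotype = rownames(ht$haplotypes),
                   n = ht$counts$n[match(rownames(ht$haplotypes),
                                         ht$counts$haplotype)])
  df <- cbind(df, setNames(as.data.frame(alle), cols))
  write_tsv(df, path)
}

#' Write a haplotype network as an edge-list TSV and simple GML
#'
#' @param net A `"haplotype_network"`.
#' @param tsv Edge-list TSV path (`from`, `to`, `steps`, `kind`).
#' @param gml Optional GML path.
#' @return `tsv`, invisibly.
#' @export
write_network <- function(net, tsv, gml = NULL) {
  edges <- rbind(
    data.frame(net$edges, kind = rep("primary", nrow(net$edges))),
    data.frame(net$alternative_edges,
               kind = rep("alternative", nrow(net$alternative_edges))))
  write_tsv(edges, tsv)
  if (!is.null(gml)) {
    id <- setNames(seq_len(nrow(net$nodes)) - 1L, net$nodes$haplotype)
    lines <- c("graph [", "  directed 0")
    for (i in seq_len(nrow(net$nodes))) {
      lines <- c(lines, "  node [",
                 paste0("    id ", id[net$nodes$haplotype[i]]),
                 paste0("    label \"", net$nodes$haplotype[i], "\""),
                 paste0("    count ", net$nodes$n[i]), "  ]")
    }
    for (i in seq_len(nrow(edges))) {
      lines <- c(lines, "  edge [",
                 paste0("    source ", id[edges$from[i]]),
                 paste0("    target ", id[edges$to[i]]),
                 paste0("    value ", edges$steps[i]),
                 paste0("    kind \"", edges$kind[i], "\""), "  ]")
    }
    writeLines(c(lines, "]"), gml)
  }
  invisible(tsv)
}
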