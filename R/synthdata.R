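#' Specification of repeats to plant in a synthetic reference
#'
#' @param n_pairs Number of repeat pairs to plant.
#' @param unit_length Length of each repeat copy in bp (>= 1).
#' @param identity Sequence identity between the two copies, in \[0,1\].
#' @param inverted_fraction Fraction of pairs planted in inverted
#'   orientation (count is `round(n_pairs * inverted_fraction)`).
#' @return A `"repeat_spec"` list.
#' @export
repeat_spec <- function(n_pairs = 0, unit_length = 1000, identity = 1,
                        inverted_fraction = 0) {
  stopifnot(n_pairs >= 0, unit_length >= 1,
            identity >= 0, identity <= 1,
            inverted_fraction >= 0, inverted_fraction <= 1)
  structure(list(n_pairs = as.integer(n_pairs),
                 unit_length = as.integer(unit_length),
                 identity = identity,
                 inverted_fraction = inverted_fraction),
            class = "repeat_spec")
}

#' Generate a synthetic organelle reference with planted repeats and genes
#'
#' Produces a uniform-random circular genome, copies `n_pairs` repeat units
#' into non-overlapping positions (optionally inverted, optionally with
#' point mutations down to the requested identity), and plants
#' non-overlapping single-CDS genes (ATG start, internal-stop-free codons,
#' terminal stop) clear of the repeat regions so translation-based effect
#' annotation is well defined. Deterministic given `seed`.
#'
#' @param length Genome length in bp (>= 1000).
#' @param rep_spec A [repeat_spec()].
#' @param gene_density Genes per kb (default 0.5).
#' @param seed Integer seed.
#' @param name Contig name.
#' @param circular Circularity flag recorded on the reference.
#' @param max_tries Retry budget for non-overlapping placement.
#' @return A list: `genome` (a `"genome_ref"`) and `repeats` (data.frame of
#'   planted pairs: `a_start`, `a_end`, `b_start`, `b_end` 0-based
#'   half-open, `strand`, `identity`).
#' @export
generate_reference <- function(length, rep_spec = repeat_spec(),
                               gene_density = 0.5, seed = 1,
                               name = "organelle", circular = TRUE,
                               max_tries = 500) {
  stopifnot(length >= 1000)
  u <- rep_spec$unit_length
  if (2L * rep_spec$n_pairs * u > length) {
    stop("planted repeats (", 2L * rep_spec$n_pairs * u,
         " bp) exceed genome length", call. = FALSE)
  }
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  seqv <- sample(bases, length, replace = TRUE)

  occupied <- IRanges::IRanges()
  place <- function(w) {
    for (t in seq_len(max_tries)) {
      s <- sample.int(length - w + 1L, 1L)
      cand <- IRanges::IRanges(s, s + w - 1L)
      if (!IRanges::overlapsAny(cand, occupied)) {
        occupied <<- c(occupied, cand)
        return(s)
      }
    }
    NA_integer_
  }

  n_inv <- round(rep_spec$n_pairs * rep_spec$inverted_fraction)
  reps <- empty_pairs()
  for (p in seq_len(rep_spec$n_pairs)) {
    a <- place(u); b <- place(u)
    if (is.na(a) || is.na(b)) {
      stop(sprintf("could not place repeat pair %d without overlap in %d tries",
                   p, max_tries), call. = FALSE)
    }
    unit <- seqv[a:(a + u - 1L)]
    copy <- unit
    n_mut <- round((1 - rep_spec$identity) * u)
    if (n_mut > 0) {
      at <- sample.int(u, n_mut)
      copy[at] <- vapply(copy[at], function(x) sample(setdiff(bases, x), 1L),
                         character(1))
    }
    inverted <- p <= n_inv
    if (inverted) copy <- strsplit(revcomp(paste(copy, collapse = "")),
                                   "")[[1]]
    seqv[b:(b + u - 1L)] <- copy
    reps <- rbind(reps, data.frame(
      a_start = min(a, b) - 1L, a_end = min(a, b) - 1L + u,
      b_start = max(a, b) - 1L, b_end = max(a, b) - 1L + u,
      strand = if (inverted) "inverted" else "same",
      length = u, identity = rep_spec$identity))
  }

  n_genes <- round(length / 1000 * gene_density)
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  genes <- empty_genes()
  for (g in seq_len(n_genes)) {
    n_cod <- sample(100:300, 1L)           # 300-900 bp CDS
    w <- 3L * (n_cod + 2L)                 # + start and stop codons
    s <- place(w)
    if (is.na(s)) next                     # genome too crowded; skip quietly
    strand <- sample(c("+", "-"), 1L)
    cds <- paste0("ATG", paste(sample(sense, n_cod, replace = TRUE),
                               collapse = ""), "TAA")
    if (strand == "-") cds <- revcomp(cds)
    seqv[s:(s + w - 1L)] <- strsplit(cds, "")[[1]]
    genes <- rbind(genes, data.frame(gene_id = sprintf("gene%02d", g),
                                     start = s, end = s + w - 1L,
                                     strand = strand, phase = 0L))
  }
  genes <- genes[order(genes$start), , drop = FALSE]
  rownames(genes) <- NULL
  list(genome = genome_ref(name, paste(seqv, collapse = ""), circular,
                           genes),
       repeats = reps)
}

#' Specification of a synthetic accession panel
#'
#' Describes a panel whose organelle genotypes are drawn from a small set of
#' haplotypes with (typically strongly skewed) frequencies, with optional
#' heteroplasmic sites carrying a target reference allele frequency (RAF).
#'
#' @param n_accessions Panel size.
#' @param haplotype_allele_matrix Integer haplotypes x sites matrix of
#'   0-based allele indices (0 = REF).
#' @param haplotype_freqs Probability vector over haplotypes (sums to 1).
#' @param species_of_haplotype Character per haplotype: `"wild"`,
#'   `"cultivated"` or `"shared"`.
#' @param het_sites Optional data.frame (`site`, `raf`, optional `alt`
#'   1-based alt index, default 1): sites emitted with binomial allele-depth
#'   mixing at the target RAF in every accession.
#' @param mean_depth Mean sequencing depth per site per accession.
#' @param missing_rate Per-call missing probability.
#' @param error_rate Per-read probability of a miscalled allele.
#' @param seed Integer seed.
#' @return A `"panel_spec"` list.
#' @export
panel_spec <- function(n_accessions, haplotype_allele_matrix,
                       haplotype_freqs,
                       species_of_haplotype = NULL,
                       het_sites = NULL, mean_depth = 60,
                       missing_rate = 0, error_rate = 0.002, seed = 1) {
  H <- nrow(haplotype_allele_matrix)
  stopifnot(n_accessions >= 1, H >= 1,
            length(haplotype_freqs) == H,
            abs(sum(haplotype_freqs) - 1) <= 1e-9,
            all(haplotype_freqs >= 0),
            all(haplotype_allele_matrix >= 0),
            mean_depth >= 1, missing_rate >= 0, missing_rate < 1)
  if (is.null(species_of_haplotype)) {
    species_of_haplotype <- rep("cultivated", H)
  }
  stopifnot(length(species_of_haplotype) == H,
            all(species_of_haplotype %in% c("wild", "cultivated", "shared")))
  if (!is.null(het_sites)) {
    stopifnot(all(het_sites$raf >= 0), all(het_sites$raf <= 1),
              all(het_sites$site >= 1),
              all(het_sites$site <= ncol(haplotype_allele_matrix)))
    if (is.null(het_sites$alt)) het_sites$alt <- 1L
  }
  structure(list(n_accessions = as.integer(n_accessions),
                 hap_alleles = haplotype_allele_matrix,
                 haplotype_freqs = haplotype_freqs,
                 species_of_haplotype = species_of_haplotype,
                 het_sites = het_sites, mean_depth = mean_depth,
                 missing_rate = missing_rate, error_rate = error_rate,
                 seed = as.integer(seed)),
            class = "panel_spec")
}

# Default geography tables: a China-majority panel shaped like a worldwide
# soybean collection (about two thirds China, a sixth of unknown origin),
# without claiming realism. Wild accessions are drawn from the same table.
default_geo_table <- function() {
  list(
    country = c(China = 0.666, USA = 0.070, Japan = 0.028,
                `South Korea` = 0.018, Russia = 0.016, `North Korea` = 0.004,
                Other = 0.018, unknown = 0.180),
    region_china = c(NE = 0.45, HS = 0.45, unknown = 0.10),
    province = list(
      NE = c("Heilongjiang", "Jilin", "Liaoning"),
      HS = c("Shandong", "Henan", "Hebei", "Jiangsu"),
      unknown = "unknown"))
}

#' Simulate a panel with planted truth
#'
#' Accession haplotypes are drawn i.i.d. from `haplotype_freqs`; species,
#' improvement status and geography are assigned from the haplotype's
#' species label and a configurable categorical table. All truth needed to
#' verify downstream recovery is recorded.
#'
#' @param spec A [panel_spec()].
#' @param site_positions 1-based positions of the polymorphic sites
#'   (strictly increasing after sorting; one per column of the allele
#'   matrix).
#' @param ref_genome A `"genome_ref"`.
#' @param geo Geography tables (see `default_geo_table()`).
#' @param alt_alleles Optional list (per site) of alt allele strings; by
#'   default SNP alts are sampled for every allele index used.
#' @return A `"panel_truth"` list: `spec`, `accessions` (data.frame with
#'   `accession`, `haplotype`, `species`, `status`, `country`, `region`,
#'   `province`), `sites` (data.frame `pos`, `ref`, `alts` list-column),
#'   `hap_alleles`, `het_sites`, `contig`, `contig_length`.
#' @export
simulate_panel <- function(spec, site_positions, ref_genome,
                           geo = default_geo_table(), alt_alleles = NULL) {
  stopifnot(inherits(spec, "panel_spec"), inherits(ref_genome, "genome_ref"))
  S <- ncol(spec$hap_alleles)
  stopifnot(length(site_positions) == S)
  if (any(site_positions < 1) || any(site_positions > ref_genome$length)) {
    stop("site positions outside [1, genome length]", call. = FALSE)
  }
  ord <- order(site_positions)
  site_positions <- site_positions[ord]
  hap_alleles <- spec$hap_alleles[, ord, drop = FALSE]
  het <- spec$het_sites
  if (!is.null(het)) het$site <- match(het$site, ord)
  if (anyDuplicated(site_positions)) {
    stop("duplicate site positions", call. = FALSE)
  }
  if (!is.null(het) && nrow(het)) {
    # a heteroplasmic site carries within-individual mixture, not
    # between-haplotype variation: it does not discriminate haplotypes
    hap_alleles[, het$site] <- 0L
    if (anyDuplicated(apply(hap_alleles, 1, allele_key))) {
      stop("haplotypes no longer pairwise distinct after reserving ",
           "heteroplasmic sites; add discriminating sites", call. = FALSE)
    }
  }
  set.seed(derive_seed(spec$seed, "panel"))
  H <- nrow(hap_alleles)
  n <- spec$n_accessions

  refbase <- substring(ref_genome$seq, site_positions, site_positions)
  bases <- c("A", "C", "G", "T")
  alts <- lapply(seq_len(S), function(j) {
    n_alt <- max(1L, max(hap_alleles[, j]))
    if (!is.null(alt_alleles)) return(alt_alleles[[ord[j]]][seq_len(n_alt)])
    pool <- setdiff(bases, refbase[j])
    sample(pool, n_alt)
  })

  hap <- sample.int(H, n, replace = TRUE, prob = spec$haplotype_freqs)
  species <- spec$species_of_haplotype[hap]
  shared <- species == "shared"
  if (any(shared)) {
    species[shared] <- sample(c("cultivated", "wild"), sum(shared),
                              replace = TRUE, prob = c(0.7, 0.3))
  }
  status <- ifelse(species == "wild", "wild",
                   sample(c("landrace", "elite"), n, replace = TRUE))
  country <- sample(names(geo$country), n, replace = TRUE,
                    prob = geo$country)
  region <- ifelse(country == "China",
                   sample(names(geo$region_china), n, replace = TRUE,
                          prob = geo$region_china),
                   "unknown")
  province <- vapply(region, function(r) {
    p <- geo$province[[r]] %||% "unknown"
    p[sample.int(length(p), 1L)]
  }, character(1))

  accs <- data.frame(accession = sprintf("ACC%04d", seq_len(n)),
                     haplotype = hap, species = species, status = status,
                     country = country, region = region,
                     province = unname(province))
  sites <- data.frame(pos = site_positions, ref = refbase)
  sites$alts <- I(alts)
  out <- list(spec = spec, accessions = accs, sites = sites,
              hap_alleles = hap_alleles, het_sites = het,
              contig = ref_genome$name, contig_length = ref_genome$length)
  class(out) <- "panel_truth"
  out
}

#' Emit the panel as a multi-sample VCF with GT and AD
#'
#' Homozygous calls get a Poisson total depth concentrated on the true
#' allele, with each read miscalled with probability `error_rate`.
#' Heteroplasmic sites get `AD_ref ~ Binomial(depth, RAF)` against the
#' designated alt allele and a heterozygous GT. Missing calls (GT `./.`,
#' AD `.`) are planted at `missing_rate`.
#'
#' @param truth A `"panel_truth"` from [simulate_panel()].
#' @param path Output VCF path.
#' @param mean_depth,missing_rate,error_rate,seed Override the values in
#'   `truth$spec` when given.
#' @return Invisibly, a list with `path`, the truth genotype matrix
#'   (`calls`, samples x sites allele indices), the missing mask and the
#'   per-accession true RAF matrix for het sites.
#' @export
emit_vcf <- function(truth, path, mean_depth = NULL, missing_rate = NULL,
                     error_rate = NULL, seed = NULL) {
  stopifnot(inherits(truth, "panel_truth"))
  sp <- truth$spec
  mean_depth <- mean_depth %||% sp$mean_depth
  missing_rate <- missing_rate %||% sp$missing_rate
  error_rate <- error_rate %||% sp$error_rate
  seed <- seed %||% sp$seed
  stopifnot(mean_depth >= 1)
  set.seed(derive_seed(seed, "vcf"))

  n <- nrow(truth$accessions)
  S <- nrow(truth$sites)
  samples <- truth$accessions$accession
  calls <- truth$hap_alleles[truth$accessions$haplotype, , drop = FALSE]
  dimnames(calls) <- list(samples, NULL)
  het_idx <- if (is.null(truth$het_sites)) integer() else
    truth$het_sites$site
  raf_truth <- NULL
  if (length(het_idx)) {
    raf_truth <- matrix(rep(truth$het_sites$raf, each = n), nrow = n,
                        dimnames = list(samples, NULL))
  }

  gt <- matrix("", n, S)
  ad <- vector("list", S)
  missing <- matrix(FALSE, n, S, dimnames = list(samples, NULL))
  for (j in seq_len(S)) {
    n_all <- 1L + length(truth$sites$alts[[j]])
    D <- rpois(n, mean_depth)
    adj <- matrix(0L, n, n_all)
    hj <- match(j, het_idx)
    if (!is.na(hj)) {
      ai <- truth$het_sites$alt[hj] # 1-based alt index
      dref <- rbinom(n, D, raf_truth[, hj])
      adj[, 1L] <- dref
      adj[, ai + 1L] <- D - dref
      gt[, j] <- paste0("0/", ai)
    } else {
      a <- calls[, j]
      err <- rbinom(n, D, error_rate)
      adj[cbind(seq_len(n), a + 1L)] <- D - err
      if (n_all > 1L) {
        for (i in which(err > 0L)) {
          wrong <- sample(setdiff(seq_len(n_all), a[i] + 1L), err[i],
                          replace = TRUE)
          tab <- tabulate(wrong, nbins = n_all)
          adj[i, ] <- adj[i, ] + tab
        }
      } else {
        adj[, 1L] <- D
      }
      gt[, j] <- as.character(a)
    }
    if (missing_rate > 0) {
      mis <- runif(n) < missing_rate
      gt[mis, j] <- "./."
      adj[mis, ] <- NA_integer_
      missing[mis, j] <- TRUE
    }
    ad[[j]] <- adj
  }
  write_organelle_vcf(truth$sites, gt, ad, samples, truth$contig,
                      truth$contig_length, path)
  invisible(list(path = path, calls = calls, missing = missing,
                 raf_truth = raf_truth))
}

#' Serialize panel truth to JSON (lossless round-trip)
#'
#' @param truth A `"panel_truth"`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  x <- list(accessions = truth$accessions,
            sites = data.frame(pos = truth$sites$pos,
                               ref = truth$sites$ref,
                               alts = vapply(truth$sites$alts, paste,
                                             character(1), collapse = ",")),
            hap_alleles = truth$hap_alleles,
            het_sites = truth$het_sites,
            contig = truth$contig, contig_length = truth$contig_length,
            spec = list(n_accessions = truth$spec$n_accessions,
                        haplotype_freqs = truth$spec$haplotype_freqs,
                        species_of_haplotype = truth$spec$species_of_haplotype,
                        mean_depth = truth$spec$mean_depth,
                        missing_rate = truth$spec$missing_rate,
                        error_rate = truth$spec$error_rate,
                        seed = truth$spec$seed))
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read panel truth back from JSON
#'
#' @param path JSON path written by [write_truth()].
#' @return A `"panel_truth"` list.
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sites <- data.frame(pos = x$sites$pos, ref = x$sites$ref)
  sites$alts <- I(strsplit(x$sites$alts, ",", fixed = TRUE))
  het <- x$het_sites
  if (!is.null(het) && !is.data.frame(het)) het <- as.data.frame(het)
  out <- list(spec = panel_spec(
                n_accessions = x$spec$n_accessions,
                haplotype_allele_matrix = x$hap_alleles,
                haplotype_freqs = x$spec$haplotype_freqs,
                species_of_haplotype = x$spec$species_of_haplotype,
                het_sites = het, mean_depth = x$spec$mean_depth,
                missing_rate = x$spec$missing_rate,
                error_rate = x$spec$error_rate, seed = x$spec$seed),
              accessions = x$accessions, sites = sites,
              hap_alleles = x$hap_alleles, het_sites = het,
              contig = x$contig, contig_length = x$contig_length)
  class(out) <- "panel_truth"
  out
}

#' Random haplotype set with paper-like skew
#'
#' Convenience builder for tests and demos: draws `n_hap` pairwise-distinct
#' allele vectors over `n_sites` biallelic sites and a strongly skewed
#' frequency vector (the two leading haplotypes carrying roughly 70% and
#' 18% of the panel, mirroring a domesticated-crop organelle panel).
#'
#' @param n_hap Number of haplotypes.
#' @param n_sites Number of polymorphic sites.
#' @param skew Base frequencies for the leading haplotypes; the remainder is
#'   spread geometrically over the rest and renormalized.
#' @param seed Integer seed.
#' @return List `hap_alleles` (matrix), `freqs` (vector).
#' @export
random_haplotypes <- function(n_hap, n_sites, skew = c(0.70, 0.18),
                              seed = 1) {
  stopifnot(n_hap >= 1, n_sites >= 1, n_hap <= 2^n_sites)
  set.seed(derive_seed(seed, "haps"))
  seen <- character()
  m <- matrix(0L, n_hap, n_sites)
  i <- 1L
  while (i <= n_hap) {
    v <- sample(0:1, n_sites, replace = TRUE)
    k <- allele_key(v)
    if (!k %in% seen) {
      m[i, ] <- v; seen <- c(seen, k); i <- i + 1L
    }
  }
  if (n_hap <= length(skew)) {
    freqs <- skew[seq_len(n_hap)] / sum(skew[seq_len(n_hap)])
  } else {
    rest <- 0.85^seq_len(n_hap - length(skew))
    rest <- rest / sum(rest) * (1 - sum(skew))
    freqs <- c(skew, rest)
  }
  list(hap_alleles = m, freqs = freqs)
}
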