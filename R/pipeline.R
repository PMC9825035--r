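#' Default pipeline configuration
#'
#' Flat key-value configuration for the end-to-end run. Two organelles are
#' simulated and analyzed: a chloroplast-like contig (`CHL`, haplotype
#' prefix CT) and a mitochondrion-like contig (`MIT`, prefix MT), at scales
#' small enough for a laptop demo.
#'
#' @param ... Overrides of the defaults, as `name = value`.
#' @return Named list of class `"run_config"`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_accessions = 300L,
    chl_length = 15000L, chl_repeat_pairs = 1L, chl_repeat_len = 1500L,
    mit_length = 30000L, mit_repeat_pairs = 3L, mit_repeat_len = 2000L,
    chl_n_hap = 10L, chl_n_sites = 20L,
    mit_n_hap = 8L, mit_n_sites = 16L,
    mean_depth = 60, missing_rate = 0, error_rate = 0.002,
    min_len = 100L, min_identity = 0.95,
    k_groups = 4L,
    naming_population = "cultivated",
    min_depth = 10L, het_band_lo = 0.05, het_band_hi = 0.95,
    het_raf = c(0.664, 0.7))
  ov <- list(...)
  cfg[names(ov)] <- ov
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a flat key-value config file
#'
#' Lines of the form `key = value`; numeric-looking values are parsed as
#' numbers, comma-separated values as vectors. Round-trips losslessly.
#'
#' @param path Config file path.
#' @return A `"run_config"` list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  kv <- strsplit(lines, "=", fixed = TRUE)
  cfg <- default_config()
  for (p in kv) {
    key <- trimws(p[1])
    val <- trimws(paste(p[-1], collapse = "="))
    parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(parts))
    cfg[[key]] <- if (anyNA(num)) parts else num
  }
  class(cfg) <- "run_config"
  cfg
}

#' @rdname read_config
#' @param cfg A `"run_config"`.
#' @export
write_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k) {
    paste0(k, " = ", paste(cfg[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_accessions >= 2, cfg$mean_depth >= 1,
            cfg$min_len >= 8, cfg$min_identity > 0, cfg$min_identity <= 1,
            cfg$k_groups >= 1, cfg$min_depth >= 1,
            cfg$het_band_lo < cfg$het_band_hi,
            all(cfg$het_raf >= 0), all(cfg$het_raf <= 1),
            cfg$missing_rate >= 0, cfg$missing_rate < 1)
  invisible(cfg)
}

log_stage <- function(stage, msg, verbose = TRUE) {
  if (verbose) {
    message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", msg)
  }
}

#' Run the full synthetic-panel pipeline
#'
#' simulate -> mask -> stats -> haplotype (CHL and MIT) -> cytoplasm ->
#' raf, writing every product to `out_dir` and returning a manifest with
#' md5 checksums. Deterministic given the config seed (each stage derives
#' its own seed from it).
#'
#' @param config A `"run_config"` (see [default_config()]) or a path to a
#'   config file.
#' @param out_dir Output directory (created if needed).
#' @param verbose Log stage progress?
#' @return A list: `manifest` (data.frame `file`, `md5`), `summary`
#'   (per-stage headline numbers), `recovery` (fraction of accessions whose
#'   haplotype assignment matches planted truth, per organelle).
#' @export
run_pipeline <- function(config = default_config(), out_dir = tempfile(),
                         verbose = TRUE) {
  cfg <- if (is.character(config)) read_config(config) else config
  validate_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  add <- function(...) files <<- c(files, file.path(out_dir, c(...)))
  summary <- list()
  recovery <- c(CHL = NA_real_, MIT = NA_real_)

  organelles <- list(
    CHL = list(prefix = "CT", length = cfg$chl_length,
               n_pairs = cfg$chl_repeat_pairs, rep_len = cfg$chl_repeat_len,
               n_hap = cfg$chl_n_hap, n_sites = cfg$chl_n_sites,
               het = FALSE),
    MIT = list(prefix = "MT", length = cfg$mit_length,
               n_pairs = cfg$mit_repeat_pairs, rep_len = cfg$mit_repeat_len,
               n_hap = cfg$mit_n_hap, n_sites = cfg$mit_n_sites,
               het = TRUE))

  ca_tables <- list()
  meta <- NULL
  for (org in names(organelles)) {
    o <- organelles[[org]]
    seed_o <- derive_seed(cfg$seed, org)

    ## --- simulate -----------------------------------------------------
    log_stage("simulate", paste0(org, ": reference + panel"), verbose)
    refspec <- repeat_spec(n_pairs = o$n_pairs, unit_length = o$rep_len,
                           identity = 1, inverted_fraction = 0.5)
    gen <- generate_reference(o$length, refspec, gene_density = 0.4,
                              seed = seed_o, name = org)
    rh <- random_haplotypes(o$n_hap, o$n_sites, seed = seed_o)
    species_lab <- c(rep("cultivated", ceiling(o$n_hap * 0.6)),
                     rep("wild", floor(o$n_hap * 0.4)))
    # polymorphic sites outside planted repeats so masking keeps them
    mask0 <- build_mask(gen$repeats, o$length)
    free <- setdiff(seq_len(o$length),
                    unlist(lapply(seq_len(nrow(mask0$intervals)), function(i)
                      (mask0$intervals$start[i] + 1L):mask0$intervals$end[i])))
    set.seed(derive_seed(seed_o, "sites"))
    positions <- sort(sample(free, o$n_sites))
    het_sites <- NULL
    if (o$het) {
      het_sites <- data.frame(site = seq_along(cfg$het_raf),
                              raf = cfg$het_raf)
    }
    spec <- panel_spec(cfg$n_accessions, rh$hap_alleles, rh$freqs,
                       species_of_haplotype = species_lab,
                       het_sites = het_sites, mean_depth = cfg$mean_depth,
                       missing_rate = cfg$missing_rate,
                       error_rate = cfg$error_rate, seed = seed_o)
    truth <- simulate_panel(spec, positions, gen$genome)
    fa <- file.path(out_dir, paste0(org, ".fasta"))
    gff <- file.path(out_dir, paste0(org, ".gff3"))
    write_genome(gen$genome, fa, gff)
    vcf_path <- file.path(out_dir, paste0(org, ".vcf"))
    emit_vcf(truth, vcf_path)
    write_truth(truth, file.path(out_dir, paste0(org, "_truth.json")))
    add(paste0(org, c(".fasta", ".gff3", ".vcf", "_truth.json")))
    if (is.null(meta)) {
      meta <- truth$accessions[, c("accession", "species", "status",
                                   "country", "region", "province")]
      write_tsv(meta, file.path(out_dir, "metadata.tsv"))
      add("metadata.tsv")
    }

    ## --- mask ---------------------------------------------------------
    log_stage("mask", paste0(org, ": repeat detection"), verbose)
    pairs <- find_repeats(gen$genome$seq, min_len = cfg$min_len,
                          min_identity = cfg$min_identity, circular = TRUE)
    mask <- build_mask(pairs, o$length)
    write_bed(mask, org, file.path(out_dir, paste0(org, "_mask.bed")))
    add(paste0(org, "_mask.bed"))

    ## --- stats --------------------------------------------------------
    log_stage("stats", paste0(org, ": variant classification"), verbose)
    vcfdata <- read_organelle_vcf(vcf_path)
    kept <- filter_variants(vcfdata$sites, mask)
    effects <- annotate_effect(kept, gen$genome,
                               code = if (org == "CHL") "11" else "1")
    summ <- summarize_variants(kept, effects)
    write_tsv(summ$counts, file.path(out_dir, paste0(org, "_stats.tsv")))
    write_tsv(effects, file.path(out_dir, paste0(org, "_effects.tsv")))
    add(paste0(org, c("_stats.tsv", "_effects.tsv")))
    summary[[org]] <- c(masked_fraction = masked_fraction(mask),
                        n_sites = nrow(kept), ts_tv = summ$counts$ts_tv)

    ## --- haplotype ----------------------------------------------------
    log_stage("haplotype", paste0(org, ": tag sites + assignment"),
              verbose)
    keep_idx <- match(kept$pos, vcfdata$sites$pos)
    calls <- genotype_calls(vcfdata)[, keep_idx, drop = FALSE]
    # heteroplasmic binomial sites are not haplotype-informative here:
    # their calls collapse to the majority allele by design
    tags <- suppressWarnings(linkage_partition(calls, kept))
    ht <- assign_haplotypes(calls, tags)
    naming <- meta$accession[meta$species %in% cfg$naming_population]
    if (!length(naming)) naming <- meta$accession
    ht <- name_haplotypes(ht, prefix = o$prefix,
                          naming_population = naming)
    groups <- cluster_groups(ht, k = min(cfg$k_groups,
                                         nrow(ht$haplotypes)))
    net <- build_network(ht)
    write_haplotype_table(ht, kept,
                          file.path(out_dir, paste0(org, "_haplotypes.tsv")))
    write_network(net, file.path(out_dir, paste0(org, "_network.tsv")),
                  file.path(out_dir, paste0(org, "_network.gml")))
    add(paste0(org, c("_haplotypes.tsv", "_network.tsv", "_network.gml")))
    ca_tables[[org]] <- list(ht = ht, groups = groups, truth = truth,
                             vcfdata = vcfdata, kept = kept)

    ## recovery against planted truth (complete-data accessions)
    tr <- truth$accessions
    true_key <- apply(truth$hap_alleles[tr$haplotype, keep_positions(
      truth$sites$pos, kept$pos), drop = FALSE], 1, allele_key)
    asg <- ht$assignment[tr$accession]
    byname <- split(true_key, asg)
    consistent <- vapply(byname, function(k) length(unique(k)) == 1L,
                         logical(1))
    recovery[org] <- mean(!is.na(asg)) * as.numeric(all(consistent))
  }

  ## --- cytoplasm ------------------------------------------------------
  log_stage("cytoplasm", "joint CT/MT typing", verbose)
  ca <- join_assignments(ca_tables$CHL$ht, ca_tables$MIT$ht, meta,
                         ct_groups = ca_tables$CHL$groups,
                         mt_groups = ca_tables$MIT$groups)
  write_tsv(ca$assignments, file.path(out_dir, "cytoplasm.tsv"))
  write_tsv(distribution_table(ca, by = "country", level = "joint"),
            file.path(out_dir, "cytoplasm_by_country.tsv"))
  write_tsv(diversity_summary(ca, by = "country"),
            file.path(out_dir, "diversity_by_country.tsv"))
  add("cytoplasm.tsv", "cytoplasm_by_country.tsv",
      "diversity_by_country.tsv")

  ## --- raf ------------------------------------------------------------
  log_stage("raf", "heteroplasmy analysis (MIT)", verbose)
  mit <- ca_tables$MIT
  if (!is.null(mit$truth$het_sites)) {
    het_pos <- mit$truth$sites$pos[mit$truth$het_sites$site]
    raf_sites <- data.frame(pos = het_pos,
                            label = paste0("p.", het_pos))
    rec <- compute_raf(mit$vcfdata, raf_sites, min_depth = cfg$min_depth)
    prof <- site_profile(rec, c(cfg$het_band_lo, cfg$het_band_hi))
    grouping <- setNames(meta$species, meta$accession)
    comp <- compare_strata(rec, grouping)
    write_tsv(rec, file.path(out_dir, "raf_records.tsv"))
    write_tsv(prof, file.path(out_dir, "raf_profiles.tsv"))
    write_tsv(comp, file.path(out_dir, "raf_comparisons.tsv"))
    add("raf_records.tsv", "raf_profiles.tsv", "raf_comparisons.tsv")
  }

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  manifest <- manifest[order(manifest$file), , drop = FALSE]
  rownames(manifest) <- NULL
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  log_stage("done", paste0(nrow(manifest), " files in ", out_dir), verbose)
  list(manifest = manifest, summary = summary, recovery = recovery)
}

keep_positions <- function(all_pos, kept_pos) {
  which(all_pos %in% kept_pos)
}
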