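#' Classify one variant site
#'
#' A site is a SNP when ref and all alts have length 1, an InDel when every
#' alt differs from the ref in length, an MNP for equal-length multi-base
#' substitutions, and `"mixed"` when the alt alleles disagree on kind.
#' Allelism is biallelic iff there is exactly one alt.
#'
#' @param ref Reference allele string.
#' @param alts Character vector of alt alleles.
#' @return List with `kind` (`"SNP"`, `"InDel"`, `"MNP"`, `"mixed"`) and
#'   `allelism` (`"biallelic"`, `"multiallelic"`).
#' @examples
#' classify_site("T", "C")             # SNP, biallelic
#' classify_site("CAGACGA", "C")       # InDel, biallelic
#' @export
classify_site <- function(ref, alts) {
  stopifnot(nchar(ref) >= 1, length(alts) >= 1,
            !ref %in% alts, !anyDuplicated(alts))
  per_alt <- vapply(alts, function(a) {
    if (nchar(a) != nchar(ref)) "InDel"
    else if (nchar(ref) == 1L) "SNP"
    else "MNP"
  }, character(1))
  kind <- if (length(unique(per_alt)) == 1L) per_alt[[1]] else "mixed"
  list(kind = kind,
       allelism = if (length(alts) == 1L) "biallelic" else "multiallelic")
}

#' Transition/transversion ratio over biallelic SNPs
#'
#' Transitions are A<->G and C<->T; every other single-base substitution is
#' a transversion. Sites that are not biallelic SNPs are ignored.
#'
#' @param sites Data.frame with `ref` and `alts` (list-column or character).
#' @return `n_ts / n_tv`; `Inf` when there are transitions but no
#'   transversions, and `NaN` when there are no biallelic SNPs at all (the
#'   defined sentinel for an empty denominator and numerator).
#' @export
ts_tv_ratio <- function(sites) {
  if (!nrow(sites)) return(NaN)
  alts <- if (is.list(sites$alts)) sites$alts else as.list(sites$alts)
  bi_snp <- lengths(alts) == 1L & nchar(sites$ref) == 1L &
    nchar(vapply(alts, `[[`, character(1), 1L)) == 1L
  if (!any(bi_snp)) return(NaN)
  a1 <- sites$ref[bi_snp]
  a2 <- vapply(alts[bi_snp], `[[`, character(1), 1L)
  pur <- c("A", "G")
  is_ts <- (a1 %in% pur) == (a2 %in% pur)
  sum(is_ts) / sum(!is_ts)
}

is_transition <- function(ref, alt) {
  pur <- c("A", "G")
  (ref %in% pur) == (alt %in% pur)
}

#' Annotate coding effects of variants against single-CDS gene models
#'
#' For each (site, alt allele, overlapping gene), the alt allele is
#' substituted into the CDS, the CDS is translated (strand-aware; minus
#' strand alleles are reverse-complemented with the CDS), and the ref and
#' alt proteins are compared. A coding indel whose length change is not a
#' multiple of 3 is a frameshift; an in-frame indel that introduces a
#' premature stop, a stop-gain substitution, a start-loss or a stop-loss
#' are folded into `"nonsense"`; otherwise in-frame indels are
#' `"inframe_indel"` and substitutions are `"synonymous"` or `"missense"`.
#' Impact mapping: frameshift/nonsense -> high, missense/inframe_indel ->
#' moderate, synonymous -> low, everything else -> modifier.
#'
#' @param sites Sites data.frame (`pos`, `ref`, `alts` list-column).
#' @param genome A `"genome_ref"` whose `genes` hold single-CDS models.
#' @param code Genetic code table id: `"1"` (standard, default) or `"11"`
#'   (bacterial/plastid); passed to `Biostrings::getGeneticCode()`.
#' @return Data.frame with one row per (site, alt, gene-or-intergenic):
#'   `pos`, `ref`, `alt`, `gene` (NA outside genes), `effect`, `impact`.
#' @export
annotate_effect <- function(sites, genome, code = "1") {
  stopifnot(inherits(genome, "genome_ref"))
  gc_tab <- Biostrings::getGeneticCode(code)
  genes <- genome$genes
  out <- list()
  for (i in seq_len(nrow(sites))) {
    pos <- sites$pos[i]; ref <- sites$ref[i]
    span_end <- pos + nchar(ref) - 1L
    hit <- which(genes$start <= span_end & genes$end >= pos)
    for (alt in sites$alts[[i]]) {
      if (!length(hit)) {
        out[[length(out) + 1L]] <- data.frame(
          pos = pos, ref = ref, alt = alt, gene = NA_character_,
          effect = "intergenic", impact = "modifier")
        next
      }
      for (g in hit) {
        out[[length(out) + 1L]] <- cbind(
          data.frame(pos = pos, ref = ref, alt = alt,
                     gene = genes$gene_id[g]),
          effect_one(pos, ref, alt, genes[g, ], genome$seq, gc_tab))
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(pos = integer(), ref = character(), alt = character(),
               gene = character(), effect = character(),
               impact = character())
  rownames(res) <- NULL
  res
}

effect_impact <- c(frameshift = "high", nonsense = "high",
                   missense = "moderate", inframe_indel = "moderate",
                   synonymous = "low", non_coding = "modifier",
                   intergenic = "modifier")

# classify one (variant, gene); returns data.frame(effect, impact)
effect_one <- function(pos, ref, alt, gene, seq, gc_tab) {
  res <- function(effect) data.frame(effect = effect,
                                     impact = unname(effect_impact[effect]))
  width <- gene$end - gene$start + 1L
  if (is.na(gene$phase) || gene$phase != 0L || width %% 3L != 0L) {
    warning("CDS phase/length inconsistent for gene ", gene$gene_id,
            "; effect not called", call. = FALSE)
    return(res("non_coding"))
  }
  span_end <- pos + nchar(ref) - 1L
  if (pos < gene$start || span_end > gene$end) {
    # partial overlap with the CDS boundary: no defined protein change
    return(res("non_coding"))
  }
  cds_ref <- substring(seq, gene$start, gene$end)
  cds_alt <- paste0(substring(seq, gene$start, pos - 1L), alt,
                    substring(seq, span_end + 1L, gene$end))
  minus <- gene$strand == "-"
  if (minus) {
    cds_ref <- revcomp(cds_ref)
    cds_alt <- revcomp(cds_alt)
  }
  dlen <- nchar(alt) - nchar(ref)
  if (dlen %% 3L != 0L) return(res("frameshift"))

  if (dlen == 0L) {
    # substitution: only the codons covering the edited bases can change
    off0 <- if (minus) gene$end - span_end else pos - gene$start
    c0 <- off0 %/% 3L
    c1 <- (off0 + nchar(ref) - 1L) %/% 3L
    ref_cod <- substring(cds_ref, 3L * c0 + 1L, 3L * c1 + 3L)
    alt_cod <- substring(cds_alt, 3L * c0 + 1L, 3L * c1 + 3L)
    aa_ref <- translate_str(ref_cod, gc_tab)
    aa_alt <- translate_str(alt_cod, gc_tab)
    if (aa_ref == aa_alt) return(res("synonymous"))
    if (c0 == 0L && !startsWith(cds_alt, "ATG")) return(res("nonsense"))
    ref_stop <- grepl("*", aa_ref, fixed = TRUE)
    alt_stop <- grepl("*", aa_alt, fixed = TRUE)
    if (alt_stop && !ref_stop) return(res("nonsense"))  # stop gained
    if (ref_stop && !alt_stop) return(res("nonsense"))  # stop lost
    return(res("missense"))
  }

  # in-frame indel: compare full proteins for premature stops / start loss
  if (!startsWith(cds_alt, "ATG")) return(res("nonsense"))
  p_ref <- translate_str(cds_ref, gc_tab)
  p_alt <- translate_str(cds_alt, gc_tab)
  stop_at <- function(p) {
    s <- regexpr("*", p, fixed = TRUE)
    if (s < 0) nchar(p) + 1L else s
  }
  if (stop_at(p_alt) < nchar(p_alt)) return(res("nonsense"))
  if (stop_at(p_ref) <= nchar(p_ref) && stop_at(p_alt) > nchar(p_alt)) {
    return(res("nonsense"))  # stop lost
  }
  res("inframe_indel")
}

translate_str <- function(s, gc_tab) {
  n <- 3L * (nchar(s) %/% 3L)
  if (n == 0L) return("")
  as.character(Biostrings::translate(
    Biostrings::DNAString(substring(s, 1L, n)),
    genetic.code = gc_tab, no.init.codon = TRUE, if.fuzzy.codon = "X"))
}

#' Summary statistics over a variant set
#'
#' @param sites Sites data.frame (`pos`, `ref`, `alts` list-column).
#' @param effects Effect table from [annotate_effect()] (optional; gene and
#'   impact counts are zero/empty without it).
#' @return List with `counts` (one-row data.frame: `n_sites`, `n_snp`,
#'   `n_indel`, `n_other`, `n_biallelic`, `n_multiallelic`, `n_in_genes`,
#'   `ts_tv`) and `per_gene` (data.frame `gene`, `n_high`, `n_moderate`,
#'   ordered by gene id).
#' @export
summarize_variants <- function(sites, effects = NULL) {
  if (nrow(sites)) {
    cls <- lapply(seq_len(nrow(sites)),
                  function(i) classify_site(sites$ref[i], sites$alts[[i]]))
    kind <- vapply(cls, `[[`, character(1), "kind")
    allelism <- vapply(cls, `[[`, character(1), "allelism")
  } else {
    kind <- allelism <- character()
  }
  in_genes <- 0L
  per_gene <- data.frame(gene = character(), n_high = integer(),
                         n_moderate = integer())
  if (!is.null(effects) && nrow(effects)) {
    coding <- effects[!is.na(effects$gene), , drop = FALSE]
    in_genes <- length(unique(coding$pos))
    if (nrow(coding)) {
      sp <- split(coding, coding$gene)
      per_gene <- data.frame(
        gene = names(sp),
        n_high = vapply(sp, function(d)
          length(unique(d$pos[d$impact == "high"])), integer(1)),
        n_moderate = vapply(sp, function(d)
          length(unique(d$pos[d$impact == "moderate"])), integer(1)))
      per_gene <- per_gene[order(per_gene$gene), , drop = FALSE]
      rownames(per_gene) <- NULL
    }
  }
  list(counts = data.frame(
         n_sites = nrow(sites),
         n_snp = sum(kind == "SNP"),
         n_indel = sum(kind == "InDel"),
         n_other = sum(!kind %in% c("SNP", "InDel")),
         n_biallelic = sum(allelism == "biallelic"),
         n_multiallelic = sum(allelism == "multiallelic"),
         n_in_genes = in_genes,
         ts_tv = ts_tv_ratio(sites)),
       per_gene = per_gene)
}
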