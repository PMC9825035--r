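#' Per-accession reference allele frequencies at designated sites
#'
#' RAF = AD_ref / (AD_ref + AD_alt), computed from the VCF allele depths;
#' at multi-allelic sites only the designated alt allele's depth enters the
#' denominator. RAF is undefined (NA) when AD_ref + AD_alt < `min_depth`:
#' below that, the ratio is dominated by sampling noise.
#'
#' @param vcfdata An `"organelle_vcf"` from [read_organelle_vcf()] (must
#'   carry AD).
#' @param sites Data.frame of requested sites: `pos`, optionally `alt` (the
#'   designated alt allele string; default first alt) and `label`
#'   (defaults to `"p.<pos>"`).
#' @param min_depth Minimum AD_ref + AD_alt for a defined RAF (default 10).
#' @return Data.frame: `accession`, `site` (label), `pos`, `ad_ref`,
#'   `ad_alt`, `raf`.
#' @export
compute_raf <- function(vcfdata, sites, min_depth = 10) {
  stopifnot(inherits(vcfdata, "organelle_vcf"))
  if (is.null(vcfdata$ad)) stop("VCF carries no AD field", call. = FALSE)
  idx <- match(sites$pos, vcfdata$sites$pos)
  if (anyNA(idx)) {
    stop("site(s) absent from VCF: ",
         paste(sites$pos[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  labels <- sites$label %||% paste0("p.", sites$pos)
  out <- lapply(seq_along(idx), function(r) {
    j <- idx[r]
    alts <- vcfdata$sites$alts[[j]]
    ai <- if (!is.null(sites$alt)) match(sites$alt[r], alts) else 1L
    if (is.na(ai)) {
      stop("designated alt allele not found at pos ", sites$pos[r],
           call. = FALSE)
    }
    ad <- vcfdata$ad[[j]]
    ad_ref <- ad[, 1L]
    ad_alt <- ad[, ai + 1L]
    depth <- ad_ref + ad_alt
    raf <- ifelse(!is.na(depth) & depth >= min_depth, ad_ref / depth,
                  NA_real_)
    data.frame(accession = vcfdata$samples, site = labels[r],
               pos = sites$pos[r], ad_ref = ad_ref, ad_alt = ad_alt,
               raf = raf)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-site heteroplasmy profile
#'
#' @param records RAF records from [compute_raf()].
#' @param het_band Open interval `(lo, hi)`; a defined RAF strictly inside
#'   it counts as heteroplasmy-like mixed signal (default (0.05, 0.95),
#'   separating sequencing error from true mixture).
#' @return Data.frame, one row per site: `site`, `n_defined`, `median_raf`
#'   (over defined RAFs only), `fraction_heterozygous`.
#' @export
site_profile <- function(records, het_band = c(0.05, 0.95)) {
  stopifnot(length(het_band) == 2L, het_band[1] < het_band[2])
  sp <- split(records, records$site)
  out <- data.frame(
    site = names(sp),
    n_defined = vapply(sp, function(d) sum(!is.na(d$raf)), integer(1)),
    median_raf = vapply(sp, function(d) {
      v <- d$raf[!is.na(d$raf)]
      if (length(v)) median(v) else NA_real_
    }, numeric(1)),
    fraction_heterozygous = vapply(sp, function(d) {
      v <- d$raf[!is.na(d$raf)]
      if (!length(v)) return(NA_real_)
      mean(v > het_band[1] & v < het_band[2])
    }, numeric(1)))
  rownames(out) <- NULL
  out[match(unique(records$site), out$site), , drop = FALSE]
}

#' Compare RAF distributions between accession strata
#'
#' Two-sided Wilcoxon rank-sum test on defined RAFs per site for each pair
#' of strata; strata with fewer than 3 defined values are flagged and not
#' tested.
#'
#' @param records RAF records from [compute_raf()].
#' @param grouping Named character vector: accession id -> stratum label.
#' @return Data.frame, one row per (site, stratum pair): `site`,
#'   `stratum_a`, `stratum_b`, `n_a`, `n_b`, `median_a`, `median_b`, `U`
#'   (rank-sum statistic), `p_value`, `flagged` (too few observations).
#' @export
compare_strata <- function(records, grouping) {
  records$stratum <- unname(grouping[records$accession])
  records <- records[!is.na(records$stratum), , drop = FALSE]
  out <- list()
  for (s in unique(records$site)) {
    d <- records[records$site == s & !is.na(records$raf), , drop = FALSE]
    strata <- sort(unique(d$stratum))
    if (length(strata) < 2L) strata <- sort(unique(records$stratum))
    for (i in seq_along(strata)) {
      for (j in seq_along(strata)) {
        if (j <= i) next
        xa <- d$raf[d$stratum == strata[i]]
        xb <- d$raf[d$stratum == strata[j]]
        flagged <- length(xa) < 3L || length(xb) < 3L
        U <- p <- NA_real_
        if (!flagged) {
          wt <- suppressWarnings(wilcox.test(xa, xb, exact = FALSE))
          U <- unname(wt$statistic)
          p <- wt$p.value
        }
        out[[length(out) + 1L]] <- data.frame(
          site = s, stratum_a = strata[i], stratum_b = strata[j],
          n_a = length(xa), n_b = length(xb),
          median_a = if (length(xa)) median(xa) else NA_real_,
          median_b = if (length(xb)) median(xb) else NA_real_,
          U = U, p_value = p, flagged = flagged)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
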