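#' Join chloroplast and mitochondrial haplotype assignments
#'
#' Inner join on accession id of the two organelle haplotype tables plus
#' the metadata; an accession unassigned in either organelle is excluded
#' and counted, never silently dropped. Metadata fields absent for an
#' accession become `"unknown"`.
#'
#' @param ct_table Named `"haplotype_table"` for the chloroplast (CT).
#' @param mt_table Named `"haplotype_table"` for the mitochondrion (MT).
#' @param meta Metadata data.frame (`accession`, `species`, `status`,
#'   `country`, `region`, `province`).
#' @param ct_groups,mt_groups Optional group label vectors from
#'   [cluster_groups()].
#' @return A `"cytoplasm_assignment"` list: `assignments` (data.frame
#'   `accession`, `ct`, `mt`, `joint` = "CTx/MTy", `ctg`, `mtg`, metadata
#'   columns) and `exclusions` (named counts: `unassigned_ct`,
#'   `unassigned_mt`, `missing_either`).
#' @export
join_assignments <- function(ct_table, mt_table, meta, ct_groups = NULL,
                             mt_groups = NULL) {
  if (anyDuplicated(meta$accession)) {
    stop("duplicate accession ids in metadata", call. = FALSE)
  }
  ct <- ct_table$assignment
  mt <- mt_table$assignment
  universe <- intersect(names(ct), names(mt))
  ok <- universe[!is.na(ct[universe]) & !is.na(mt[universe])]
  excl <- c(unassigned_ct = sum(is.na(ct[universe])),
            unassigned_mt = sum(is.na(mt[universe])),
            missing_either = length(universe) - length(ok))
  df <- data.frame(accession = as.character(ok), ct = unname(ct[ok]),
                   mt = unname(mt[ok]))
  pj <- function(a, b) if (nrow(df)) paste0(a, "/", b) else character()
  df$joint <- pj(df$ct, df$mt)
  df$ctg <- if (is.null(ct_groups)) rep(NA_character_, nrow(df)) else
    unname(ct_groups[df$ct])
  df$mtg <- if (is.null(mt_groups)) rep(NA_character_, nrow(df)) else
    unname(mt_groups[df$mt])
  mi <- match(df$accession, meta$accession)
  for (col in c("species", "status", "country", "region", "province")) {
    v <- if (col %in% names(meta)) meta[[col]][mi] else NA_character_
    v[is.na(v) | v == ""] <- "unknown"
    df[[col]] <- v
  }
  df$joint_group <- if (is.null(ct_groups) || is.null(mt_groups))
    rep(NA_character_, nrow(df)) else pj(df$ctg, df$mtg)
  structure(list(assignments = df, exclusions = excl),
            class = "cytoplasm_assignment")
}

level_column <- function(level, organelle = NULL) {
  switch(level,
         haplotype = switch(organelle %||% "CT", CT = "ct", MT = "mt"),
         group = switch(organelle %||% "CT", CT = "ctg", MT = "mtg"),
         joint = "joint",
         joint_group = "joint_group",
         stop("unknown level: ", level, call. = FALSE))
}

#' Tabulate cytoplasm composition by a metadata category
#'
#' For every category value, counts per type and percentages
#' (count / category total, rounded half-up to one decimal, e.g. 1712 of
#' 2473 prints 69.2). A totals row over all categories is appended.
#'
#' @param ca A `"cytoplasm_assignment"` (or its `assignments` data.frame).
#' @param by Metadata key: `"species"`, `"status"`, `"country"`,
#'   `"region"`, or `"province"`.
#' @param level `"haplotype"`, `"group"`, `"joint"` (CTx/MTy) or
#'   `"joint_group"`.
#' @param organelle For per-organelle levels: `"CT"` or `"MT"`.
#' @return A long-format data.frame: `category`, `type`, `n`, `total`,
#'   `pct`.
#' @export
distribution_table <- function(ca, by = "country", level = "joint",
                               organelle = "CT") {
  df <- if (inherits(ca, "cytoplasm_assignment")) ca$assignments else ca
  stopifnot(by %in% names(df))
  col <- level_column(level, organelle)
  cat_v <- df[[by]]
  type_v <- df[[col]]
  tab <- table(category = cat_v, type = type_v)
  long <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(long)[3] <- "n"
  long <- long[long$n > 0, , drop = FALSE]
  tot <- rowSums(tab)
  long$total <- as.integer(tot[long$category])
  long$pct <- round_half_up(100 * long$n / long$total, 1)
  totals <- as.data.frame(table(type = type_v), stringsAsFactors = FALSE)
  names(totals)[2] <- "n"
  totals <- data.frame(category = "all", type = totals$type, n = totals$n,
                       total = length(type_v),
                       pct = round_half_up(100 * totals$n / length(type_v),
                                           1))
  out <- rbind(long, totals)
  out <- out[order(out$category, -out$n, out$type), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Haplotypes shared between wild and cultivated accessions
#'
#' @param ca A `"cytoplasm_assignment"` (or its `assignments` data.frame).
#' @param organelle `"CT"` or `"MT"`.
#' @return List: `shared` (haplotype names observed in both species
#'   classes, sorted), `n_cultivated` and `n_wild` (accessions of each
#'   class carrying any shared haplotype).
#' @export
shared_haplotypes <- function(ca, organelle = "CT") {
  df <- if (inherits(ca, "cytoplasm_assignment")) ca$assignments else ca
  col <- level_column("haplotype", organelle)
  h_c <- df[[col]][df$species == "cultivated"]
  h_w <- df[[col]][df$species == "wild"]
  shared <- sort(intersect(unique(h_c), unique(h_w)))
  list(shared = shared,
       n_cultivated = sum(h_c %in% shared),
       n_wild = sum(h_w %in% shared))
}

#' Per-category haplotype count and unbiased haplotype diversity
#'
#' Haplotype (gene) diversity per category: H = n/(n-1) * (1 - sum p_i^2),
#' the unbiased estimator; undefined (NA) for n < 2.
#'
#' @param ca A `"cytoplasm_assignment"` (or its `assignments` data.frame).
#' @param by Metadata key.
#' @param level,organelle As in [distribution_table()].
#' @return Data.frame: `category`, `n`, `n_haplotypes`, `diversity`.
#' @export
diversity_summary <- function(ca, by = "country", level = "haplotype",
                              organelle = "CT") {
  df <- if (inherits(ca, "cytoplasm_assignment")) ca$assignments else ca
  col <- level_column(level, organelle)
  sp <- split(df[[col]], df[[by]])
  out <- data.frame(
    category = names(sp),
    n = vapply(sp, length, integer(1)),
    n_haplotypes = vapply(sp, function(x) length(unique(x)), integer(1)),
    diversity = vapply(sp, haplotype_diversity, numeric(1)))
  rownames(out) <- NULL
  out[order(out$category), , drop = FALSE]
}

#' Unbiased haplotype diversity of a type vector
#'
#' @param x Vector of type labels.
#' @return H = n/(n-1) * (1 - sum p_i^2); NA for n < 2.
#' @export
haplotype_diversity <- function(x) {
  n <- length(x)
  if (n < 2L) return(NA_real_)
  p <- table(x) / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Chi-square test of type composition between two categories
#'
#' Optional utility for questions like "are the leading haplotypes
#' distributed differently between two regions"; a plain contingency
#' chi-square on the counts of the selected types.
#'
#' @param ca A `"cytoplasm_assignment"` (or its `assignments` data.frame).
#' @param by Metadata key.
#' @param cats Two category values to compare.
#' @param level,organelle As in [distribution_table()].
#' @param types Optional subset of types (e.g. `c("CT1","CT2","CT3")`).
#' @return The `htest` object from [stats::chisq.test()].
#' @export
composition_test <- function(ca, by = "region", cats, level = "haplotype",
                             organelle = "CT", types = NULL) {
  df <- if (inherits(ca, "cytoplasm_assignment")) ca$assignments else ca
  col <- level_column(level, organelle)
  df <- df[df[[by]] %in% cats, , drop = FALSE]
  if (!is.null(types)) df <- df[df[[col]] %in% types, , drop = FALSE]
  tab <- table(df[[by]], df[[col]])
  stats::chisq.test(tab)
}
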