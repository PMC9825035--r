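#' Read an organelle reference genome
#'
#' Loads a single-contig FASTA (and optionally its GFF3 gene models) into a
#' `"genome_ref"` object.
#'
#' @param fasta Path to a FASTA file with exactly one sequence.
#' @param gff Optional path to a GFF3 file with CDS features.
#' @param circular Is the genome circular?
#' @return A `"genome_ref"`: list with `name`, `seq` (character), `length`,
#'   `circular`, `genes` (data.frame: `gene_id`, `start`, `end` 1-based
#'   inclusive, `strand`, `phase`).
#' @export
read_genome <- function(fasta, gff = NULL, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(fasta)
  if (length(ss) != 1L) stop("expected exactly one sequence in ", fasta)
  genes <- if (is.null(gff)) empty_genes() else read_gff3(gff)
  genome_ref(name = sub("\\s.*$", "", names(ss)[1]),
             seq = as.character(ss[[1]]), circular = circular,
             genes = genes)
}

genome_ref <- function(name, seq, circular, genes = empty_genes()) {
  seq <- check_dna(seq, budget = 1, what = "reference")
  out <- list(name = name, seq = seq, length = nchar(seq),
              circular = isTRUE(circular), genes = genes)
  class(out) <- "genome_ref"
  out
}

empty_genes <- function() {
  data.frame(gene_id = character(), start = integer(), end = integer(),
             strand = character(), phase = integer())
}

#' @export
print.genome_ref <- function(x, ...) {
  cat(sprintf("<genome_ref> %s: %d bp, %s, %d gene(s)\n", x$name, x$length,
              if (x$circular) "circular" else "linear", nrow(x$genes)))
  invisible(x)
}

#' Write a genome_ref to FASTA (and optionally GFF3)
#'
#' @param genome A `"genome_ref"`.
#' @param fasta Output FASTA path.
#' @param gff Optional output GFF3 path for the gene models.
#' @return `fasta`, invisibly.
#' @export
write_genome <- function(genome, fasta, gff = NULL) {
  ss <- Biostrings::DNAStringSet(setNames(genome$seq, genome$name))
  Biostrings::writeXStringSet(ss, fasta, width = 70)
  if (!is.null(gff)) write_gff3(genome$genes, genome$name, gff)
  invisible(fasta)
}

#' Write single-CDS gene models as GFF3
#'
#' Each gene is emitted as a `gene` feature plus one `CDS` child carrying
#' the phase, 1-based inclusive coordinates per the GFF3 convention.
#'
#' @param genes Gene data.frame (`gene_id`, `start`, `end`, `strand`,
#'   `phase`).
#' @param contig Contig name.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, contig, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    writeLines(c(
      paste(contig, "organellotype", "gene", g$start, g$end, ".", g$strand,
            ".", paste0("ID=", g$gene_id), sep = "\t"),
      paste(contig, "organellotype", "CDS", g$start, g$end, ".", g$strand,
            g$phase, paste0("ID=", g$gene_id, ".cds;Parent=", g$gene_id),
            sep = "\t")), con)
  }
  invisible(path)
}

#' Read CDS gene models from GFF3
#'
#' @param path GFF3 file path.
#' @return Gene data.frame (`gene_id`, `start`, `end`, `strand`, `phase`),
#'   one row per CDS feature.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(empty_genes())
  f <- do.call(rbind, strsplit(lines, "\t", fixed = TRUE))
  cds <- f[f[, 3] == "CDS", , drop = FALSE]
  attr_id <- sub("^.*Parent=([^;]+).*$", "\\1", cds[, 9])
  no_parent <- !grepl("Parent=", cds[, 9])
  attr_id[no_parent] <- sub("^.*ID=([^;]+).*$", "\\1", cds[no_parent, 9])
  data.frame(gene_id = sub("\\.cds$", "", attr_id),
             start = as.integer(cds[, 4]), end = as.integer(cds[, 5]),
             strand = cds[, 7],
             phase = suppressWarnings(as.integer(cds[, 8])))
}

#' Read a multi-sample organelle VCF
#'
#' Thin wrapper around `VariantAnnotation::readVcf()` returning the site
#' table, raw genotype strings and per-site allele-depth matrices in the
#' shapes the rest of the package consumes.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @return A list of class `"organelle_vcf"`: `sites` (data.frame `contig`,
#'   `pos`, `ref`, `alts` list-column), `gt` (samples x sites character
#'   matrix of GT strings), `ad` (list, one samples x n_alleles integer
#'   matrix per site; NULL when AD absent), `samples`.
#' @export
read_organelle_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alts <- VariantAnnotation::alt(vcf)
  sites <- data.frame(
    contig = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)))
  sites$alts <- I(lapply(seq_len(nrow(sites)), function(i) {
    as.character(alts[[i]])
  }))
  gt <- t(VariantAnnotation::geno(vcf)$GT)  # samples x sites
  samples <- rownames(gt)
  ad <- NULL
  if ("AD" %in% names(VariantAnnotation::geno(vcf))) {
    adraw <- VariantAnnotation::geno(vcf)$AD  # sites x samples (list/array)
    ad <- lapply(seq_len(nrow(sites)), function(i) {
      na <- 1L + length(sites$alts[[i]])
      if (length(dim(adraw)) == 3L) {
        m <- matrix(as.integer(adraw[i, , seq_len(na)]), ncol = na)
      } else {
        m <- do.call(rbind, lapply(adraw[i, ], function(v) {
          as.integer(v[seq_len(na)])
        }))
      }
      rownames(m) <- samples
      m
    })
  }
  out <- list(sites = sites, gt = gt, ad = ad, samples = samples)
  class(out) <- "organelle_vcf"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Collapse VCF genotypes to haploid allele-index calls
#'
#' Organelle genomes are effectively haploid; heterozygous diploid calls
#' (heteroplasmy) are collapsed to the majority allele by allele depth, with
#' depth ties (or a het call without AD) treated as missing. Missing GT
#' stays missing.
#'
#' @param vcfdata An `"organelle_vcf"` from [read_organelle_vcf()].
#' @return Integer samples x sites matrix of 0-based allele indices
#'   (0 = REF), NA = missing.
#' @export
genotype_calls <- function(vcfdata) {
  gt <- vcfdata$gt
  n_samp <- nrow(gt); n_site <- ncol(gt)
  calls <- matrix(NA_integer_, n_samp, n_site,
                  dimnames = list(vcfdata$samples, NULL))
  for (j in seq_len(n_site)) {
    g <- gt[, j]
    toks <- strsplit(g, "[/|]")
    for (i in seq_len(n_samp)) {
      a <- suppressWarnings(as.integer(toks[[i]]))
      a <- a[!is.na(a)]
      if (!length(a)) next
      if (length(unique(a)) == 1L) {
        calls[i, j] <- a[1]
      } else if (!is.null(vcfdata$ad)) {
        d <- vcfdata$ad[[j]][i, a + 1L]
        if (!anyNA(d) && sum(d == max(d)) == 1L) {
          calls[i, j] <- a[which.max(d)]
        }
      }
    }
  }
  calls
}

# Write a multi-sample VCF v4.2 with GT and AD. gt: samples x sites GT
# strings; ad: list per site of samples x n_alleles integer matrices (NA row
# -> "."). Sites must be sorted by position.
write_organelle_vcf <- function(sites, gt, ad, samples, contig,
                                contig_length, path) {
  stopifnot(!is.unsorted(sites$pos))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=organellotype",
    sprintf("##contig=<ID=%s,length=%d>", contig, contig_length),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
           "\"Allelic depths for the ref and alt alleles\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(nrow(sites)), function(j) {
    adj <- ad[[j]]
    adstr <- apply(adj, 1, function(v) {
      if (anyNA(v)) "." else paste(v, collapse = ",")
    })
    cells <- paste(gt[, j], adstr, sep = ":")
    paste(c(contig, sites$pos[j], ".", sites$ref[j],
            paste(sites$alts[[j]], collapse = ","), ".", "PASS", ".",
            "GT:AD", cells), collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an accession metadata table
#'
#' @param path TSV with columns `accession`, `species`, `status`, `country`,
#'   `region`, `province`.
#' @return A data.frame.
#' @export
read_metadata <- function(path) {
  meta <- read.table(path, header = TRUE, sep = "\t", quote = "",
                     stringsAsFactors = FALSE, comment.char = "")
  need <- c("accession", "species", "status", "country", "region",
            "province")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing columns: ",
                         paste(miss, collapse = ", "))
  meta
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
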