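#' Read a reference genome FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write a reference genome FASTA
#'
#' @param seqs Named character vector.
#' @param path Output file.
#' @export
write_genome <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Write a haploid variant table as VCF v4.2
#'
#' Emits plain-text VCF with the site confidence as INFO `SITE_CONF` and
#' per-sample FORMAT fields `GT` (haploid), `GT_CONF` and `COV`.
#'
#' @param vt A [variant_table()].
#' @param path Output file.
#' @export
write_vcf <- function(vt, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=SITE_CONF,Number=1,Type=Float,Description=\"Site confidence\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Haploid genotype\">",
    "##FORMAT=<ID=GT_CONF,Number=1,Type=Float,Description=\"Genotype confidence\">",
    "##FORMAT=<ID=COV,Number=1,Type=Integer,Description=\"Coverage of called allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vt$samples), collapse = "\t")), con)
  if (nrow(vt$sites) > 0) {
    gt_chr <- matrix(as.character(vt$gt), nrow = nrow(vt$gt))
    gt_chr[is.na(gt_chr)] <- "."
    fields <- matrix(paste(gt_chr,
                           formatC(vt$gt_conf, format = "g"),
                           ifelse(is.na(vt$cov), ".", vt$cov), sep = ":"),
                     nrow = nrow(vt$gt))
    lines <- paste(vt$sites$scaffold, vt$sites$pos, ".",
                   vt$sites$ref, vt$sites$alt, ".", "PASS",
                   paste0("SITE_CONF=", formatC(vt$sites$site_conf, format = "g")),
                   "GT:GT_CONF:COV",
                   apply(fields, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a haploid VCF into a variant table
#'
#' Diploid genotypes (containing `/` or `|`) are rejected: the analysis is
#' defined on haploid males only.
#'
#' @param path VCF file (plain text or gzipped).
#' @return A [variant_table()].
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  samples <- colnames(v@gt)[-1]
  if (nrow(fix) == 0L) {
    empty <- matrix(integer(0), nrow = 0, ncol = length(samples),
                    dimnames = list(NULL, samples))
    return(variant_table(
      data.frame(scaffold = character(), pos = integer(), ref = character(),
                 alt = character(), class = character(), site_conf = numeric()),
      empty, empty, empty, samples))
  }
  gt_chr <- vcfR::extract.gt(v, element = "GT")
  if (any(grepl("[/|]", gt_chr)))
    stop("haploid required: diploid genotypes found in ", path)
  gt <- matrix(suppressWarnings(as.integer(gt_chr)), nrow = nrow(gt_chr),
               dimnames = list(NULL, colnames(gt_chr)))
  gt_conf <- vcfR::extract.gt(v, element = "GT_CONF", as.numeric = TRUE)
  cov <- vcfR::extract.gt(v, element = "COV", as.numeric = TRUE)
  site_conf <- as.numeric(vcfR::extract.info(v, element = "SITE_CONF"))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  alt_alleles <- strsplit(alt, ",", fixed = TRUE)
  is_snp <- nchar(ref) == 1L &
    vapply(alt_alleles, function(a) all(nchar(a) == 1L), logical(1))
  sites <- data.frame(scaffold = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = ref, alt = alt,
                      class = ifelse(is_snp, "snp", "indel"),
                      site_conf = site_conf,
                      stringsAsFactors = FALSE)
  variant_table(sites, gt, gt_conf, cov, samples)
}

#' Read/write gene models as GFF3
#'
#' Gene models are stored as one row per CDS segment with attributes
#' `gene_id`, `partial` and `transl_table` preserved.
#'
#' @param path GFF3 file.
#' @return data.frame with columns `gene_id`, `scaffold`, `start`, `end`,
#'   `strand`, `partial`, `transl_table`, ordered by gene and position.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  md <- S4Vectors::mcols(gr)
  df <- data.frame(
    gene_id = as.character(md$gene_id),
    scaffold = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    partial = if (!is.null(md$partial))
      as.character(md$partial) == "true" else FALSE,
    transl_table = if (!is.null(md$transl_table))
      as.integer(md$transl_table) else 1L,
    stringsAsFactors = FALSE)
  df$partial[is.na(df$partial)] <- FALSE
  df$transl_table[is.na(df$transl_table)] <- 1L
  df[order(df$gene_id, df$start), , drop = FALSE]
}

#' @rdname read_gene_models
#' @param genes data.frame in the layout returned by [read_gene_models()].
#' @export
write_gene_models <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$scaffold,
    ranges = IRanges::IRanges(genes$start, genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$source <- "supergenescan"
  S4Vectors::mcols(gr)$ID <- paste0("cds-", genes$gene_id, "-",
                                    seq_len(nrow(genes)))
  ord <- order(genes$gene_id, genes$start)
  lens <- genes$end - genes$start + 1L
  phase <- integer(nrow(genes))
  phase[ord] <- unlist(lapply(split(lens[ord], genes$gene_id[ord]),
                              function(l) cumsum(c(0L, l[-length(l)])) %% 3L),
                       use.names = FALSE)
  S4Vectors::mcols(gr)$phase <- as.integer(phase)
  S4Vectors::mcols(gr)$gene_id <- genes$gene_id
  S4Vectors::mcols(gr)$partial <- ifelse(genes$partial, "true", "false")
  S4Vectors::mcols(gr)$transl_table <- as.character(genes$transl_table)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read/write linkage-map marker tables
#'
#' Tab-delimited with columns `marker_id`, `scaffold`, `pos`,
#' `linkage_group`, `cM`, `family_id`, `family_type`
#' (single-queen/multiple-queen) and `cosegregates_gp9` (0/1 flag for
#' markers cosegregating with the diagnostic Gp-9 locus).
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
read_markers <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_markers
#' @param markers Marker data.frame.
#' @export
write_markers <- function(markers, path) {
  utils::write.table(markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write STR genotype tables
#'
#' Wide tab-delimited layout: locus columns (`locus_id`, `scaffold`, `pos`,
#' `period`, `ref_units`, `score`) followed by four columns per sample
#' (`<sample>.units`, `<sample>.q`, `<sample>.support`, `<sample>.coverage`),
#' mirroring per-call fields of read-based STR genotypers.
#'
#' @param path TSV file.
#' @return An [str_table()].
#' @export
read_str_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  locus_cols <- c("locus_id", "scaffold", "pos", "period", "ref_units", "score")
  unit_cols <- grep("\\.units$", names(df), value = TRUE)
  samples <- sub("\\.units$", "", unit_cols)
  pick <- function(suffix)
    as.matrix(df[, paste0(samples, ".", suffix), drop = FALSE])
  mats <- lapply(c("units", "q", "support", "coverage"), pick)
  for (i in seq_along(mats)) colnames(mats[[i]]) <- samples
  str_table(df[, locus_cols], mats[[1]], mats[[2]], mats[[3]], mats[[4]],
            samples)
}

#' @rdname read_str_table
#' @param st An [str_table()].
#' @export
write_str_table <- function(st, path) {
  df <- st$loci
  for (s in st$samples) {
    df[[paste0(s, ".units")]] <- st$units[, s]
    df[[paste0(s, ".q")]] <- st$q[, s]
    df[[paste0(s, ".support")]] <- st$support[, s]
    df[[paste0(s, ".coverage")]] <- st$coverage[, s]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write the sample sheet
#'
#' @param path TSV with columns `sample`, `group`, `coverage`, `pair`.
#' @return A [sample_set()].
#' @export
read_sample_set <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  sample_set(df$sample, df$group,
             coverage = if ("coverage" %in% names(df)) df$coverage else "low",
             pair = if ("pair" %in% names(df)) df$pair else NA)
}

#' @rdname read_sample_set
#' @param ss A [sample_set()].
#' @export
write_sample_set <- function(ss, path) {
  utils::write.table(as.data.frame(ss), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
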