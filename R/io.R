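SITES_REQUIRED <- c("gene_id", "pos", "ref", "alt", "consequence", "AC", "AN")
SITES_OPTIONAL <- c("transcript_id", "context", "methylation_tier", "n_hom",
                    "spliceai", "mmsplice", "pred_del_count", "mu")

validate_sites <- function(df, path = "<sites>") {
  miss <- setdiff(SITES_REQUIRED, names(df))
  if (length(miss))
    stopf("%s: missing required column(s): %s", path, paste(miss, collapse = ", "))
  bad <- which(df$AC > df$AN)
  if (length(bad))
    stopf("%s: AC > AN at data line %d", path, bad[1L])
  unknown <- setdiff(unique(df$consequence), CONSEQUENCE_VOCAB)
  if (length(unknown))
    stopf("%s: consequence value(s) outside the controlled vocabulary: %s",
          path, paste(unknown, collapse = ", "))
  df
}

#' Read a sites table
#'
#' Accepts two dialects of the same data: a flat TSV with a header, and a
#' VCF whose INFO fields carry the summary columns (`TX` transcript, `CSQ`
#' consequence class, `CTX` context, `TIER` methylation tier, `AC`, `AN`,
#' `NHOM`, `SAI`/`MMS` splice scores, `PD5` predicted-deleterious count;
#' CHROM holds the gene id and POS the 1-based CDS position).  Both
#' dialects of the same data produce the identical in-memory table.
#' Unknown TSV columns are preserved.
#'
#' @param path input file.
#' @param dialect `"auto"` (by extension), `"tsv"` or `"vcf"`.
#' @return sites data frame.
#' @export
read_sites <- function(path, dialect = c("auto", "tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("no such file: %s", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (dialect == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    return(validate_sites(df, path))
  }
  vcf <- VariantAnnotation::readVcf(path, genome = "cds")
  rr <- SummarizedExperiment::rowRanges(vcf)
  info <- VariantAnnotation::info(vcf)
  need <- c("TX", "CSQ", "CTX", "TIER", "AC", "AN", "NHOM", "SAI", "MMS", "PD5")
  miss <- setdiff(need, names(info))
  if (length(miss))
    stopf("%s: missing INFO key(s): %s", path, paste(miss, collapse = ", "))
  df <- data.frame(
    gene_id = as.character(GenomeInfoDb::seqnames(rr)),
    transcript_id = as.character(info$TX),
    pos = BiocGenerics::start(rr),
    ref = as.character(VariantAnnotation::ref(vcf)),
    alt = as.character(unlist(VariantAnnotation::alt(vcf))),
    consequence = as.character(info$CSQ),
    context = as.character(info$CTX),
    methylation_tier = as.character(info$TIER),
    AC = as.integer(info$AC),
    AN = as.integer(info$AN),
    n_hom = as.integer(info$NHOM),
    spliceai = as.numeric(info$SAI),
    mmsplice = as.numeric(info$MMS),
    pred_del_count = as.integer(info$PD5),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  validate_sites(df, path)
}

#' Write a sites table
#'
#' `write_sites()` emits the TSV dialect; `write_sites_vcf()` emits the VCF
#' dialect with the INFO keys [read_sites()] expects.  Numeric columns
#' round-trip exactly through the TSV dialect.
#'
#' @param df sites data frame.
#' @param path output file.
#' @export
write_sites <- function(df, path) {
  validate_sites(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sites
#' @export
write_sites_vcf <- function(df, path) {
  validate_sites(df)
  fmt_num <- function(x, default) {
    x <- if (is.null(x)) rep(default, nrow(df)) else x
    ifelse(is.na(x), default, format(x, digits = 15, trim = TRUE, scientific = FALSE))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=TX,Number=1,Type=String,Description=\"Transcript id\">",
    "##INFO=<ID=CSQ,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=CTX,Number=1,Type=String,Description=\"Trinucleotide context\">",
    "##INFO=<ID=TIER,Number=1,Type=String,Description=\"Methylation tier\">",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alternate allele count\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Total genotyped alleles\">",
    "##INFO=<ID=NHOM,Number=1,Type=Integer,Description=\"Homozygote count\">",
    "##INFO=<ID=SAI,Number=1,Type=Float,Description=\"Splice score A\">",
    "##INFO=<ID=MMS,Number=1,Type=Float,Description=\"Splice score B\">",
    "##INFO=<ID=PD5,Number=1,Type=Integer,Description=\"Predicted deleterious by k of 5\">",
    paste0("#", paste(c("CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO"), collapse = "\t")))
  info <- paste0("TX=", df$transcript_id %||% df$gene_id,
                 ";CSQ=", df$consequence,
                 ";CTX=", df$context %||% "NNN",
                 ";TIER=", df$methylation_tier %||% "none",
                 ";AC=", df$AC, ";AN=", df$AN,
                 ";NHOM=", fmt_num(df$n_hom, "0"),
                 ";SAI=", fmt_num(df$spliceai, "0"),
                 ";MMS=", fmt_num(df$mmsplice, "0"),
                 ";PD5=", fmt_num(df$pred_del_count, "0"))
  body <- paste(df$gene_id, df$pos, ".", df$ref, df$alt, ".", ".", info,
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Rate table TSV round trip
#'
#' Writes rates with full precision so that a written table reads back
#' bit-exactly.
#'
#' @param table a `mu_table`.
#' @param path file path.
#' @export
write_rate_table <- function(table, path) {
  df <- as.data.frame(table)[, c("context", "alt", "tier", "rate")]
  df$rate <- sprintf("%.17g", df$rate)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rate_table
#' @export
read_rate_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character",
                                         "character", "numeric"))
  structure(df,
            class = c("mu_table", "data.frame"),
            key = stats::setNames(df$rate,
                                  paste(df$context, df$alt, df$tier, sep = ":")))
}

#' Gene models as CDS FASTA plus metadata TSV
#'
#' The FASTA headers carry transcript ids; the metadata table maps
#' transcript to gene, essential splice-site count and flanking bases.  An
#' optional BED-like methylation track (1-based inclusive CDS intervals
#' with a tier label) fills the per-position tier vector.
#'
#' @param genes named list of [gene_model()] objects.
#' @param fasta,meta,meth file paths (`meth` optional).
#' @export
write_gene_models <- function(genes, fasta, meta, meth = NULL) {
  seqs <- Biostrings::DNAStringSet(vapply(genes, `[[`, "", "cds"))
  names(seqs) <- vapply(genes, `[[`, "", "transcript_id")
  Biostrings::writeXStringSet(seqs, fasta)
  md <- data.frame(gene_id = vapply(genes, `[[`, "", "gene_id"),
                   transcript_id = names(seqs),
                   splice_site_count = vapply(genes, `[[`, 0L, "splice_site_count"),
                   flank5 = vapply(genes, `[[`, "", "flank5"),
                   flank3 = vapply(genes, `[[`, "", "flank3"))
  utils::write.table(md, meta, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meth)) {
    rows <- do.call(rbind, lapply(genes, function(g) {
      r <- rle(g$meth_tier)
      end <- cumsum(r$lengths)
      data.frame(transcript_id = g$transcript_id,
                 start = end - r$lengths + 1L, end = end, tier = r$values)
    }))
    rows <- rows[rows$tier != "none", ]
    utils::write.table(rows, meth, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(fasta)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(fasta, meta, meth = NULL) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  # single-base flanks like "T" would otherwise be parsed as logicals
  hdr <- strsplit(readLines(meta, n = 1L), "\t", fixed = TRUE)[[1L]]
  cc <- c(flank5 = "character", flank3 = "character")
  cc <- cc[names(cc) %in% hdr]
  md <- utils::read.delim(meta, stringsAsFactors = FALSE,
                          colClasses = if (length(cc)) cc else NA)
  track <- if (!is.null(meth)) utils::read.delim(meth, stringsAsFactors = FALSE)
  genes <- lapply(seq_len(nrow(md)), function(i) {
    tx <- md$transcript_id[i]
    if (!tx %in% names(seqs)) stopf("transcript %s missing from FASTA", tx)
    cds <- as.character(seqs[[tx]])
    tier <- rep("none", nchar(cds))
    if (!is.null(track)) {
      tr <- track[track$transcript_id == tx, , drop = FALSE]
      for (j in seq_len(nrow(tr))) tier[tr$start[j]:tr$end[j]] <- tr$tier[j]
    }
    gene_model(md$gene_id[i], tx, cds,
               splice_site_count = md$splice_site_count[i] %||% 0L,
               meth_tier = tier,
               flank5 = md$flank5[i] %||% "T", flank3 = md$flank3[i] %||% "A")
  })
  names(genes) <- md$gene_id
  genes
}

#' Export constrained regions
#'
#' TSV keeps the 1-based inclusive codon coordinates of
#' [segment_regions()]; the BED export converts to 0-based half-open
#' intervals.
#'
#' @param regions data frame from [segment_regions()].
#' @param path output file.
#' @param format `"tsv"` or `"bed"`.
#' @export
write_regions <- function(regions, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(regions, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    bed <- data.frame(chrom = regions$gene_id,
                      start = regions$start_codon - 1L,
                      end = regions$end_codon,
                      name = sprintf("%s:%d-%d", regions$gene_id,
                                     regions$start_codon, regions$end_codon),
                      score = round(1000 * pmin(1, pmax(0, 1 - regions$mean_mtr))))
    utils::write.table(bed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
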