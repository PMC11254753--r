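#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

PLOF_CLASSES <- c("stop_gained", "splice_donor", "splice_acceptor", "frameshift")
SURVEY_CLASSES <- c("synonymous", "missense", "stop_gained")
CONSEQUENCE_VOCAB <- c("synonymous", "missense", "stop_gained",
                       "splice_donor", "splice_acceptor", "frameshift",
                       "start_loss", "stop_loss", "noncoding")
METH_TIERS <- c("none", "low", "mid", "high")

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_plof <- function(consequence) consequence %in% PLOF_CLASSES

#' Reverse complement of character vectors of DNA
#'
#' Vectorised over its argument; kept internal because [Biostrings] offers the
#' same for XString objects and this avoids object conversion in hot loops.
#' @noRd
revcomp_chr <- function(x) {
  comp <- chartr("ACGT", "TGCA", x)
  if (all(nchar(x) == 3L))
    return(paste0(substr(comp, 3L, 3L), substr(comp, 2L, 2L), substr(comp, 1L, 1L)))
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

#' Strand-normalize trinucleotide contexts
#'
#' Contexts whose middle base is a purine are replaced by the reverse
#' complement of the 3-mer, with the alternate allele complemented to match,
#' so a context and its reverse complement share one representation
#' (pyrimidine-centered).
#'
#' @param context character vector of 3-mers.
#' @param alt character vector of alternate alleles (single bases), recycled.
#' @return list with elements `context` and `alt`, both normalized.
#' @export
normalize_context <- function(context, alt) {
  stopifnot(all(nchar(context) == 3L))
  n <- max(length(context), length(alt))
  context <- rep_len(context, n)
  alt <- rep_len(alt, n)
  mid <- substr(context, 2L, 2L)
  flip <- mid %in% c("A", "G")
  if (any(flip)) {
    context[flip] <- revcomp_chr(context[flip])
    alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
  }
  list(context = context, alt = alt)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
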