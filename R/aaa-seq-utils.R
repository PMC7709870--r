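PYRIMIDINES <- c("C", "T")
PURINES <- c("A", "G")
BASES <- c("A", "C", "G", "T")

#' Complement and reverse-complement of DNA strings
#'
#' Vectorized over character vectors. Any character outside A,C,G,T is
#' mapped through unchanged except N, which complements to N.
#'
#' @param x character vector of DNA strings.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(strsplit(comp, ""), function(v) paste(rev(v), collapse = ""), "")
}

#' @rdname revcomp
#' @export
complement <- function(x) chartr("ACGTNacgtn", "TGCANtgcan", x)

is_pyrimidine <- function(b) b %in% PYRIMIDINES

#' Coerce a genome to the internal representation
#'
#' Accepts a \code{Biostrings::DNAStringSet}, a named character vector of
#' chromosome sequences, or a path to a FASTA file.
#'
#' @param genome genome in any accepted form.
#' @return named character vector of uppercase chromosome sequences.
#' @export
as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      is.null(names(genome))) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    out <- as.character(genome)
    names(out) <- sub("\\s.*$", "", names(genome))
    return(toupper(out))
  }
  if (is.character(genome) && !is.null(names(genome))) {
    return(toupper(genome))
  }
  stop("genome must be a DNAStringSet, a named character vector, or a FASTA path")
}

# 1-based inclusive window on the plus strand, N-padded beyond contig ends.
seq_window <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) {
    stop("chromosome '", chrom, "' not present in genome")
  }
  s <- genome[[chrom]]
  len <- nchar(s)
  lo <- max(start, 1L)
  hi <- min(end, len)
  core <- if (lo > hi) "" else substr(s, lo, hi)
  paste0(strrep("N", max(0L, lo - start)), core, strrep("N", max(0L, end - hi)))
}

# character vector of single bases for one chromosome (cached by callers)
chrom_chars <- function(genome, chrom) strsplit(genome[[chrom]], "")[[1]]
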