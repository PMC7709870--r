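# UVDE-seq damage mapping: aligned read positions to dinucleotide lesion
# sites, dinucleotide tallies, and treated-versus-control enrichment.

DINUCS <- as.vector(outer(BASES, BASES, paste0))
DIPYR_DINUCS <- c("TT", "TC", "CT", "CC")

#' Read a BED6 alignment file
#'
#' @param path path to a BED6 file (0-based half-open intervals).
#' @return data.frame with columns \code{chrom}, \code{start}, \code{end}
#'   (0-based half-open), \code{strand}.
#' @export
read_bed <- function(path) {
  bed <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 6) stop("BED6 requires 6 columns")
  data.frame(chrom = bed[[1]], start = as.integer(bed[[2]]),
             end = as.integer(bed[[3]]), strand = bed[[6]],
             stringsAsFactors = FALSE)
}

#' Write reads as BED6
#'
#' @param reads data.frame with \code{chrom}, \code{start}, \code{end},
#'   \code{strand} (0-based half-open).
#' @param path output path.
#' @export
write_bed <- function(reads, path) {
  bed <- data.frame(reads$chrom, reads$start, reads$end,
                    name = ".", score = 0L, strand = reads$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Locate the lesion site implied by a damage-seq read
#'
#' The sequencing adaptor ligates immediately downstream of the
#' endonuclease cut, so the sequenced strand is synthesized from the
#' damaged template: under the default convention the lesion occupies the
#' two nucleotides immediately upstream of the read's 5' terminus
#' (\code{offset = -2}) on the strand opposite the read
#' (\code{lesion_strand_side = "opposite"}). Both are configurable because
#' library chemistries differ in the cut-to-lesion offset.
#'
#' @param reads data.frame of alignments (0-based half-open,
#'   \code{chrom}/\code{start}/\code{end}/\code{strand}).
#' @param offset signed distance from the read 5' terminus to the nearest
#'   lesion base, in the read's upstream direction; -2 places the lesion
#'   dinucleotide immediately upstream.
#' @param lesion_strand_side \code{"opposite"} or \code{"same"} as the read.
#' @param genome optional; when supplied, sites whose dinucleotide runs off
#'   the contig are dropped.
#' @return data.frame with \code{chrom}, \code{start0} (0-based leftmost
#'   base of the lesion dinucleotide on the plus strand), \code{pos5}
#'   (0-based position of the lesion's 5' base on the lesion strand),
#'   \code{lesion_strand}; attribute \code{n_dropped} counts out-of-bounds
#'   sites.
#' @export
lesion_site <- function(reads, offset = -2L, genome = NULL,
                        lesion_strand_side = c("opposite", "same")) {
  lesion_strand_side <- match.arg(lesion_strand_side)
  stopifnot(all(reads$strand %in% c("+", "-")), all(reads$start < reads$end))
  plus <- reads$strand == "+"
  start0 <- ifelse(plus, reads$start + offset, reads$end - offset - 2L)
  lesion_strand <- if (lesion_strand_side == "opposite") {
    ifelse(plus, "-", "+")
  } else reads$strand
  out <- data.frame(chrom = reads$chrom, start0 = as.integer(start0),
                    lesion_strand = lesion_strand, stringsAsFactors = FALSE)
  out$pos5 <- ifelse(out$lesion_strand == "+", out$start0, out$start0 + 1L)
  keep <- out$start0 >= 0L
  if (!is.null(genome)) {
    genome <- as_genome(genome)
    lens <- nchar(genome)[out$chrom]
    keep <- keep & (out$start0 + 2L <= lens)
  }
  n_dropped <- sum(!keep)
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Tally lesion-site dinucleotides
#'
#' Reads each lesion dinucleotide 5' to 3' on the lesion strand and counts
#' occurrences of the 16 dinucleotides. Sites containing N are dropped and
#' counted.
#'
#' @param sites data.frame from \code{\link{lesion_site}}.
#' @param genome genome accepted by \code{\link{as_genome}}.
#' @param label sample label carried in the result.
#' @return object of class \code{uv_dinuc_counts}: list with \code{counts}
#'   (named integer vector over the 16 dinucleotides), \code{total},
#'   \code{n_dropped}, \code{label}.
#' @export
count_dinucs <- function(sites, genome, label = "sample") {
  genome <- as_genome(genome)
  counts <- stats::setNames(integer(length(DINUCS)), DINUCS)
  n_dropped <- 0L
  if (nrow(sites)) {
    dinucs <- character(nrow(sites))
    for (i in seq_len(nrow(sites))) {
      d <- seq_window(genome, sites$chrom[i], sites$start0[i] + 1L,
                      sites$start0[i] + 2L)
      if (sites$lesion_strand[i] == "-") d <- revcomp(d)
      dinucs[i] <- d
    }
    ok <- dinucs %in% DINUCS
    n_dropped <- sum(!ok)
    tab <- table(dinucs[ok])
    counts[names(tab)] <- as.integer(tab)
  }
  structure(list(counts = counts, total = sum(counts),
                 n_dropped = n_dropped, label = label),
            class = "uv_dinuc_counts")
}

#' @export
print.uv_dinuc_counts <- function(x, ...) {
  cat("Lesion dinucleotide counts for", x$label, "(total", x$total, ")\n")
  print(sort(x$counts, decreasing = TRUE))
  invisible(x)
}

#' Damage enrichment of treated over control
#'
#' Converts two dinucleotide count tables to fractions of total, forms the
#' treated/control fraction ratio per dinucleotide, and ranks dinucleotides
#' by treated fraction within a configurable subset (e.g. restricted to
#' non-CPD-relevant classes).
#'
#' @param uv,control \code{uv_dinuc_counts} for the treated and control
#'   samples.
#' @param rank_subset dinucleotides eligible for ranking; default all 16.
#' @return data.frame with per-dinucleotide \code{uv_frac},
#'   \code{ctrl_frac}, \code{ratio}, and \code{rank} (NA outside the
#'   subset).
#' @export
damage_enrichment <- function(uv, control, rank_subset = DINUCS) {
  stopifnot(inherits(uv, "uv_dinuc_counts"),
            inherits(control, "uv_dinuc_counts"))
  if (control$total == 0) stop("control total is zero")
  if (uv$total == 0) stop("treated total is zero")
  uv_frac <- uv$counts / uv$total
  ctrl_frac <- control$counts / control$total
  out <- data.frame(dinuc = DINUCS, uv_frac = as.numeric(uv_frac[DINUCS]),
                    ctrl_frac = as.numeric(ctrl_frac[DINUCS]),
                    stringsAsFactors = FALSE)
  out$ratio <- ifelse(out$ctrl_frac > 0, out$uv_frac / out$ctrl_frac, Inf)
  out$rank <- NA_integer_
  sub <- out$dinuc %in% rank_subset
  out$rank[sub] <- rank(-out$uv_frac[sub], ties.method = "min")
  out
}
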