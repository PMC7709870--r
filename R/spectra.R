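# Aggregation of classified events into trinucleotide spectra, dipyrimidine
# tables, tandem spectra, flanking-base matrices, and per-isolate strain
# comparisons.

PYR_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
DIPYR_LEVELS <- c("FIVE_PRIME", "THREE_PRIME", "NONE")

#' The 96 pyrimidine-strand trinucleotide classes
#'
#' @return data.frame with columns \code{pyr_class} and \code{context} in
#'   the conventional order (classes ordered C>A..T>G, contexts by 5' then
#'   3' flank).
#' @export
trinuc_classes <- function() {
  out <- do.call(rbind, lapply(PYR_CLASSES, function(cl) {
    central <- substr(cl, 1, 1)
    grid <- expand.grid(f3 = BASES, f5 = BASES, stringsAsFactors = FALSE)
    data.frame(pyr_class = cl,
               context = paste0(grid$f5, central, grid$f3),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Build a 96-class trinucleotide mutation spectrum
#'
#' Counts classified single-nucleotide substitutions over the 96
#' pyrimidine-strand (class, trinucleotide-context) cells. Events whose
#' context contains N (contig edges) are excluded and counted.
#'
#' @param classified data.frame from \code{\link{classify_snv}}.
#' @param metadata optional named list (strain, dose, ...) carried along.
#' @return object of class \code{uv_spectrum}: list with \code{counts}
#'   (96-row data.frame with a \code{count} column), \code{total},
#'   \code{n_excluded}, \code{metadata}.
#' @export
build_spectrum <- function(classified, metadata = list()) {
  tab <- trinuc_classes()
  if (is.null(classified) || nrow(classified) == 0) {
    tab$count <- 0L
    return(structure(list(counts = tab, total = 0L, n_excluded = 0L,
                          metadata = metadata), class = "uv_spectrum"))
  }
  has_n <- grepl("N", classified$context, fixed = TRUE)
  keep <- classified[!has_n, , drop = FALSE]
  key <- paste(keep$pyr_class, keep$context)
  cnt <- table(key)
  tab$count <- as.integer(cnt[paste(tab$pyr_class, tab$context)])
  tab$count[is.na(tab$count)] <- 0L
  bad <- setdiff(names(cnt), paste(tab$pyr_class, tab$context))
  if (length(bad)) stop("unrecognized class/context: ", bad[1])
  structure(list(counts = tab, total = sum(tab$count),
                 n_excluded = sum(has_n), metadata = metadata),
            class = "uv_spectrum")
}

#' @export
print.uv_spectrum <- function(x, ...) {
  cat("Trinucleotide mutation spectrum:", x$total, "substitutions",
      if (x$n_excluded) paste0("(", x$n_excluded, " N-context excluded)"), "\n")
  by_class <- class_fractions(x)
  for (i in seq_len(nrow(by_class))) {
    cat(sprintf("  %s  %6d  (%4.1f%%)\n", by_class$pyr_class[i],
                by_class$count[i], 100 * by_class$fraction[i]))
  }
  invisible(x)
}

#' Per-class marginals of a spectrum
#'
#' @param spectrum a \code{uv_spectrum}.
#' @return data.frame with \code{pyr_class}, \code{count}, \code{fraction}.
#' @export
class_fractions <- function(spectrum) {
  stopifnot(inherits(spectrum, "uv_spectrum"))
  agg <- stats::aggregate(count ~ pyr_class, spectrum$counts, sum)
  agg$fraction <- if (spectrum$total > 0) agg$count / spectrum$total else 0
  agg
}

#' Dipyrimidine-category table
#'
#' Cross-tabulates the six pyrimidine-strand classes against the position of
#' the mutated base within a dipyrimidine (5' position, 3' position, or not
#' in a dipyrimidine). N-context events are excluded so that the marginals
#' match \code{\link{build_spectrum}}.
#'
#' @param classified data.frame from \code{\link{classify_snv}}.
#' @return data.frame with columns \code{pyr_class}, \code{dipyr},
#'   \code{count} covering all 18 cells.
#' @export
build_dipyr_table <- function(classified) {
  grid <- expand.grid(dipyr = DIPYR_LEVELS, pyr_class = PYR_CLASSES,
                      stringsAsFactors = FALSE)[, c("pyr_class", "dipyr")]
  if (is.null(classified) || nrow(classified) == 0) {
    grid$count <- 0L
    return(grid)
  }
  keep <- classified[!grepl("N", classified$context, fixed = TRUE), , drop = FALSE]
  key <- paste(keep$pyr_class, keep$dipyr)
  cnt <- table(key)
  grid$count <- as.integer(cnt[paste(grid$pyr_class, grid$dipyr)])
  grid$count[is.na(grid$count)] <- 0L
  grid
}

#' T>A mutations in an NTA context
#'
#' Counts T>A substitutions whose pyrimidine-strand trinucleotide context
#' ends in A (ATA, CTA, GTA, TTA) — the signature of a lesion at the
#' complementary TAN sequence — and reports them as fractions of all T>A
#' events and of all classified substitutions. N-context events are
#' excluded, matching the spectrum.
#'
#' @param classified data.frame from \code{\link{classify_snv}}.
#' @return list with \code{n_NTA}, \code{frac_of_TA}, \code{frac_of_all}.
#' @export
nta_fraction <- function(classified) {
  if (is.null(classified) || nrow(classified) == 0) {
    return(list(n_NTA = 0L, frac_of_TA = 0, frac_of_all = 0))
  }
  keep <- classified[!grepl("N", classified$context, fixed = TRUE), , drop = FALSE]
  is_ta <- keep$pyr_class == "T>A"
  is_nta <- is_ta & substr(keep$context, 3, 3) == "A"
  n_ta <- sum(is_ta)
  list(n_NTA = sum(is_nta),
       frac_of_TA = if (n_ta > 0) sum(is_nta) / n_ta else 0,
       frac_of_all = if (nrow(keep) > 0) sum(is_nta) / nrow(keep) else 0)
}

#' Tandem mutation spectrum
#'
#' Counts tandem events by canonical label, pooling each class with its
#' reverse complement (GT>AA counts as AC>TT).
#'
#' @param tandems data.frame of tandem events; canonicalized if needed.
#' @return named integer vector of counts, sorted decreasing.
#' @export
build_tandem_spectrum <- function(tandems) {
  if (is.null(tandems) || nrow(tandems) == 0) return(integer(0))
  if (!"canonical_label" %in% names(tandems)) {
    tandems <- canonicalize_tandem(tandems)
  }
  sort(table(tandems$canonical_label), decreasing = TRUE) |>
    (\(x) stats::setNames(as.integer(x), names(x)))()
}

#' Flanking-base frequency matrix for one tandem class
#'
#' For tandem events of a single canonical class, tallies the base
#' composition at each position within \code{w} nucleotides of the
#' dinucleotide, read 5' to 3' on each event's canonical strand. Events
#' whose window runs off the contig or contains N are dropped and counted.
#' The canonical 4-mer (one flanking base each side of the reference
#' dinucleotide) is tabulated alongside.
#'
#' @param tandems canonicalized tandem events of one class.
#' @param genome genome accepted by \code{\link{as_genome}}.
#' @param w positive window half-width.
#' @return object of class \code{uv_flank_matrix}: list with \code{freq}
#'   (4 x 2w column-stochastic matrix, columns -w..-1, 1..w), \code{n_used},
#'   \code{n_dropped}, \code{label}, \code{fourmer_counts}.
#' @export
flank_matrix <- function(tandems, genome, w = 5L) {
  if (w <= 0) stop("w must be positive")
  genome <- as_genome(genome)
  if (!"canonical_label" %in% names(tandems)) {
    tandems <- canonicalize_tandem(tandems)
  }
  labs <- unique(tandems$canonical_label)
  if (length(labs) > 1) {
    stop("all events must share one canonical label; got ",
         paste(labs, collapse = ", "))
  }
  positions <- c(-(w:1), 1:w)
  counts <- matrix(0L, nrow = 4, ncol = 2 * w,
                   dimnames = list(BASES, as.character(positions)))
  fourmers <- character(0)
  n_dropped <- 0L
  for (i in seq_len(nrow(tandems))) {
    p <- tandems$start_pos[i]
    win <- seq_window(genome, tandems$chrom[i], p - w, p + 1L + w)
    if (tandems$canonical_strand[i] == "minus") win <- revcomp(win)
    flanks <- c(substr(win, 1, w),
                substr(win, w + 3L, 2L * w + 2L))
    fl <- strsplit(paste0(flanks[1], flanks[2]), "")[[1]]
    if (any(!fl %in% BASES)) {
      n_dropped <- n_dropped + 1L
      next
    }
    for (j in seq_along(fl)) counts[fl[j], j] <- counts[fl[j], j] + 1L
    fourmers <- c(fourmers, paste0(substr(win, w, w),
                                   substr(win, w + 1L, w + 2L),
                                   substr(win, w + 3L, w + 3L)))
  }
  n_used <- nrow(tandems) - n_dropped
  freq <- if (n_used > 0) counts / n_used else counts
  structure(list(freq = freq, n_used = n_used, n_dropped = n_dropped,
                 label = if (length(labs)) labs else NA_character_,
                 fourmer_counts = sort(table(fourmers), decreasing = TRUE)),
            class = "uv_flank_matrix")
}

#' @export
print.uv_flank_matrix <- function(x, ...) {
  cat("Flanking-base frequencies for", x$label, "events (n =", x$n_used, ")\n")
  print(round(x$freq, 3))
  invisible(x)
}

#' Holm-Sidak step-down adjustment
#'
#' Sorts raw p-values ascending and applies the Sidak single-step bound to
#' the shrinking family at each rank, \eqn{1 - (1 - p_{(i)})^{m - i + 1}},
#' enforcing monotonicity by running maximum.
#'
#' @param p numeric vector of raw p-values (NA allowed, passed through).
#' @return adjusted p-values in the original order.
#' @export
holm_sidak <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  if (!length(ok)) return(out)
  m <- length(ok)
  ord <- ok[order(p[ok])]
  adj <- 1 - (1 - p[ord])^(m - seq_len(m) + 1)
  adj <- pmin(1, cummax(adj))
  out[ord] <- adj
  out
}

#' Per-class comparison of mutation counts between strains
#'
#' For each mutation class, compares per-isolate counts between two groups
#' with a two-sided t-test (Welch by default) and adjusts across classes by
#' Holm-Sidak step-down. Classes absent from both groups are excluded;
#' classes observed in only one group are kept with mean zero in the other.
#'
#' @param counts_a,counts_b numeric matrices (isolates x classes) of
#'   per-isolate event counts; column names identify classes.
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return data.frame with per-class means, SEMs, t statistic, raw and
#'   Holm-Sidak adjusted p-values.
#' @export
strain_class_comparison <- function(counts_a, counts_b, var_equal = FALSE) {
  counts_a <- as.matrix(counts_a)
  counts_b <- as.matrix(counts_b)
  if (nrow(counts_a) < 2 || nrow(counts_b) < 2) {
    stop("need at least 2 isolates per group")
  }
  classes <- union(colnames(counts_a), colnames(counts_b))
  fill <- function(m, cls) {
    out <- matrix(0, nrow(m), length(cls), dimnames = list(NULL, cls))
    out[, colnames(m)] <- m
    out
  }
  a <- fill(counts_a, classes)
  b <- fill(counts_b, classes)
  present <- colSums(a) > 0 | colSums(b) > 0
  classes <- classes[present]
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  rows <- lapply(classes, function(cl) {
    x <- a[, cl]; y <- b[, cl]
    if (stats::sd(c(x, y)) == 0) {
      tt <- list(statistic = 0, p.value = 1)
    } else if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      # constant but different groups: zero standard error, degenerate t
      tt <- list(statistic = sign(mean(x) - mean(y)) * Inf, p.value = 0)
    } else {
      tt <- stats::t.test(x, y, var.equal = var_equal)
    }
    data.frame(class = cl, mean_a = mean(x), sem_a = sem(x),
               mean_b = mean(y), sem_b = sem(y),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm_sidak <- holm_sidak(out$p)
  rownames(out) <- NULL
  out
}
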