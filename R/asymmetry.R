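# Transcriptional strand asymmetry: trinucleotide-frequency-normalized
# NTS/TS mutation ratios per class, chi-square tests with Bonferroni
# correction, count thresholds, gene exclusions, and expression-quartile
# stratification.

# rDNA- and CUP1-overlapping genes excluded from the yeast analysis
YEAST_EXCLUDED_GENES <- c("YLR154C-G", "YLR155C", "YLR161W", "YLR162W-A",
                          "YHR053C", "YHR054C", "YHR055C")

#' Read a gene annotation table
#'
#' TSV with columns \code{gene_id}, \code{chrom}, \code{tss}, \code{tes},
#' \code{strand} (+/-), and optionally \code{expression}. The transcribed
#' interval is \code{[min(tss, tes), max(tss, tes)]}; the strand determines
#' which genomic strand is the template (transcribed) strand.
#'
#' @param path path to the TSV file.
#' @return data.frame of gene annotations.
#' @export
read_gene_table <- function(path) {
  genes <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  validate_genes(genes)
}

validate_genes <- function(genes) {
  need <- c("gene_id", "chrom", "tss", "tes", "strand")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("missing gene column(s): ", paste(miss, collapse = ", "))
  if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be + or -")
  if (!"expression" %in% names(genes)) genes$expression <- NA_real_
  genes$start <- pmin(genes$tss, genes$tes)
  genes$end <- pmax(genes$tss, genes$tes)
  genes
}

genes_granges <- function(genes) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand, gene_id = genes$gene_id)
}

# regions covered by genes on both strands (excluded from all strand work)
opposite_overlap_ranges <- function(genes) {
  gr <- genes_granges(genes)
  plus <- GenomicRanges::reduce(gr[BiocGenerics::strand(gr) == "+"],
                                ignore.strand = TRUE)
  minus <- GenomicRanges::reduce(gr[BiocGenerics::strand(gr) == "-"],
                                 ignore.strand = TRUE)
  GenomicRanges::intersect(plus, minus, ignore.strand = TRUE)
}

#' Assign classified mutations to the transcribed or non-transcribed strand
#'
#' The strand bearing the mutated pyrimidine is compared with each
#' overlapping gene's mRNA-identical (non-transcribed) strand: equal gives
#' NTS, opposite gives TS. Positions covered by genes on both strands are
#' excluded; positions outside all genes are intergenic.
#'
#' @param classified data.frame from \code{\link{classify_snv}}.
#' @param genes gene annotation data.frame.
#' @return the input with columns \code{strand_class} (one of NTS, TS,
#'   intergenic, excluded) and \code{gene_id} added.
#' @export
assign_gene_strand <- function(classified, genes) {
  genes <- validate_genes(genes)
  gr <- genes_granges(genes)
  excl <- opposite_overlap_ranges(genes)
  pos <- GenomicRanges::GRanges(classified$chrom,
                                IRanges::IRanges(classified$pos, classified$pos))
  in_excl <- IRanges::overlapsAny(pos, excl, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(pos, gr, ignore.strand = TRUE)
  first_hit <- tapply(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits),
                      `[`, 1)
  gene_idx <- rep(NA_integer_, nrow(classified))
  gene_idx[as.integer(names(first_hit))] <- as.integer(first_hit)

  pyr_strand <- ifelse(classified$flipped, "-", "+")
  strand_class <- rep("intergenic", nrow(classified))
  has_gene <- !is.na(gene_idx)
  gs <- as.character(BiocGenerics::strand(gr))[gene_idx[has_gene]]
  strand_class[has_gene] <- ifelse(pyr_strand[has_gene] == gs, "NTS", "TS")
  strand_class[in_excl] <- "excluded"
  classified$strand_class <- strand_class
  classified$gene_id <- ifelse(has_gene & !in_excl,
                               genes$gene_id[gene_idx], NA_character_)
  classified
}

#' Strand k-mer frequencies over transcribed regions
#'
#' Counts, over the retained transcribed intervals of a gene set, how often
#' each k-mer occurs on the non-transcribed versus the transcribed strand.
#' For trinucleotides (\code{k = 3}) the key is the pyrimidine-strand 3-mer
#' (central base C or T); each genomic position therefore contributes to
#' exactly one strand column. For dinucleotides (\code{k = 2}) the key is
#' the canonical orientation (lexicographically smaller of the pair and its
#' reverse complement); strand-palindromic dinucleotides (AT, TA, CG, GC)
#' are counted on both strands. Positions covered by genes on both strands
#' and genes on the deny-list are excluded.
#'
#' @param genome genome accepted by \code{\link{as_genome}}.
#' @param genes gene annotation data.frame.
#' @param exclude_ids gene ids to drop before counting.
#' @param k k-mer size, 2 or 3.
#' @return data.frame with columns \code{kmer}, \code{f_NTS}, \code{f_TS}.
#' @export
build_strand_freqs <- function(genome, genes, exclude_ids = character(), k = 3L) {
  stopifnot(k %in% c(2L, 3L))
  genome <- as_genome(genome)
  genes <- validate_genes(genes)
  genes <- genes[!genes$gene_id %in% exclude_ids, , drop = FALSE]
  for (i in seq_len(nrow(genes))) {
    len <- nchar(genome[[genes$chrom[i]]])
    if (is.null(len) || genes$end[i] > len || genes$start[i] < 1) {
      stop("gene ", genes$gene_id[i], " exceeds contig bounds")
    }
  }
  excl <- opposite_overlap_ranges(genes)
  key_all <- character(0)
  col_all <- character(0)
  for (i in seq_len(nrow(genes))) {
    chrom <- genes$chrom[i]
    v <- chrom_chars(genome, chrom)
    s <- genes$start[i]; e <- genes$end[i]
    ex <- excl[as.character(GenomeInfoDb::seqnames(excl)) == chrom]
    masked <- if (length(ex)) {
      unlist(Map(seq, BiocGenerics::start(ex), BiocGenerics::end(ex)))
    } else integer(0)
    gene_plus <- genes$strand[i] == "+"
    if (k == 3L) {
      lo <- max(s, 2L); hi <- min(e, length(v) - 1L)
      if (lo > hi) next
      centers <- setdiff(seq(lo, hi), masked)
      if (!length(centers)) next
      mers <- paste0(v[centers - 1L], v[centers], v[centers + 1L])
      ok <- !grepl("N", mers, fixed = TRUE)
      mers <- mers[ok]
      pyr <- v[centers][ok] %in% PYRIMIDINES
      key <- mers
      key[!pyr] <- revcomp(mers[!pyr])
      # pyrimidine on the plus strand: NTS occurrence iff the gene is plus
      col <- ifelse(pyr == gene_plus, "f_NTS", "f_TS")
      key_all <- c(key_all, key)
      col_all <- c(col_all, col)
    } else {
      lo <- s; hi <- min(e - 1L, length(v) - 1L)
      if (lo > hi) next
      starts <- setdiff(seq(lo, hi), masked)
      if (!length(starts)) next
      mers <- paste0(v[starts], v[starts + 1L])
      ok <- !grepl("N", mers, fixed = TRUE)
      mers <- mers[ok]
      rc <- revcomp(mers)
      pal <- mers == rc
      fwd <- mers < rc
      key <- ifelse(fwd | pal, mers, rc)
      col <- ifelse(pal, "f_NTS", ifelse(fwd == gene_plus, "f_NTS", "f_TS"))
      # palindromic dinucleotides occur on both strands at once
      key_all <- c(key_all, key, key[pal])
      col_all <- c(col_all, col, rep("f_TS", sum(pal)))
    }
  }
  if (!length(key_all)) {
    return(data.frame(kmer = character(), f_NTS = integer(),
                      f_TS = integer(), stringsAsFactors = FALSE))
  }
  tab <- table(key_all, col_all)
  keys <- sort(rownames(tab))
  getcol <- function(col) {
    if (col %in% colnames(tab)) as.integer(tab[keys, col]) else
      integer(length(keys))
  }
  data.frame(kmer = keys, f_NTS = getcol("f_NTS"), f_TS = getcol("f_TS"),
             stringsAsFactors = FALSE)
}

#' Frequency-normalized strand asymmetry ratio
#'
#' \deqn{(n_{NTS} / f_{NTS}) / (n_{TS} / f_{TS})}
#' where the f's are the strand occurrence counts of the class's sequence
#' context. Returns \code{Inf} when \code{n_TS} is zero.
#'
#' @param n_NTS,n_TS mutation counts on each strand.
#' @param f_NTS,f_TS strand context frequencies (must be positive).
#' @return numeric ratio (vectorized).
#' @export
asymmetry_ratio <- function(n_NTS, n_TS, f_NTS, f_TS) {
  if (any(f_NTS <= 0) || any(f_TS <= 0)) {
    stop("context frequencies must be positive (class absent from gene set)")
  }
  ifelse(n_TS == 0, Inf, (n_NTS / f_NTS) / (n_TS / f_TS))
}

#' Chi-square test for strand asymmetry
#'
#' One-degree-of-freedom goodness-of-fit of the observed strand split
#' against an expected split proportional to the strand context frequencies
#' (\code{null = "freq"}) or an even split (\code{null = "even"}). No
#' continuity correction.
#'
#' @param n_NTS,n_TS observed mutation counts.
#' @param f_NTS,f_TS strand context frequencies.
#' @param null expected-split rule.
#' @return list with \code{chi2} and \code{p} (both NA when the total
#'   count is zero).
#' @export
asymmetry_test <- function(n_NTS, n_TS, f_NTS = 1, f_TS = 1,
                           null = c("freq", "even")) {
  null <- match.arg(null)
  total <- n_NTS + n_TS
  if (total == 0) return(list(chi2 = NA_real_, p = NA_real_))
  w <- if (null == "freq") c(f_NTS, f_TS) else c(1, 1)
  expected <- total * w / sum(w)
  chi2 <- sum((c(n_NTS, n_TS) - expected)^2 / expected)
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

default_min_count <- function(mode, organism) {
  if (mode == "single") 30L
  else if (organism == "human") 1000L
  else 19L
}

# palindromic dinucleotides have no resolvable strand orientation
is_palindromic_dinuc <- function(d) d == revcomp(d)

#' Transcriptional asymmetry analysis per mutation class
#'
#' Runs the full strand-asymmetry analysis: assigns events to the
#' transcribed/non-transcribed strand, tallies counts per class
#' (trinucleotide class for singles, canonical label for tandems),
#' normalizes by the strand k-mer frequencies of the gene set, tests each
#' class with enough events by chi-square, and applies Bonferroni
#' correction across the tested classes.
#'
#' @param events for \code{mode = "single"}, a classified SNV data.frame;
#'   for \code{mode = "tandem"}, a canonicalized tandem data.frame.
#' @param genome genome accepted by \code{\link{as_genome}}.
#' @param genes gene annotation data.frame.
#' @param mode \code{"single"} or \code{"tandem"}.
#' @param organism \code{"yeast"} or \code{"human"}; sets the default
#'   minimum event count per tested class (single: 30; tandem: 19 yeast,
#'   1000 human).
#' @param min_count override the class count threshold.
#' @param exclude_ids gene ids dropped from both mutation assignment and
#'   frequency counting; defaults to the repetitive rDNA/CUP1 deny-list for
#'   yeast and none for human.
#' @param stratify if TRUE, genes are ranked by expression into quartiles
#'   and the analysis is run independently on the top and bottom quartile
#'   with quartile-specific frequency tables.
#' @param null expected-split rule passed to \code{\link{asymmetry_test}}.
#' @return object of class \code{uv_asymmetry}: list with \code{records}
#'   (per-class data.frame), \code{pooled} (one-row summary over tested
#'   classes), counts of intergenic/excluded events, and parameters. When
#'   \code{stratify} is TRUE, a list with elements \code{top} and
#'   \code{bottom}.
#' @export
run_asymmetry <- function(events, genome, genes,
                          mode = c("single", "tandem"),
                          organism = c("yeast", "human"),
                          min_count = NULL,
                          exclude_ids = NULL,
                          stratify = FALSE,
                          null = "freq") {
  mode <- match.arg(mode)
  organism <- match.arg(organism)
  if (is.null(min_count)) min_count <- default_min_count(mode, organism)
  if (is.null(exclude_ids)) {
    exclude_ids <- if (organism == "yeast") YEAST_EXCLUDED_GENES else character()
  }
  genes <- validate_genes(genes)
  genes <- genes[!genes$gene_id %in% exclude_ids, , drop = FALSE]

  if (stratify) {
    if (all(is.na(genes$expression))) {
      stop("expression values required for quartile stratification")
    }
    ord <- order(genes$expression, genes$gene_id)
    ranked <- genes[ord, , drop = FALSE]
    qsize <- floor(nrow(ranked) / 4)
    bottom <- ranked[seq_len(qsize), , drop = FALSE]
    top <- ranked[seq(nrow(ranked) - qsize + 1L, nrow(ranked)), , drop = FALSE]
    return(list(
      top = run_asymmetry(events, genome, genes = top, mode = mode,
                          organism = organism, min_count = min_count,
                          exclude_ids = character(), stratify = FALSE,
                          null = null),
      bottom = run_asymmetry(events, genome, genes = bottom, mode = mode,
                             organism = organism, min_count = min_count,
                             exclude_ids = character(), stratify = FALSE,
                             null = null)))
  }

  genome <- as_genome(genome)
  k <- if (mode == "single") 3L else 2L
  freqs <- build_strand_freqs(genome, genes, exclude_ids = character(), k = k)

  if (mode == "single") {
    ev <- assign_gene_strand(events, genes)
    ev <- ev[!grepl("N", ev$context, fixed = TRUE), , drop = FALSE]
    ev$class_label <- paste0(ev$context, ":", ev$pyr_class)
    ev$freq_key <- ev$context
  } else {
    ev <- events
    if (!"canonical_label" %in% names(ev)) ev <- canonicalize_tandem(ev)
    # the event sits on the genomic strand carrying its canonical ref dinuc
    ev$flipped <- ev$canonical_strand == "minus"
    ev <- assign_gene_strand_tandem(ev, genes)
    ev$class_label <- ev$canonical_label
    ev$freq_key <- sub(">.*$", "", ev$canonical_label)
  }

  n_intergenic <- sum(ev$strand_class == "intergenic")
  n_excluded <- sum(ev$strand_class == "excluded")
  genic <- ev[ev$strand_class %in% c("NTS", "TS"), , drop = FALSE]

  labels <- sort(unique(genic$class_label))
  rows <- lapply(labels, function(lab) {
    sel <- genic[genic$class_label == lab, , drop = FALSE]
    key <- sel$freq_key[1]
    fi <- match(key, freqs$kmer)
    f_nts <- if (is.na(fi)) 0L else freqs$f_NTS[fi]
    f_ts <- if (is.na(fi)) 0L else freqs$f_TS[fi]
    n_nts <- sum(sel$strand_class == "NTS")
    n_ts <- sum(sel$strand_class == "TS")
    ambiguous <- mode == "tandem" && is_palindromic_dinuc(key)
    tested <- (n_nts + n_ts) >= min_count && f_nts > 0 && f_ts > 0 && !ambiguous
    ratio <- if (f_nts > 0 && f_ts > 0) {
      asymmetry_ratio(n_nts, n_ts, f_nts, f_ts)
    } else NA_real_
    tst <- if (tested) asymmetry_test(n_nts, n_ts, f_nts, f_ts, null = null)
           else list(chi2 = NA_real_, p = NA_real_)
    data.frame(class = lab, n_NTS = n_nts, n_TS = n_ts,
               f_NTS = f_nts, f_TS = f_ts, ratio = ratio,
               chi2 = tst$chi2, p = tst$p, tested = tested,
               stringsAsFactors = FALSE)
  })
  records <- if (length(rows)) do.call(rbind, rows) else
    data.frame(class = character(), n_NTS = integer(), n_TS = integer(),
               f_NTS = integer(), f_TS = integer(), ratio = numeric(),
               chi2 = numeric(), p = numeric(), tested = logical())
  m <- sum(records$tested)
  records$p_bonferroni <- ifelse(records$tested, pmin(1, m * records$p), NA_real_)
  rownames(records) <- NULL

  structure(list(records = records,
                 pooled = pooled_asymmetry(records, freqs, genic, null = null),
                 n_intergenic = n_intergenic, n_excluded = n_excluded,
                 m_tested = m, mode = mode, min_count = min_count,
                 null = null),
            class = "uv_asymmetry")
}

# Tandem strand assignment reuses the single-nucleotide machinery with
# `flipped` meaning "canonical orientation is the minus strand" and the
# position taken at the 5' base of the dinucleotide.
assign_gene_strand_tandem <- function(tandems, genes) {
  fake <- data.frame(chrom = tandems$chrom, pos = tandems$start_pos,
                     flipped = tandems$flipped, stringsAsFactors = FALSE)
  res <- assign_gene_strand(cbind(fake), genes)
  tandems$strand_class <- res$strand_class
  tandems$gene_id <- res$gene_id
  tandems
}

# Pooled (genome-wide) asymmetry over all genic events: total strand counts
# normalized by the summed frequencies of the distinct contexts involved,
# so the ratio is a mutation density ratio (events per available site).
pooled_asymmetry <- function(records, freqs, genic, null = "freq") {
  if (!nrow(genic)) {
    return(data.frame(n_NTS = 0L, n_TS = 0L, f_NTS = 0L, f_TS = 0L,
                      ratio = NA_real_, chi2 = NA_real_, p = NA_real_))
  }
  keys <- unique(genic$freq_key)
  fi <- match(keys, freqs$kmer)
  f_nts <- sum(freqs$f_NTS[fi], na.rm = TRUE)
  f_ts <- sum(freqs$f_TS[fi], na.rm = TRUE)
  n_nts <- sum(genic$strand_class == "NTS")
  n_ts <- sum(genic$strand_class == "TS")
  ratio <- if (f_nts > 0 && f_ts > 0) asymmetry_ratio(n_nts, n_ts, f_nts, f_ts)
           else NA_real_
  tst <- asymmetry_test(n_nts, n_ts, max(f_nts, 1), max(f_ts, 1), null = null)
  data.frame(n_NTS = n_nts, n_TS = n_ts, f_NTS = f_nts, f_TS = f_ts,
             ratio = ratio, chi2 = tst$chi2, p = tst$p)
}

#' @export
print.uv_asymmetry <- function(x, ...) {
  cat("Transcriptional asymmetry (", x$mode, " mode, min count ",
      x$min_count, ")\n", sep = "")
  cat("  genic events:", sum(x$records$n_NTS) + sum(x$records$n_TS),
      " intergenic:", x$n_intergenic, " excluded:", x$n_excluded, "\n")
  cat("  tested classes:", x$m_tested, "\n")
  cat(sprintf("  pooled NTS/TS ratio: %.3f (chi2 = %.2f, p = %.3g)\n",
              x$pooled$ratio, x$pooled$chi2, x$pooled$p))
  invisible(x)
}
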