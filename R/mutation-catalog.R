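# Reading, filtering, and structural partitioning of mutation call tables,
# plus normalization of single substitutions to the pyrimidine-strand
# convention with trinucleotide context.

DEFAULT_MITO_CHROMS <- c("chrM", "chrMT", "MT")

new_calls <- function(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      support_fraction = NA_real_) {
  if (length(pos) == 0L) {
    return(data.frame(sample_id = character(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      support_fraction = numeric(), stringsAsFactors = FALSE))
  }
  data.frame(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt,
             support_fraction = as.numeric(support_fraction),
             stringsAsFactors = FALSE)
}

validate_calls <- function(calls) {
  stopifnot(is.data.frame(calls))
  need <- c("sample_id", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(calls))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!"support_fraction" %in% names(calls)) calls$support_fraction <- NA_real_
  bad <- which(calls$ref == calls$alt)
  if (length(bad)) stop("ref equals alt at row ", bad[1])
  if (any(calls$pos < 1L)) stop("positions must be >= 1")
  calls
}

#' Read a mutation call table
#'
#' Reads per-sample somatic mutation calls from a TSV file (columns
#' \code{sample}, \code{chrom}, \code{pos}, \code{ref}, \code{alt}, and
#' optionally \code{support_fraction}) or a VCF. Multi-allelic VCF records
#' are expanded to one call per alternate allele. Records whose alleles
#' contain characters other than A, C, G, T are rejected; the number
#' rejected is attached as attribute \code{n_rejected} and reported with a
#' warning.
#'
#' @param path path to the input file.
#' @param format \code{"tsv"} or \code{"vcf"}.
#' @return data.frame of calls with columns \code{sample_id}, \code{chrom},
#'   \code{pos} (1-based), \code{ref}, \code{alt}, \code{support_fraction}.
#' @export
read_mutation_table <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  calls <- if (format == "tsv") read_mutation_tsv(path) else read_mutation_vcf(path)
  ok <- grepl("^[ACGT]+$", calls$ref) & grepl("^[ACGT]+$", calls$alt)
  n_rej <- sum(!ok)
  if (n_rej > 0) {
    warning(n_rej, " record(s) with non-ACGT alleles rejected")
  }
  calls <- calls[ok, , drop = FALSE]
  rownames(calls) <- NULL
  calls <- validate_calls(calls)
  attr(calls, "n_rejected") <- n_rej
  calls
}

read_mutation_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(new_calls())
  fields <- strsplit(lines, "\t| +")
  header <- tolower(fields[[1]])
  has_header <- any(c("sample", "sample_id") %in% header)
  col_of <- function(nms, default) {
    i <- which(header %in% nms)
    if (length(i)) i[1] else default
  }
  if (has_header) {
    idx <- c(sample = col_of(c("sample", "sample_id"), NA),
             chrom = col_of(c("chrom", "chr", "chromosome"), NA),
             pos = col_of(c("pos", "position"), NA),
             ref = col_of("ref", NA), alt = col_of("alt", NA),
             sf = col_of(c("support_fraction", "frequency", "freq"), NA))
    if (anyNA(idx[1:5])) {
      stop("TSV header must name sample, chrom, pos, ref, alt columns")
    }
    fields <- fields[-1]
    line_no <- seq_along(fields) + 1L
  } else {
    idx <- c(sample = 1L, chrom = 2L, pos = 3L, ref = 4L, alt = 5L, sf = 6L)
    line_no <- seq_along(fields)
  }
  grab <- function(row, i) if (!is.na(i) && length(row) >= i) row[i] else NA_character_
  parse_row <- function(row, ln) {
    if (length(row) < 5L) stop("malformed row at line ", ln, ": fewer than 5 fields")
    pos <- suppressWarnings(as.integer(grab(row, idx[["pos"]])))
    if (is.na(pos)) stop("malformed row at line ", ln, ": non-integer position")
    list(grab(row, idx[["sample"]]), grab(row, idx[["chrom"]]), pos,
         toupper(grab(row, idx[["ref"]])), toupper(grab(row, idx[["alt"]])),
         suppressWarnings(as.numeric(grab(row, idx[["sf"]]))))
  }
  parsed <- Map(parse_row, fields, line_no)
  new_calls(
    sample_id = vapply(parsed, `[[`, "", 1L),
    chrom = vapply(parsed, `[[`, "", 2L),
    pos = vapply(parsed, `[[`, 1L, 3L),
    ref = vapply(parsed, `[[`, "", 4L),
    alt = vapply(parsed, `[[`, "", 5L),
    support_fraction = vapply(parsed, `[[`, 0, 6L)
  )
}

read_mutation_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || length(fix) == 0) return(new_calls())
  if (is.null(dim(fix))) {
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  if (nrow(fix) == 0) return(new_calls())
  default_sample <- sub("\\.[^.]*$", "", basename(path))
  gt <- if (ncol(v@gt) > 1) v@gt else NULL
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (k in seq_along(alts)) {
      samples <- default_sample
      if (!is.null(gt)) {
        gts <- gt[i, -1]
        carriers <- names(gts)[grepl(as.character(k),
                                     sub(":.*$", "", gts), fixed = TRUE)]
        samples <- if (length(carriers)) carriers else character()
      }
      for (s in samples) {
        rows[[length(rows) + 1L]] <- list(s, fix[i, "CHROM"],
                                          as.integer(fix[i, "POS"]),
                                          toupper(fix[i, "REF"]),
                                          toupper(alts[k]))
      }
    }
  }
  if (!length(rows)) return(new_calls())
  new_calls(
    sample_id = vapply(rows, `[[`, "", 1L),
    chrom = vapply(rows, `[[`, "", 2L),
    pos = vapply(rows, `[[`, 1L, 3L),
    ref = vapply(rows, `[[`, "", 4L),
    alt = vapply(rows, `[[`, "", 5L),
    support_fraction = rep(NA_real_, length(rows))
  )
}

#' Filter calls by read-support fraction
#'
#' Retains calls supported by strictly more than \code{min_fraction} of the
#' reads covering the site. Calls without a support fraction are retained;
#' their number is attached as attribute \code{n_missing_support}.
#'
#' @param calls data.frame of mutation calls.
#' @param min_fraction threshold in \[0, 1\]; default 0.45.
#' @return filtered data.frame.
#' @export
filter_support <- function(calls, min_fraction = 0.45) {
  calls <- validate_calls(calls)
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  missing <- is.na(calls$support_fraction)
  keep <- missing | calls$support_fraction > min_fraction
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_missing_support") <- sum(missing)
  out
}

#' Keep only single-isolate variants
#'
#' Removes every variant (chrom, pos, ref, alt) observed in two or more
#' distinct samples, from all samples. Shared variants predate the
#' mutagenic treatment or are systematic artifacts.
#'
#' @param calls data.frame of mutation calls.
#' @return filtered data.frame with attribute \code{n_shared_removed}.
#' @export
filter_sample_unique <- function(calls) {
  calls <- validate_calls(calls)
  key <- paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = "\r")
  n_samples <- vapply(split(calls$sample_id, key),
                      function(s) length(unique(s)), 1L)
  shared <- names(n_samples)[n_samples >= 2L]
  keep <- !(key %in% shared)
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_shared_removed") <- sum(!keep)
  out
}

#' Drop calls on denied chromosomes
#'
#' By default removes mitochondrial records.
#'
#' @param calls data.frame of mutation calls.
#' @param deny character vector of chromosome names to exclude.
#' @return filtered data.frame.
#' @export
filter_chroms <- function(calls, deny = DEFAULT_MITO_CHROMS) {
  calls <- validate_calls(calls)
  out <- calls[!calls$chrom %in% deny, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Partition calls into singles, tandems, triples, indels
#'
#' Single-base substitutions at adjacent positions within one sample and
#' chromosome are merged: maximal runs of two adjacent substituted positions
#' become one tandem event, runs of three one triple event. Pre-merged
#' multi-nucleotide rows (equal-length ref/alt of length 2 or 3) are routed
#' directly to the corresponding category. Length differences between ref
#' and alt mark indels, which never merge. Runs longer than three positions
#' go to \code{complex}.
#'
#' @param calls data.frame of mutation calls.
#' @return object of class \code{uv_event_partition}: a list with elements
#'   \code{singles}, \code{tandems}, \code{triples}, \code{indels},
#'   \code{complex}, and \code{n_input}. Tandems carry \code{start_pos}
#'   (1-based plus-strand position of the 5' base), \code{ref_dinuc},
#'   \code{alt_dinuc}.
#' @export
partition_events <- function(calls) {
  calls <- validate_calls(calls)
  reflen <- nchar(calls$ref)
  altlen <- nchar(calls$alt)
  is_indel <- reflen != altlen
  indels <- calls[is_indel, , drop = FALSE]
  subs <- calls[!is_indel, , drop = FALSE]

  pre_tandem <- subs[nchar(subs$ref) == 2L, , drop = FALSE]
  pre_triple <- subs[nchar(subs$ref) == 3L, , drop = FALSE]
  cx <- subs[nchar(subs$ref) > 3L, , drop = FALSE]
  single_rows <- subs[nchar(subs$ref) == 1L, , drop = FALSE]

  singles <- list()
  tandems <- list()
  triples <- list()
  complex_runs <- list()

  if (nrow(single_rows)) {
    grp <- paste(single_rows$sample_id, single_rows$chrom, sep = "\r")
    for (g in split(seq_len(nrow(single_rows)), grp)) {
      d <- single_rows[g, , drop = FALSE]
      if (anyDuplicated(d$pos)) {
        dup <- d$pos[duplicated(d$pos)][1]
        stop("conflicting duplicate records at ", d$chrom[1], ":", dup,
             " in sample ", d$sample_id[1])
      }
      d <- d[order(d$pos), , drop = FALSE]
      run_id <- cumsum(c(1L, diff(d$pos) != 1L))
      for (r in split(seq_len(nrow(d)), run_id)) {
        rd <- d[r, , drop = FALSE]
        n <- nrow(rd)
        if (n == 1L) {
          singles[[length(singles) + 1L]] <- rd
        } else if (n == 2L) {
          tandems[[length(tandems) + 1L]] <- data.frame(
            sample_id = rd$sample_id[1], chrom = rd$chrom[1],
            start_pos = rd$pos[1],
            ref_dinuc = paste(rd$ref, collapse = ""),
            alt_dinuc = paste(rd$alt, collapse = ""),
            stringsAsFactors = FALSE)
        } else if (n == 3L) {
          triples[[length(triples) + 1L]] <- data.frame(
            sample_id = rd$sample_id[1], chrom = rd$chrom[1],
            start_pos = rd$pos[1],
            ref_tri = paste(rd$ref, collapse = ""),
            alt_tri = paste(rd$alt, collapse = ""),
            stringsAsFactors = FALSE)
        } else {
          complex_runs[[length(complex_runs) + 1L]] <- rd
        }
      }
    }
  }

  bind <- function(lst, proto) {
    if (length(lst)) do.call(rbind, lst) else proto
  }
  tandem_proto <- data.frame(sample_id = character(), chrom = character(),
                             start_pos = integer(), ref_dinuc = character(),
                             alt_dinuc = character(), stringsAsFactors = FALSE)
  triple_proto <- data.frame(sample_id = character(), chrom = character(),
                             start_pos = integer(), ref_tri = character(),
                             alt_tri = character(), stringsAsFactors = FALSE)

  tandems_df <- bind(tandems, tandem_proto)
  if (nrow(pre_tandem)) {
    tandems_df <- rbind(tandems_df, data.frame(
      sample_id = pre_tandem$sample_id, chrom = pre_tandem$chrom,
      start_pos = pre_tandem$pos, ref_dinuc = pre_tandem$ref,
      alt_dinuc = pre_tandem$alt, stringsAsFactors = FALSE))
  }
  triples_df <- bind(triples, triple_proto)
  if (nrow(pre_triple)) {
    triples_df <- rbind(triples_df, data.frame(
      sample_id = pre_triple$sample_id, chrom = pre_triple$chrom,
      start_pos = pre_triple$pos, ref_tri = pre_triple$ref,
      alt_tri = pre_triple$alt, stringsAsFactors = FALSE))
  }
  singles_df <- bind(singles, new_calls())
  complex_df <- bind(complex_runs, new_calls())
  if (nrow(cx)) complex_df <- rbind(complex_df, cx)
  rownames(singles_df) <- rownames(tandems_df) <- rownames(triples_df) <- NULL

  structure(list(singles = singles_df, tandems = tandems_df,
                 triples = triples_df, indels = indels,
                 complex = complex_df, n_input = nrow(calls)),
            class = "uv_event_partition")
}

#' @export
print.uv_event_partition <- function(x, ...) {
  cat("Event partition of", x$n_input, "mutation records\n")
  cat("  singles:", nrow(x$singles), " tandems:", nrow(x$tandems),
      " triples:", nrow(x$triples), " indels:", nrow(x$indels),
      " complex:", nrow(x$complex), "\n")
  invisible(x)
}

#' Classify single substitutions on the pyrimidine strand
#'
#' Normalizes each single-base substitution to the strand carrying the
#' mutated pyrimidine (C or T): records with a purine reference are
#' reverse-complemented, alleles and flanking context alike. Each call gets
#' a six-way class (C>A, C>G, C>T, T>A, T>C, T>G), its trinucleotide context
#' on the pyrimidine strand, and a dipyrimidine category: THREE_PRIME when
#' the mutated base sits in the 3' position of a dipyrimidine (its 5'
#' neighbor is a pyrimidine), FIVE_PRIME when only its 3' neighbor is a
#' pyrimidine, NONE otherwise. When both neighbors are pyrimidines the tie
#' goes to the category named by \code{dipyr_tie}.
#'
#' @param calls data.frame of single-base substitution calls.
#' @param genome genome accepted by \code{\link{as_genome}}.
#' @param dipyr_tie \code{"three_prime"} (default) or \code{"five_prime"}.
#' @return data.frame with the input columns plus \code{pyr_class},
#'   \code{context}, \code{flipped}, \code{dipyr}. Contexts at contig edges
#'   are N-padded.
#' @export
classify_snv <- function(calls, genome, dipyr_tie = c("three_prime", "five_prime")) {
  dipyr_tie <- match.arg(dipyr_tie)
  calls <- validate_calls(calls)
  genome <- as_genome(genome)
  if (any(nchar(calls$ref) != 1L | nchar(calls$alt) != 1L)) {
    stop("classify_snv expects single-base substitutions")
  }
  n <- nrow(calls)
  context <- character(n)
  for (i in seq_len(n)) {
    ctx <- seq_window(genome, calls$chrom[i], calls$pos[i] - 1L, calls$pos[i] + 1L)
    if (substr(ctx, 2, 2) != calls$ref[i]) {
      stop("reference mismatch at ", calls$chrom[i], ":", calls$pos[i],
           " (genome ", substr(ctx, 2, 2), ", call ", calls$ref[i], ")")
    }
    context[i] <- ctx
  }
  flipped <- calls$ref %in% PURINES
  pyr_ref <- ifelse(flipped, complement(calls$ref), calls$ref)
  pyr_alt <- ifelse(flipped, complement(calls$alt), calls$alt)
  context[flipped] <- revcomp(context[flipped])
  n5 <- substr(context, 1, 1)
  n3 <- substr(context, 3, 3)
  p5 <- n5 %in% PYRIMIDINES
  p3 <- n3 %in% PYRIMIDINES
  dipyr <- if (dipyr_tie == "three_prime") {
    ifelse(p5, "THREE_PRIME", ifelse(p3, "FIVE_PRIME", "NONE"))
  } else {
    ifelse(p3, "FIVE_PRIME", ifelse(p5, "THREE_PRIME", "NONE"))
  }
  out <- calls
  out$pyr_class <- paste0(pyr_ref, ">", pyr_alt)
  out$context <- context
  out$flipped <- flipped
  out$dipyr <- dipyr
  out
}

#' Canonical label for tandem substitutions
#'
#' A tandem substitution and its reverse complement describe the same event
#' on opposite strands (AC>TT on the plus strand reads GT>AA on the minus).
#' The canonical label is chosen by a fixed total order: the orientation
#' with the lexicographically smaller reference dinucleotide wins; on a tie
#' the smaller alternate dinucleotide wins; a full tie keeps the plus
#' orientation. The choice is recorded in \code{canonical_strand}.
#'
#' @param tandems data.frame with \code{ref_dinuc} and \code{alt_dinuc}
#'   (as produced by \code{\link{partition_events}}).
#' @return the input with columns \code{canonical_label} and
#'   \code{canonical_strand} added; idempotent.
#' @export
canonicalize_tandem <- function(tandems) {
  stopifnot(all(c("ref_dinuc", "alt_dinuc") %in% names(tandems)))
  ref <- toupper(tandems$ref_dinuc)
  alt <- toupper(tandems$alt_dinuc)
  rc_ref <- revcomp(ref)
  rc_alt <- revcomp(alt)
  use_rc <- (rc_ref < ref) | (rc_ref == ref & rc_alt < alt)
  lab_ref <- ifelse(use_rc, rc_ref, ref)
  lab_alt <- ifelse(use_rc, rc_alt, alt)
  tandems$canonical_label <- paste0(lab_ref, ">", lab_alt)
  tandems$canonical_strand <- ifelse(use_rc, "minus", "plus")
  tandems
}
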