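# Reporter mutation/reversion frequencies, cohort frequency ratios, and
# recurrent-mutation odds ratios from sample tables.

#' Forward-reporter mutation frequency
#'
#' Converts colony counts on selective and permissive plates to a mutation
#' frequency. Each dilution is the multiplicative factor restoring the
#' plate count to the undiluted suspension (plating a 1e-5 dilution means
#' \code{dil = 1e5}):
#' \deqn{f = (n_{sel} \cdot dil_{sel}) / (n_{perm} \cdot dil_{perm})}
#'
#' @param n_selective colonies on selective plates.
#' @param dil_selective fold-dilution factor for the selective plating.
#' @param n_permissive colonies on permissive plates (must be positive).
#' @param dil_permissive fold-dilution factor for the permissive plating.
#' @return mutation frequency (vectorized).
#' @export
reporter_frequency <- function(n_selective, dil_selective,
                               n_permissive, dil_permissive) {
  stopifnot(all(n_selective >= 0), all(dil_selective > 0),
            all(dil_permissive > 0))
  if (any(n_permissive <= 0)) stop("permissive plate count must be positive")
  (n_selective * dil_selective) / (n_permissive * dil_permissive)
}

#' Reversion frequency with zero-count convention
#'
#' Frequency of revertant colonies per cell plated. When no revertants are
#' recovered, \code{zero_policy = "max_estimate"} reports the maximum
#' estimated frequency as if the replicate had contained one revertant
#' colony, flagged as an upper bound; \code{"literal"} reports zero.
#'
#' @param colonies revertant colony count.
#' @param cells_plated number of cells plated (positive).
#' @param zero_policy \code{"max_estimate"} (default) or \code{"literal"}.
#' @return list with \code{frequency} and \code{is_upper_bound}.
#' @export
reversion_frequency <- function(colonies, cells_plated,
                                zero_policy = c("max_estimate", "literal")) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(cells_plated > 0, colonies >= 0)
  if (colonies == 0 && zero_policy == "max_estimate") {
    list(frequency = 1 / cells_plated, is_upper_bound = TRUE)
  } else {
    list(frequency = colonies / cells_plated, is_upper_bound = FALSE)
  }
}

#' Compare reversion frequencies between two conditions
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test, exact for small
#' tie-free samples; with ties across groups the mid-rank normal
#' approximation is used.
#'
#' @param x,y numeric vectors of per-replicate frequencies (at least 3
#'   each).
#' @return list with \code{median_x}, \code{median_y}, \code{U}, \code{p}.
#' @export
compare_reversion <- function(x, y) {
  if (length(x) < 3 || length(y) < 3) stop("need at least 3 replicates per group")
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = TRUE,
                                            correct = FALSE))
  list(median_x = stats::median(x), median_y = stats::median(y),
       U = unname(wt$statistic), p = wt$p.value)
}

#' Per-tumor mutation class frequencies for one cohort
#'
#' @param counts named integer vector: total mutations per class summed
#'   over the cohort's tumors.
#' @param n_tumors number of tumors in the cohort.
#' @param label cohort label.
#' @return object of class \code{uv_cohort_freq}.
#' @export
cohort_class_freq <- function(counts, n_tumors, label = "cohort") {
  stopifnot(n_tumors > 0, all(counts >= 0))
  structure(list(counts = counts, n_tumors = n_tumors, label = label),
            class = "uv_cohort_freq")
}

#' Ratio of per-tumor mutation frequencies between cohorts
#'
#' For each mutation class, the ratio of mean mutations per tumor in cohort
#' \code{a} over cohort \code{b}. Classes failing the per-cohort minimum
#' total counts are flagged untested. A zero denominator with passing
#' counts yields \code{Inf}.
#'
#' @param a,b \code{uv_cohort_freq} objects with matching class universes.
#' @param min_counts length-2 integer vector: minimum total count required
#'   in \code{a} and in \code{b}.
#' @return data.frame with per-class frequencies, ratio, tested flag.
#' @export
cohort_ratio <- function(a, b, min_counts = c(150L, 10L)) {
  stopifnot(inherits(a, "uv_cohort_freq"), inherits(b, "uv_cohort_freq"))
  classes <- union(names(a$counts), names(b$counts))
  ca <- ifelse(is.na(a$counts[classes]), 0L, a$counts[classes])
  cb <- ifelse(is.na(b$counts[classes]), 0L, b$counts[classes])
  fa <- ca / a$n_tumors
  fb <- cb / b$n_tumors
  tested <- ca >= min_counts[1] & cb >= min_counts[2]
  ratio <- ifelse(fb > 0, fa / fb, Inf)
  data.frame(class = classes, count_a = as.integer(ca),
             count_b = as.integer(cb), per_tumor_a = fa, per_tumor_b = fb,
             ratio = ratio, tested = tested, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Hygiene filters for cancer-sample mutation tables
#'
#' Applies three explicit filters: rows with an unspecified tissue of
#' origin, rows with an ambiguous nucleotide change annotation (missing,
#' empty, or containing characters other than standard change syntax), and
#' duplicated (sample, gene, mutation) rows. Removal counts are attached as
#' attribute \code{filter_counts}.
#'
#' @param samples data.frame with columns \code{sample_id}, \code{tissue},
#'   \code{gene}, \code{mutation}.
#' @return filtered data.frame.
#' @export
filter_cosmic_samples <- function(samples) {
  need <- c("sample_id", "tissue", "gene", "mutation")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  tissue_bad <- is.na(samples$tissue) | samples$tissue %in% c("", "NS")
  s1 <- samples[!tissue_bad, , drop = FALSE]
  mut_bad <- is.na(s1$mutation) | s1$mutation == "" |
    grepl("[?]", s1$mutation)
  s2 <- s1[!mut_bad, , drop = FALSE]
  dup <- duplicated(s2[, c("sample_id", "gene", "mutation")])
  out <- s2[!dup, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_counts") <- c(unspecified_tissue = sum(tissue_bad),
                                  ambiguous_mutation = sum(mut_bad),
                                  duplicated = sum(dup))
  out
}

#' Odds ratios for recurrent mutations between tissue cohorts
#'
#' For each mutation observed at least \code{min_occurrences} times in the
#' dataset, computes the odds ratio of carrying the mutation in the focal
#' cohort relative to the comparison cohort:
#' \deqn{OR = (a / b) / (c / d)}
#' with \code{a}/\code{b} the focal-cohort samples with/without the
#' mutation and \code{c}/\code{d} likewise for the comparison cohort. A
#' zero among \code{b}, \code{c}, \code{d} yields an \code{Inf}/0 sentinel
#' with a flag unless a continuity correction is requested.
#'
#' @param samples table of (sample_id, tissue, gene, mutation); pass
#'   through \code{\link{filter_cosmic_samples}} first.
#' @param focal_label tissue label of the focal cohort (e.g. skin).
#' @param other_label optional tissue label restricting the comparison
#'   cohort (e.g. thyroid); default all non-focal samples.
#' @param min_occurrences minimum dataset-wide occurrence count (>= 1).
#' @param continuity additive continuity correction applied to all four
#'   cells when any is zero (0 disables; 0.5 is Haldane-Anscombe).
#' @param cohort_sizes optional named vector giving the number of screened
#'   samples per tissue label. Required when the table lists only mutation
#'   carriers; by default cohort sizes are the distinct sample counts
#'   observed in the table.
#' @return data.frame of per-mutation records with cells, odds ratio,
#'   occurrence count, and degeneracy flag, ordered by gene then mutation.
#' @export
recurrent_odds_ratios <- function(samples, focal_label, other_label = NULL,
                                  min_occurrences = 10L, continuity = 0,
                                  cohort_sizes = NULL) {
  if (min_occurrences < 1) stop("min_occurrences must be >= 1")
  is_focal <- samples$tissue == focal_label
  in_comp <- if (is.null(other_label)) !is_focal else
    samples$tissue == other_label
  universe <- samples[is_focal | in_comp, , drop = FALSE]
  if (is.null(cohort_sizes)) {
    n_focal <- length(unique(samples$sample_id[is_focal]))
    n_comp <- length(unique(samples$sample_id[in_comp]))
  } else {
    n_focal <- cohort_sizes[[focal_label]]
    n_comp <- if (is.null(other_label)) {
      sum(unlist(cohort_sizes[setdiff(names(cohort_sizes), focal_label)]))
    } else cohort_sizes[[other_label]]
  }

  key <- paste(universe$gene, universe$mutation, sep = "\r")
  occ <- vapply(split(universe$sample_id, key),
                function(s) length(unique(s)), 1L)
  recurrent <- names(occ)[occ >= min_occurrences]
  if (!length(recurrent)) {
    return(data.frame(gene = character(), mutation = character(),
                      a = integer(), b = integer(), c = integer(),
                      d = integer(), odds_ratio = numeric(),
                      n_occurrences = integer(), degenerate = logical()))
  }
  rows <- lapply(recurrent, function(kk) {
    parts <- strsplit(kk, "\r", fixed = TRUE)[[1]]
    sel <- universe[key == kk, , drop = FALSE]
    carriers_focal <- unique(sel$sample_id[sel$tissue == focal_label])
    carriers_comp <- unique(sel$sample_id[!(sel$tissue == focal_label)])
    a <- length(carriers_focal)
    b <- n_focal - a
    cc <- length(carriers_comp)
    d <- n_comp - cc
    degenerate <- any(c(b, cc, d) == 0)
    cells <- c(a, b, cc, d)
    if (degenerate && continuity > 0) cells <- cells + continuity
    or <- (cells[1] / cells[2]) / (cells[3] / cells[4])
    data.frame(gene = parts[1], mutation = parts[2], a = a, b = b, c = cc,
               d = d, odds_ratio = or, n_occurrences = unname(occ[kk]),
               degenerate = degenerate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$mutation), , drop = FALSE]
  rownames(out) <- NULL
  out
}
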