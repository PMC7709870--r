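# Forward simulator of the UV lesion -> repair -> translesion-bypass
# process. Lesions (not mutations) are the primitive: one truth set drives
# the mutation-catalog pipeline and the damage-map pipeline alike.

outcome <- function(kind, weight, pos = NA_integer_, map = NULL) {
  list(kind = kind, weight = weight, pos = pos, map = map)
}

default_lesion_classes <- function() {
  # CPD/6-4PP: dipyrimidine lesions; mutagenic bypass gives mostly single
  # substitutions at the lesion bases (C->T, T->C), occasionally tandems.
  pyr_map <- c(C = "T", T = "C")
  list(
    CPD = list(
      targets = DIPYR_DINUCS, formation = 4e-4,
      outcomes = list(outcome("single", 0.55, pos = 2L, map = pyr_map),
                      outcome("single", 0.20, pos = 1L, map = pyr_map),
                      outcome("tandem", 0.05, map = pyr_map),
                      outcome("none", 0.20))),
    # 6-4PP formation follows the endonuclease cutting preference
    # TC > TT > CC > CT rather than site abundance
    SIXFOUR = list(
      targets = DIPYR_DINUCS,
      formation = c(TC = 6e-4, TT = 3e-4, CC = 3e-4, CT = 1.2e-4),
      outcomes = list(outcome("single", 0.60, pos = 2L, map = pyr_map),
                      outcome("single", 0.10, pos = 1L, map = pyr_map),
                      outcome("tandem", 0.05, map = pyr_map),
                      outcome("none", 0.25))),
    # thymine-adenine photoproduct: A->T at the lesion's 3' base, read as
    # T>A at NTA on the opposite strand
    TA_PP = list(
      targets = "TA", formation = 1.5e-4,
      outcomes = list(outcome("single", 0.90, pos = 2L, map = c(A = "T")),
                      outcome("none", 0.10))),
    # adenine-cytosine photoproduct: tandem AC>TT / AC>CT or single A>T;
    # formation set so AC>TT tandems run about twice the CC>TT level
    AC_PP = list(
      targets = "AC", formation = 1e-4,
      outcomes = list(outcome("tandem", 0.50, map = c(A = "T", C = "T")),
                      outcome("tandem", 0.20, map = c(A = "C", C = "T")),
                      outcome("single", 0.20, pos = 1L, map = c(A = "T")),
                      outcome("none", 0.10)))
  )
}

#' Repair survival presets by repair genotype
#'
#' Probability that a lesion survives repair long enough to be fixed as a
#' mutation, by the role of the lesion-bearing strand in an overlapping
#' gene. Transcription-coupled repair acts only on the transcribed strand,
#' so in repair-proficient cells s_TS < s_NTS; loss of global-genomic
#' repair (rad16) raises both, the TS still lower; loss of
#' transcription-coupled repair (rad26) equalizes the two.
#'
#' @param genotype \code{"WT"}, \code{"rad16"}, or \code{"rad26"}.
#' @return list with \code{s_NTS} and \code{s_TS}.
#' @export
repair_preset <- function(genotype = c("WT", "rad16", "rad26")) {
  genotype <- match.arg(genotype)
  switch(genotype,
         WT = list(s_NTS = 0.5, s_TS = 0.25),
         rad16 = list(s_NTS = 0.95, s_TS = 0.15),
         rad26 = list(s_NTS = 0.5, s_TS = 0.5))
}

#' Simulator configuration
#'
#' Full parameterization of the synthetic lesion/repair/bypass generator.
#' Defaults emulate repeated UV exposure of repair-proficient diploid
#' yeast, scaled to a desk-size genome.
#'
#' @param seed integer seed; identical configurations reproduce identical
#'   outputs byte for byte.
#' @param genome_length total genome length in bp (>= 1000).
#' @param gc_fraction genomic G+C fraction.
#' @param n_genes number of non-overlapping genes to place.
#' @param gene_length_mean mean gene length (gamma-distributed lengths).
#' @param n_isolates number of independently mutagenized isolates.
#' @param n_doses number of UV exposures per isolate.
#' @param genotype repair genotype preset (see \code{\link{repair_preset}}).
#' @param repair optional list(s_NTS, s_TS) overriding the preset.
#' @param lesion_classes named list of lesion class definitions (targets,
#'   per-site per-dose formation probability, bypass outcome
#'   distribution); default covers CPD, 6-4PP, TA and AC photoproducts.
#' @param expression_meanlog,expression_sdlog log-normal expression
#'   parameters for gene annotations.
#' @return object of class \code{uv_sim_config}.
#' @export
sim_config <- function(seed = 1L, genome_length = 200000L,
                       gc_fraction = 0.38, n_genes = 120L,
                       gene_length_mean = 1200, n_isolates = 12L,
                       n_doses = 15L, genotype = "WT", repair = NULL,
                       lesion_classes = default_lesion_classes(),
                       expression_meanlog = 2, expression_sdlog = 1) {
  if (genome_length < 1000) stop("genome_length must be >= 1000")
  stopifnot(gc_fraction >= 0, gc_fraction <= 1)
  if (is.null(repair)) repair <- repair_preset(genotype)
  stopifnot(repair$s_NTS >= 0, repair$s_NTS <= 1,
            repair$s_TS >= 0, repair$s_TS <= 1)
  for (cl in lesion_classes) {
    w <- vapply(cl$outcomes, `[[`, 1, "weight")
    if (abs(sum(w) - 1) > 1e-8) stop("outcome weights must sum to 1")
    if (any(cl$formation < 0) || any(cl$formation > 1)) {
      stop("formation must be in [0,1]")
    }
    if (length(cl$formation) > 1 &&
        !all(cl$targets %in% names(cl$formation))) {
      stop("per-target formation must name every target dinucleotide")
    }
  }
  structure(list(seed = as.integer(seed), genome_length = genome_length,
                 gc_fraction = gc_fraction, n_genes = n_genes,
                 gene_length_mean = gene_length_mean,
                 n_isolates = n_isolates, n_doses = n_doses,
                 genotype = genotype, repair = repair,
                 lesion_classes = lesion_classes,
                 expression_meanlog = expression_meanlog,
                 expression_sdlog = expression_sdlog),
            class = "uv_sim_config")
}

#' Generate a synthetic genome and gene annotation
#'
#' Bases are drawn i.i.d. at the configured G+C fraction on one chromosome;
#' genes of gamma-distributed length are placed without overlap, each with
#' a random strand and log-normal expression value.
#'
#' @param cfg a \code{uv_sim_config}.
#' @return list with \code{genome} (named character vector, one chromosome
#'   \code{chrI}) and \code{genes} (annotation data.frame with gene_id,
#'   chrom, tss, tes, strand, expression).
#' @export
generate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "uv_sim_config"))
  set.seed(cfg$seed)
  p <- c(A = (1 - cfg$gc_fraction) / 2, C = cfg$gc_fraction / 2,
         G = cfg$gc_fraction / 2, T = (1 - cfg$gc_fraction) / 2)
  seq <- paste(sample(BASES, cfg$genome_length, replace = TRUE, prob = p),
               collapse = "")
  genome <- stats::setNames(seq, "chrI")

  lens <- pmax(300L, round(stats::rgamma(cfg$n_genes, shape = 4,
                                         scale = cfg$gene_length_mean / 4)))
  # place each gene uniformly in the free gaps that still fit it,
  # longest first to limit fragmentation
  free <- IRanges::IRanges(1L, cfg$genome_length)
  starts <- integer(cfg$n_genes)
  for (i in order(lens, decreasing = TRUE)) {
    fits <- free[IRanges::width(free) >= lens[i]]
    if (!length(fits)) {
      stop("could not place ", cfg$n_genes,
           " non-overlapping genes; reduce n_genes or lengths")
    }
    room <- IRanges::width(fits) - lens[i] + 1L
    g <- if (length(fits) == 1L) 1L else
      sample.int(length(fits), 1L, prob = room)
    s <- BiocGenerics::start(fits)[g] +
      (if (room[g] > 1L) sample.int(room[g], 1L) - 1L else 0L)
    starts[i] <- s
    free <- IRanges::setdiff(free, IRanges::IRanges(s, s + lens[i] - 1L))
  }
  strand <- sample(c("+", "-"), cfg$n_genes, replace = TRUE)
  expr <- stats::rlnorm(cfg$n_genes, cfg$expression_meanlog,
                        cfg$expression_sdlog)
  ends <- starts + lens - 1L
  genes <- data.frame(
    gene_id = if (cfg$n_genes > 0) sprintf("G%04d", seq_len(cfg$n_genes))
              else character(),
    chrom = rep("chrI", cfg$n_genes),
    tss = as.integer(ifelse(strand == "+", starts, ends)),
    tes = as.integer(ifelse(strand == "+", ends, starts)),
    strand = strand, expression = expr, stringsAsFactors = FALSE)
  list(genome = genome, genes = genes)
}

# per-position gene-strand coverage flags for one chromosome
strand_coverage <- function(genes, chrom, len) {
  cov_plus <- logical(len)
  cov_minus <- logical(len)
  sel <- genes[genes$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(sel))) {
    idx <- sel$start[i]:sel$end[i]
    if (sel$strand[i] == "+") cov_plus[idx] <- TRUE else cov_minus[idx] <- TRUE
  }
  list(plus = cov_plus, minus = cov_minus)
}

#' Simulate per-isolate mutation tables from a lesion model
#'
#' For each isolate and dose, lesions form independently at each target
#' dinucleotide on each strand with the class's formation probability. A
#' lesion inside a gene survives repair with probability \code{s_NTS} or
#' \code{s_TS} according to whether the lesion-bearing strand is the gene's
#' non-transcribed or transcribed strand (intergenic lesions use
#' \code{s_NTS}; positions transcribed on both strands use \code{s_TS}).
#' Surviving lesions draw a bypass outcome (single substitution at the 5'
#' or 3' lesion base, tandem substitution, or none) and the resulting calls
#' are written in plus-strand coordinates. Every formed lesion is logged in
#' the truth table regardless of fate.
#'
#' @param cfg a \code{uv_sim_config}.
#' @param genome,genes output of \code{\link{generate_genome}}.
#' @return list with \code{calls} (mutation table across isolates) and
#'   \code{truth} (per-lesion truth table).
#' @export
simulate_mutation_tables <- function(cfg, genome, genes) {
  stopifnot(inherits(cfg, "uv_sim_config"))
  genome <- as_genome(genome)
  genes <- validate_genes(genes)
  set.seed(cfg$seed + 1L)

  chroms <- names(genome)
  site_index <- lapply(chroms, function(ch) {
    v <- chrom_chars(genome, ch)
    di <- paste0(v[-length(v)], v[-1L])
    split(seq_along(di), di)
  })
  names(site_index) <- chroms
  coverage <- lapply(chroms, function(ch) {
    strand_coverage(genes, ch, nchar(genome[[ch]]))
  })
  names(coverage) <- chroms

  truth_rows <- list()
  call_rows <- list()

  for (iso in seq_len(cfg$n_isolates)) {
    iso_id <- sprintf("iso%02d", iso)
    for (dose in seq_len(cfg$n_doses)) {
      for (class_name in names(cfg$lesion_classes)) {
        cl <- cfg$lesion_classes[[class_name]]
        for (ch in chroms) {
          for (strand in c("+", "-")) {
            for (target in cl$targets) {
              plus_dinuc <- if (strand == "+") target else revcomp(target)
              sites <- site_index[[ch]][[plus_dinuc]]
              if (is.null(sites)) next
              form_p <- if (length(cl$formation) > 1) {
                cl$formation[[target]]
              } else cl$formation
              formed <- sites[stats::runif(length(sites)) < form_p]
              if (!length(formed)) next
              p <- formed
              # role of the lesion-bearing strand at each position
              covp <- coverage[[ch]]$plus[p] | coverage[[ch]]$plus[p + 1L]
              covm <- coverage[[ch]]$minus[p] | coverage[[ch]]$minus[p + 1L]
              role <- ifelse(!covp & !covm, "intergenic",
                      ifelse(covp & covm, "TS",
                      ifelse((strand == "+") == covp, "NTS", "TS")))
              s_surv <- ifelse(role == "TS", cfg$repair$s_TS,
                               cfg$repair$s_NTS)
              survived <- stats::runif(length(p)) < s_surv
              w <- vapply(cl$outcomes, `[[`, 1, "weight")
              oc_idx <- rep(NA_integer_, length(p))
              if (any(survived)) {
                oc_idx[survived] <- sample.int(length(w), sum(survived),
                                               replace = TRUE, prob = w)
              }
              kinds <- vapply(cl$outcomes, function(o) {
                if (o$kind == "single") {
                  paste0("single_", if (o$pos == 1L) "5p" else "3p")
                } else o$kind
              }, "")
              out_kind <- ifelse(is.na(oc_idx), "none", kinds[oc_idx])
              emitted <- !is.na(oc_idx) & out_kind != "none"
              for (j in seq_along(cl$outcomes)) {
                oc <- cl$outcomes[[j]]
                if (oc$kind == "none") next
                sel <- which(!is.na(oc_idx) & oc_idx == j)
                if (!length(sel)) next
                call_rows[[length(call_rows) + 1L]] <-
                  lesion_to_calls(iso_id, ch, p[sel], strand, target, oc)
              }
              truth_rows[[length(truth_rows) + 1L]] <- data.frame(
                isolate = iso_id, dose = dose, lesion_class = class_name,
                chrom = ch, plus_start = p, lesion_strand = strand,
                target_dinuc = target, role = role, survived = survived,
                outcome = out_kind, emitted = emitted,
                stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }

  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(isolate = character(), dose = integer(),
               lesion_class = character(), chrom = character(),
               plus_start = integer(), lesion_strand = character(),
               target_dinuc = character(), role = character(),
               survived = logical(), outcome = character(),
               emitted = logical())
  calls <- if (length(call_rows)) do.call(rbind, call_rows) else new_calls()
  if (nrow(calls)) {
    # heterozygous diploid calls: read support scatters around one half
    calls$support_fraction <- round(stats::rbeta(nrow(calls), 40, 30), 3)
    # independent lesions very occasionally strike one locus twice in one
    # isolate; keep the first call
    dup <- duplicated(calls[, c("sample_id", "chrom", "pos")])
    calls <- calls[!dup, , drop = FALSE]
    calls <- calls[order(calls$sample_id, calls$chrom, calls$pos), ,
                   drop = FALSE]
    rownames(calls) <- NULL
  }
  list(calls = calls, truth = truth)
}

# Translate one surviving lesion's bypass outcome into plus-strand calls.
# The lesion dinucleotide occupies plus positions [p, p+1]; on the minus
# strand its 5' base is at plus position p+1.
lesion_to_calls <- function(iso_id, chrom, p, strand, target, oc) {
  b1 <- substr(target, 1, 1)  # 5' base on the lesion strand
  b2 <- substr(target, 2, 2)
  if (oc$kind == "single") {
    base <- if (oc$pos == 1L) b1 else b2
    to <- oc$map[[base]]
    if (is.null(to)) return(new_calls())
    if (strand == "+") {
      pos <- p + (oc$pos - 1L)
      new_calls(iso_id, chrom, pos, base, to)
    } else {
      pos <- p + (2L - oc$pos)
      new_calls(iso_id, chrom, pos, complement(base), complement(to))
    }
  } else {
    to1 <- oc$map[[b1]]
    to2 <- oc$map[[b2]]
    if (is.null(to1) || is.null(to2)) return(new_calls())
    if (strand == "+") {
      rbind(new_calls(iso_id, chrom, p, b1, to1),
            new_calls(iso_id, chrom, p + 1L, b2, to2))
    } else {
      rbind(new_calls(iso_id, chrom, p, complement(b2), complement(to2)),
            new_calls(iso_id, chrom, p + 1L, complement(b1), complement(to1)))
    }
  }
}

#' Simulate damage-seq reads from the lesion truth table
#'
#' Models the damage-mapping library: lesions of the photoreactivated
#' classes (CPD by default) are removed, and each remaining formed lesion
#' emits one read on the strand opposite the lesion whose 5' terminus sits
#' \code{offset} bases downstream of the lesion dinucleotide, matching the
#' \code{\link{lesion_site}} convention. Optional background reads with
#' uniform positions and strands emulate the untreated control.
#'
#' @param cfg a \code{uv_sim_config}.
#' @param truth truth table from \code{\link{simulate_mutation_tables}}.
#' @param genome genome accepted by \code{\link{as_genome}}.
#' @param read_length read length in bp.
#' @param offset lesion-site offset convention (see
#'   \code{\link{lesion_site}}).
#' @param photolyase_removes lesion classes removed before library
#'   construction.
#' @param n_background number of uniform background reads to add.
#' @return data.frame of reads (BED-style 0-based half-open) with
#'   \code{chrom}, \code{start}, \code{end}, \code{strand}; reads that
#'   would run off the contig are dropped.
#' @export
simulate_uvde_reads <- function(cfg, truth, genome, read_length = 40L,
                                offset = -2L,
                                photolyase_removes = "CPD",
                                n_background = 0L) {
  stopifnot(inherits(cfg, "uv_sim_config"))
  genome <- as_genome(genome)
  set.seed(cfg$seed + 2L)
  keep <- truth[!truth$lesion_class %in% photolyase_removes, , drop = FALSE]
  reads <- NULL
  if (nrow(keep)) {
    p0 <- keep$plus_start - 1L  # 0-based leftmost lesion base
    plus_lesion <- keep$lesion_strand == "+"
    # read on the opposite strand; its 5' terminus is -offset bases
    # downstream of the lesion dinucleotide
    start <- ifelse(plus_lesion,
                    p0 + offset + 2L - read_length,  # minus-strand read [e-L, e)
                    p0 - offset)                     # plus-strand read
    end <- start + read_length
    reads <- data.frame(chrom = keep$chrom, start = as.integer(start),
                        end = as.integer(end),
                        strand = ifelse(plus_lesion, "-", "+"),
                        stringsAsFactors = FALSE)
  }
  if (n_background > 0) {
    lens <- nchar(genome)
    ch <- sample(names(genome), n_background, replace = TRUE,
                 prob = lens / sum(lens))
    start <- vapply(ch, function(c1) {
      sample.int(lens[[c1]] - read_length - 4L, 1L) + 2L
    }, 1L)
    bg <- data.frame(chrom = ch, start = as.integer(start),
                     end = as.integer(start + read_length),
                     strand = sample(c("+", "-"), n_background,
                                     replace = TRUE),
                     stringsAsFactors = FALSE)
    reads <- if (is.null(reads)) bg else rbind(reads, bg)
  }
  if (is.null(reads)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  }
  lens <- nchar(genome)[reads$chrom]
  ok <- reads$start >= 0L & reads$end <= lens
  out <- reads[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Simulate a cancer-sample mutation table
#'
#' Independent Bernoulli draws per sample and mutation, with per-tissue
#' carriage probabilities. The planted odds ratios are recoverable from the
#' configured probabilities.
#'
#' @param n_per_cohort named integer vector of cohort sizes; names are
#'   tissue labels.
#' @param probs matrix of carriage probabilities, rows = mutation ids
#'   (rownames \code{gene:mutation}), columns = tissue labels.
#' @param seed integer seed.
#' @return data.frame with columns \code{sample_id}, \code{tissue},
#'   \code{gene}, \code{mutation}; attribute \code{planted_or} gives the
#'   odds ratio of each mutation for the first tissue against the rest
#'   implied by the probabilities.
#' @export
simulate_cosmic_table <- function(n_per_cohort, probs, seed = 1L) {
  stopifnot(!is.null(names(n_per_cohort)), !is.null(rownames(probs)),
            all(colnames(probs) %in% names(n_per_cohort) |
                  names(n_per_cohort) %in% colnames(probs)))
  set.seed(seed)
  rows <- list()
  all_samples <- list()
  for (tissue in names(n_per_cohort)) {
    n <- n_per_cohort[[tissue]]
    ids <- sprintf("%s_s%05d", tissue, seq_len(n))
    all_samples[[tissue]] <- ids
    for (mut in rownames(probs)) {
      pr <- probs[mut, tissue]
      carriers <- ids[stats::runif(n) < pr]
      if (length(carriers)) {
        parts <- strsplit(mut, ":", fixed = TRUE)[[1]]
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = carriers, tissue = tissue, gene = parts[1],
          mutation = parts[2], stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample_id = character(), tissue = character(),
               gene = character(), mutation = character())
  rownames(out) <- NULL
  focal <- names(n_per_cohort)[1]
  others <- setdiff(colnames(probs), focal)
  odds <- function(p) p / (1 - p)
  p_other <- if (length(others) == 1) probs[, others] else
    rowMeans(probs[, others, drop = FALSE])
  attr(out, "planted_or") <- odds(probs[, focal]) / odds(p_other)
  attr(out, "cohort_sizes") <- n_per_cohort
  out
}

#' Write a mutation table as TSV
#'
#' @param calls mutation call data.frame.
#' @param path output path.
#' @export
write_mutation_tsv <- function(calls, path) {
  out <- calls[, c("sample_id", "chrom", "pos", "ref", "alt",
                   "support_fraction")]
  names(out)[1] <- "sample"
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write a genome as FASTA
#'
#' @param genome named character vector of chromosome sequences.
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(as_genome(genome)),
                              path)
}

#' Write a gene annotation as TSV
#'
#' @param genes gene annotation data.frame.
#' @param path output path.
#' @export
write_gene_tsv <- function(genes, path) {
  out <- genes[, c("gene_id", "chrom", "tss", "tes", "strand", "expression")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
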