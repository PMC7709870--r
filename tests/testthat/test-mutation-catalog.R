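test_that("TSV mutation tables are read with 1-based positions", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tchrom\tpos\tref\talt\tsupport_fraction",
               "iso1\tchrII\t100\tC\tT\t0.52",
               "iso1\tchrII\t200\tG\tA\t0.9"), tmp)
  calls <- read_mutation_table(tmp, "tsv")
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$sample_id[1], "iso1")
  expect_equal(calls$pos[1], 100L)
  expect_equal(calls$ref[1], "C")
  expect_equal(calls$support_fraction[1], 0.52)
})

test_that("empty files, malformed rows, and bad alleles are handled", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), tmp)
  expect_equal(nrow(read_mutation_table(tmp, "tsv")), 0L)

  writeLines(c("iso1\tchrI\t100\tC\tT\t0.5",
               "iso1\tchrI\tnotanumber\tC\tT\t0.5"), tmp)
  expect_error(read_mutation_table(tmp, "tsv"), "line 2")

  writeLines(c("iso1\tchrI\t100\tC\tT\t0.5",
               "iso1\tchrI\t101\tX\tT\t0.5"), tmp)
  expect_warning(calls <- read_mutation_table(tmp, "tsv"), "rejected")
  expect_equal(nrow(calls), 1L)
  expect_equal(attr(calls, "n_rejected"), 1L)
})

test_that("multi-allelic VCF records expand to one call per alt", {
  tmp <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chrI\t500\t.\tC\tT,G\t50\tPASS\t."), tmp)
  calls <- read_mutation_table(tmp, "vcf")
  expect_equal(nrow(calls), 2L)
  expect_equal(calls$pos, c(500L, 500L))
  expect_setequal(calls$alt, c("T", "G"))
})

test_that("support filtering is strictly greater-than", {
  calls <- data.frame(sample_id = "a", chrom = "chrI", pos = 1:3,
                      ref = "C", alt = "T",
                      support_fraction = c(0.44, 0.45, 0.46))
  kept <- filter_support(calls, 0.45)
  expect_equal(kept$support_fraction, 0.46)
  expect_equal(nrow(filter_support(calls, 0)), 3L)

  calls$support_fraction <- NA_real_
  all_kept <- filter_support(calls, 0.45)
  expect_equal(nrow(all_kept), 3L)
  expect_equal(attr(all_kept, "n_missing_support"), 3L)
})

test_that("variants shared between isolates are removed from all samples", {
  shared <- data.frame(sample_id = c("iso1", "iso2"), chrom = "chrI",
                       pos = 500L, ref = "C", alt = "T",
                       support_fraction = NA_real_)
  out <- filter_sample_unique(shared)
  expect_equal(nrow(out), 0L)

  single <- data.frame(sample_id = "iso1", chrom = "chrI", pos = 1:4,
                       ref = "C", alt = "T", support_fraction = NA_real_)
  expect_equal(nrow(filter_sample_unique(single)), 4L)

  # 3 samples share one site, plus 5 private sites each
  set.seed(1)
  private <- do.call(rbind, lapply(1:3, function(i) {
    data.frame(sample_id = paste0("iso", i), chrom = "chrI",
               pos = 100L * i + 1:5, ref = "C", alt = "T",
               support_fraction = NA_real_)
  }))
  both <- rbind(private,
                data.frame(sample_id = paste0("iso", 1:3), chrom = "chrI",
                           pos = 9999L, ref = "T", alt = "A",
                           support_fraction = NA_real_))
  out <- filter_sample_unique(both)
  expect_equal(nrow(out), 15L)
  # oracle: no (chrom,pos,ref,alt) key left in more than one sample
  key <- paste(out$chrom, out$pos, out$ref, out$alt)
  expect_true(all(tapply(out$sample_id, key,
                         function(s) length(unique(s))) == 1L))
})

test_that("adjacent substitutions merge into tandem and triple events", {
  mk <- function(pos, ref = "C", alt = "T", sample = "iso1") {
    data.frame(sample_id = sample, chrom = "chrI", pos = pos, ref = ref,
               alt = alt, support_fraction = NA_real_)
  }
  part <- partition_events(rbind(mk(100L), mk(101L)))
  expect_equal(nrow(part$tandems), 1L)
  expect_equal(part$tandems$ref_dinuc, "CC")
  expect_equal(part$tandems$alt_dinuc, "TT")
  expect_equal(part$tandems$start_pos, 100L)

  part <- partition_events(rbind(mk(100L), mk(102L)))
  expect_equal(nrow(part$singles), 2L)
  expect_equal(nrow(part$tandems), 0L)

  part <- partition_events(rbind(mk(100L), mk(101L), mk(102L)))
  expect_equal(nrow(part$triples), 1L)
  expect_equal(nrow(part$tandems), 0L)

  # adjacency does not cross samples
  part <- partition_events(rbind(mk(100L), mk(101L, sample = "iso2")))
  expect_equal(nrow(part$singles), 2L)

  # pre-merged double rows route directly to tandems; indels never merge
  pre <- data.frame(sample_id = "iso1", chrom = "chrI", pos = c(10L, 11L),
                    ref = c("AC", "A"), alt = c("TT", "AG"),
                    support_fraction = NA_real_)
  part <- partition_events(pre)
  expect_equal(nrow(part$tandems), 1L)
  expect_equal(nrow(part$indels), 1L)

  expect_error(partition_events(rbind(mk(100L), mk(100L, alt = "G"))),
               "conflicting duplicate")
})

test_that("event partitioning conserves record counts on random inputs", {
  set.seed(42)
  for (rep in 1:5) {
    pos <- sort(sample(1:300, 60))
    calls <- data.frame(sample_id = sample(c("a", "b"), 60, TRUE),
                        chrom = sample(c("chrI", "chrII"), 60, TRUE),
                        pos = pos, ref = "C", alt = "T",
                        support_fraction = NA_real_)
    calls <- calls[!duplicated(calls[, c("sample_id", "chrom", "pos")]), ]
    part <- partition_events(calls)
    expect_equal(nrow(part$singles) + 2L * nrow(part$tandems) +
                   3L * nrow(part$triples) + nrow(part$indels) +
                   nrow(part$complex),
                 nrow(calls))
    # oracle: maximal-run merging over enumerated position sets
    runs <- unlist(lapply(split(calls$pos, paste(calls$sample_id, calls$chrom)),
                          function(p) {
                            p <- sort(p)
                            rle(cumsum(c(1L, diff(p) != 1L)))$lengths
                          }))
    expect_equal(nrow(part$singles), sum(runs == 1L))
    expect_equal(nrow(part$tandems), sum(runs == 2L))
    expect_equal(nrow(part$triples), sum(runs == 3L))
  }
})

test_that("purine-reference calls are normalized to the pyrimidine strand", {
  g <- c(chrI = "AATGACC")  # plus-strand context around pos 3 is "ATG"
  call <- data.frame(sample_id = "s", chrom = "chrI", pos = 3L, ref = "T",
                     alt = "A", support_fraction = NA_real_)
  out <- classify_snv(call, g)
  expect_equal(out$pyr_class, "T>A")
  expect_false(out$flipped)

  # G>A on the plus strand with context TGA reads C>T at TCA on the minus
  g2 <- c(chrI = "ATGAC")
  call2 <- data.frame(sample_id = "s", chrom = "chrI", pos = 3L, ref = "G",
                      alt = "A", support_fraction = NA_real_)
  out2 <- classify_snv(call2, g2)
  expect_true(out2$flipped)
  expect_equal(out2$pyr_class, "C>T")
  expect_equal(out2$context, "TCA")
  expect_equal(out2$dipyr, "THREE_PRIME")

  expect_error(classify_snv(
    data.frame(sample_id = "s", chrom = "chrI", pos = 3L, ref = "C",
               alt = "T", support_fraction = NA_real_), g2),
    "mismatch.*chrI:3")
})

test_that("dipyrimidine categories follow the stated precedence rule", {
  # enumerate all 16 neighbor pairs around a mutated C
  grid <- expand.grid(n5 = c("A", "C", "G", "T"), n3 = c("A", "C", "G", "T"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    ctx <- paste0(grid$n5[i], "C", grid$n3[i])
    g <- setNames(paste0("A", ctx, "A"), "chrI")
    call <- data.frame(sample_id = "s", chrom = "chrI", pos = 3L, ref = "C",
                       alt = "T", support_fraction = NA_real_)
    out3 <- classify_snv(call, g, dipyr_tie = "three_prime")
    out5 <- classify_snv(call, g, dipyr_tie = "five_prime")
    p5 <- grid$n5[i] %in% c("C", "T")
    p3 <- grid$n3[i] %in% c("C", "T")
    exp3 <- if (p5) "THREE_PRIME" else if (p3) "FIVE_PRIME" else "NONE"
    exp5 <- if (p3) "FIVE_PRIME" else if (p5) "THREE_PRIME" else "NONE"
    expect_equal(out3$dipyr, exp3, info = ctx)
    expect_equal(out5$dipyr, exp5, info = ctx)
  }
  # the flagship tie case
  g <- c(chrI = "ATCTA")
  call <- data.frame(sample_id = "s", chrom = "chrI", pos = 3L, ref = "C",
                     alt = "T", support_fraction = NA_real_)
  expect_equal(classify_snv(call, g)$dipyr, "THREE_PRIME")
})

test_that("classification is invariant under strand of reporting", {
  set.seed(7)
  n <- 50L
  g <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  genome_fwd <- c(chrI = g)
  genome_rev <- c(chrI = revcomp(g))
  pos <- sample(5:395, n)
  ref <- substring(g, pos, pos)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
  fwd <- classify_snv(data.frame(sample_id = "s", chrom = "chrI", pos = pos,
                                 ref = ref, alt = alt,
                                 support_fraction = NA_real_), genome_fwd)
  rev <- classify_snv(data.frame(sample_id = "s", chrom = "chrI",
                                 pos = 400L - pos + 1L,
                                 ref = complement(ref), alt = complement(alt),
                                 support_fraction = NA_real_), genome_rev)
  expect_equal(fwd$pyr_class, rev$pyr_class)
  expect_equal(fwd$context, rev$context)
  expect_equal(fwd$dipyr, rev$dipyr)
})

test_that("contig edges pad context with N", {
  g <- c(chrI = "CATG")
  call <- data.frame(sample_id = "s", chrom = "chrI", pos = 1L, ref = "C",
                     alt = "A", support_fraction = NA_real_)
  out <- classify_snv(call, g)
  expect_equal(out$context, "NCA")
  expect_equal(out$dipyr, "NONE")
})

test_that("tandem canonicalization pools reverse-complement orientations", {
  ev <- data.frame(sample_id = "s", chrom = "chrI", start_pos = 1L,
                   ref_dinuc = c("GT", "AC", "CC", "GG"),
                   alt_dinuc = c("AA", "TT", "TT", "AA"))
  out <- canonicalize_tandem(ev)
  expect_equal(out$canonical_label,
               c("AC>TT", "AC>TT", "CC>TT", "CC>TT"))
  expect_equal(out$canonical_strand, c("minus", "plus", "plus", "minus"))
  # idempotent
  expect_equal(canonicalize_tandem(out)$canonical_label, out$canonical_label)
})

test_that("canonicalization maps each orientation pair to one label", {
  dinucs <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0))
  pairs <- expand.grid(ref = dinucs, alt = dinucs, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  ev <- data.frame(sample_id = "s", chrom = "chrI",
                   start_pos = seq_len(nrow(pairs)),
                   ref_dinuc = pairs$ref, alt_dinuc = pairs$alt)
  fwd <- canonicalize_tandem(ev)
  rc <- ev
  rc$ref_dinuc <- revcomp(ev$ref_dinuc)
  rc$alt_dinuc <- revcomp(ev$alt_dinuc)
  bwd <- canonicalize_tandem(rc)
  expect_equal(fwd$canonical_label, bwd$canonical_label)
  # non-palindromic-pair classes collapse exactly two orientations to one
  n_pal <- sum(pairs$ref == revcomp(pairs$ref) &
                 pairs$alt == revcomp(pairs$alt))
  expect_equal(length(unique(fwd$canonical_label)),
               (nrow(pairs) - n_pal) / 2 + n_pal)
})

test_that("mitochondrial records are excluded by the chromosome deny-list", {
  calls <- data.frame(sample_id = "s", chrom = c("chrI", "chrM", "MT"),
                      pos = 1:3, ref = "C", alt = "T",
                      support_fraction = NA_real_)
  expect_equal(filter_chroms(calls)$chrom, "chrI")
})
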