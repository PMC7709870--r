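toy_genes <- function(...) {
  validate <- function(df) df
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(gene_id = r[[1]], chrom = r[[2]], tss = as.integer(r[[3]]),
               tes = as.integer(r[[4]]), strand = r[[5]],
               expression = if (length(r) > 5) as.numeric(r[[6]]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
}

test_that("mutations are assigned to the strand role of their pyrimidine", {
  genes <- toy_genes(list("gp", "chrI", 10, 30, "+"),
                     list("gm", "chrI", 50, 70, "-"))
  mk <- function(pos, flipped) {
    data.frame(chrom = "chrI", pos = pos, flipped = flipped,
               pyr_class = "C>T", context = "TCA")
  }
  # pyrimidine on plus strand inside a plus-strand gene: NTS
  expect_equal(assign_gene_strand(mk(20L, FALSE), genes)$strand_class, "NTS")
  # same site with the pyrimidine on the minus strand: TS
  expect_equal(assign_gene_strand(mk(20L, TRUE), genes)$strand_class, "TS")
  # minus-strand gene flips the roles
  expect_equal(assign_gene_strand(mk(60L, FALSE), genes)$strand_class, "TS")
  # outside all genes
  expect_equal(assign_gene_strand(mk(40L, FALSE), genes)$strand_class,
               "intergenic")
  # overlapping genes on opposite strands exclude the site
  over <- rbind(genes, toy_genes(list("go", "chrI", 25, 35, "-")))
  expect_equal(assign_gene_strand(mk(28L, FALSE), over)$strand_class,
               "excluded")
})

test_that("strand trinucleotide frequencies match a sliding-window tally", {
  set.seed(9)
  g <- setNames(paste(sample(c("A", "C", "G", "T"), 500, TRUE),
                      collapse = ""), "chrI")
  genes <- toy_genes(list("g1", "chrI", 20, 120, "+"),
                     list("g2", "chrI", 200, 320, "-"),
                     list("g3", "chrI", 300, 400, "+"))
  got <- build_strand_freqs(g, genes, k = 3L)
  want <- strand_freq_oracle(g, genes, k = 3L)
  expect_equal(got, want)

  # swapping every gene strand swaps the NTS and TS columns
  flipped <- genes
  flipped$strand <- ifelse(genes$strand == "+", "-", "+")
  got_f <- build_strand_freqs(g, flipped, k = 3L)
  expect_equal(got_f$f_NTS, got$f_TS)
  expect_equal(got_f$f_TS, got$f_NTS)

  # fully overlapping opposite-strand genes exclude everything
  both <- toy_genes(list("a", "chrI", 50, 100, "+"),
                    list("b", "chrI", 50, 100, "-"))
  expect_equal(nrow(build_strand_freqs(g, both, k = 3L)), 0L)

  expect_error(build_strand_freqs(g, toy_genes(list("x", "chrI", 400, 600, "+"))),
               "contig")
})

test_that("asymmetry ratio is the frequency-normalized NTS/TS quotient", {
  expect_equal(asymmetry_ratio(50, 50, 1000, 1000), 1.0)
  expect_equal(asymmetry_ratio(60, 20, 1000, 1000), 3.0)
  expect_equal(asymmetry_ratio(30, 20, 1500, 500), 0.5)
  expect_equal(asymmetry_ratio(10, 0, 100, 100), Inf)
  expect_error(asymmetry_ratio(10, 10, 0, 100), "positive")
})

test_that("chi-square asymmetry test matches its closed form and oracle", {
  res <- asymmetry_test(75, 25, 1000, 1000)
  expect_equal(res$chi2, 25)
  expect_equal(res$p, 5.733031e-07, tolerance = 1e-4)

  expect_equal(asymmetry_test(50, 50, 1, 1)$chi2, 0)
  expect_equal(asymmetry_test(50, 50, 1, 1)$p, 1)

  res <- asymmetry_test(30, 30, 2000, 1000)
  expect_equal(res$chi2, 7.5)

  expect_true(is.na(asymmetry_test(0, 0, 1, 1)$chi2))

  # oracle equivalence on a grid of counts against stats::chisq.test
  grid <- expand.grid(n1 = c(0, 1, 5, 30, 75, 200),
                      n2 = c(1, 4, 25, 60, 200),
                      f1 = c(500, 2000), f2 = c(1000, 3000))
  for (i in seq_len(nrow(grid))) {
    gr <- grid[i, ]
    mine <- asymmetry_test(gr$n1, gr$n2, gr$f1, gr$f2)
    ref <- suppressWarnings(stats::chisq.test(
      c(gr$n1, gr$n2), p = c(gr$f1, gr$f2) / (gr$f1 + gr$f2)))
    expect_equal(mine$chi2, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value)
  }

  # even-split null option
  expect_equal(asymmetry_test(75, 25, 2000, 1000, null = "even")$chi2, 25)
})

test_that("class thresholds and Bonferroni correction are applied per run", {
  sim <- asym_sim(3)
  res <- run_asymmetry(sim$classified, sim$genome, sim$genes,
                       mode = "single", organism = "yeast")
  # untested classes have fewer events than the threshold and no p
  under <- res$records[!res$records$tested, ]
  if (nrow(under)) {
    expect_true(all(under$n_NTS + under$n_TS < 30 |
                      under$f_NTS == 0 | under$f_TS == 0))
    expect_true(all(is.na(under$p_bonferroni)))
  }
  tested <- res$records[res$records$tested, ]
  expect_true(all(tested$n_NTS + tested$n_TS >= 30))
  expect_equal(res$m_tested, nrow(tested))
  expect_equal(tested$p_bonferroni, pmin(1, res$m_tested * tested$p))
})

test_that("planted strand survival ratios are recovered from the catalog", {
  sim <- asym_sim(3)
  res <- run_asymmetry(sim$classified, sim$genome, sim$genes,
                       mode = "single", organism = "yeast")
  n_genic <- res$pooled$n_NTS + res$pooled$n_TS
  expect_gte(n_genic, 2000)
  expect_true(res$pooled$ratio > 2.6 && res$pooled$ratio < 3.5)
  # the planted value lies inside the ratio-scale binomial 95% interval
  ci <- stats::binom.test(res$pooled$n_NTS, n_genic)$conf.int
  f_odds <- res$pooled$f_NTS / res$pooled$f_TS
  ratio_ci <- (ci / (1 - ci)) / f_odds
  expect_true(ratio_ci[1] <= 3 && 3 <= ratio_ci[2])
})

test_that("a symmetric simulation is calibrated", {
  sim <- asym_sim(1)
  res <- run_asymmetry(sim$classified, sim$genome, sim$genes,
                       mode = "single", organism = "yeast")
  expect_true(abs(res$pooled$ratio - 1) < 0.15)
  tested <- res$records[res$records$tested, ]
  expect_lte(mean(tested$p_bonferroni < 0.05), 0.05 + 1e-9)
})

test_that("reversing every gene strand inverts the ratios", {
  sim <- asym_sim(3)
  res <- run_asymmetry(sim$classified, sim$genome, sim$genes,
                       mode = "single", organism = "yeast")
  flipped <- sim$genes
  flipped$strand <- ifelse(flipped$strand == "+", "-", "+")
  tmp <- flipped$tss
  flipped$tss <- flipped$tes
  flipped$tes <- tmp
  res_f <- run_asymmetry(sim$classified, sim$genome, flipped,
                         mode = "single", organism = "yeast")
  common <- intersect(res$records$class[res$records$tested],
                      res_f$records$class[res_f$records$tested])
  r1 <- res$records$ratio[match(common, res$records$class)]
  r2 <- res_f$records$ratio[match(common, res_f$records$class)]
  expect_equal(r1, 1 / r2, tolerance = 1e-9)
  expect_equal(res$pooled$ratio, 1 / res_f$pooled$ratio, tolerance = 1e-9)
})

test_that("tandem asymmetry attributes events by canonical orientation", {
  # one plus-strand gene; AC on the plus strand is on its NTS
  set.seed(31)
  g <- setNames(paste(sample(c("A", "C", "G", "T"), 2000, TRUE),
                      collapse = ""), "chrI")
  genes <- toy_genes(list("g1", "chrI", 1, 2000, "+"))
  v <- strsplit(g[[1]], "")[[1]]
  di <- paste0(v[-length(v)], v[-1])
  ac_sites <- which(di == "AC")
  gt_sites <- which(di == "GT")
  ev <- canonicalize_tandem(data.frame(
    sample_id = "s", chrom = "chrI",
    start_pos = c(rep(ac_sites, 3), gt_sites),
    ref_dinuc = c(rep("AC", 3 * length(ac_sites)),
                  rep("GT", length(gt_sites))),
    alt_dinuc = c(rep("TT", 3 * length(ac_sites)),
                  rep("AA", length(gt_sites)))))
  res <- run_asymmetry(ev, g, genes, mode = "tandem", organism = "yeast",
                       exclude_ids = character())
  rec <- res$records[res$records$class == "AC>TT", ]
  # plus-orientation (AC) events land on the NTS, GT-orientation on the TS
  expect_equal(rec$n_NTS, 3L * length(ac_sites))
  expect_equal(rec$n_TS, length(gt_sites))
  expect_true(rec$tested)
  expect_gt(rec$ratio, 2)
})

test_that("expression stratification runs on top and bottom quartiles", {
  sim <- asym_sim(3)
  res <- run_asymmetry(sim$classified, sim$genome, sim$genes,
                       mode = "single", organism = "yeast", stratify = TRUE)
  expect_named(res, c("top", "bottom"))
  expect_s3_class(res$top, "uv_asymmetry")
  # disjoint gene sets imply disjoint genic event assignments
  tot <- res$top$pooled$n_NTS + res$top$pooled$n_TS +
    res$bottom$pooled$n_NTS + res$bottom$pooled$n_TS
  full <- run_asymmetry(sim$classified, sim$genome, sim$genes,
                        mode = "single", organism = "yeast")
  expect_lte(tot, full$pooled$n_NTS + full$pooled$n_TS)

  no_expr <- sim$genes
  no_expr$expression <- NA_real_
  expect_error(run_asymmetry(sim$classified, sim$genome, no_expr,
                             mode = "single", stratify = TRUE), "expression")
})
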