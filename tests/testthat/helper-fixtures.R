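# Shared fixtures, built in code. Expensive simulations are computed once
# per test run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# a tiny genome with known sequence for hand-checkable examples
toy_genome <- function() {
  c(chrI = "ATGACCTGACTTAGGCTACATTTACGATCGT",
    chrII = "CCCCTTTTAAAAGGGG")
}

# wild-type-like simulation shared by spectrum/tandem/acceptance tests
wt_sim <- function() {
  fixture("wt_sim", function() {
    cfg <- sim_config(seed = 101, genome_length = 150000L, n_genes = 80L,
                      n_isolates = 8L, n_doses = 15L, genotype = "WT")
    gg <- generate_genome(cfg)
    sim <- simulate_mutation_tables(cfg, gg$genome, gg$genes)
    calls <- filter_chroms(filter_sample_unique(filter_support(sim$calls)))
    part <- partition_events(calls)
    classified <- classify_snv(part$singles, gg$genome)
    list(cfg = cfg, genome = gg$genome, genes = gg$genes, sim = sim,
         calls = calls, part = part, classified = classified)
  })
}

# CPD-only simulation with a known strand survival ratio, for asymmetry
# parameter recovery (>= 2000 genic single events)
asym_sim <- function(s_ratio) {
  fixture(paste0("asym_sim_", s_ratio), function() {
    classes <- list(CPD = list(
      targets = c("TT", "TC", "CT", "CC"), formation = 1.2e-3,
      outcomes = list(list(kind = "single", weight = 0.8, pos = 2L,
                           map = c(C = "T", T = "C")),
                      list(kind = "none", weight = 0.2, pos = NA, map = NULL))))
    cfg <- sim_config(seed = 211, genome_length = 150000L, n_genes = 85L,
                      gene_length_mean = 1500, n_isolates = 6L, n_doses = 10L,
                      repair = list(s_NTS = 0.9, s_TS = 0.9 / s_ratio),
                      lesion_classes = classes)
    gg <- generate_genome(cfg)
    sim <- simulate_mutation_tables(cfg, gg$genome, gg$genes)
    part <- partition_events(sim$calls)
    classified <- classify_snv(part$singles, gg$genome)
    list(cfg = cfg, genome = gg$genome, genes = gg$genes,
         truth = sim$truth, classified = classified)
  })
}

# brute-force Holm-Sidak step-down, kept independent of the implementation
holm_sidak_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    val <- 1 - (1 - p[ord[i]])^(m - i + 1)
    running <- max(running, val)
    adj[ord[i]] <- min(1, running)
  }
  adj
}

# exact two-sided Mann-Whitney by full enumeration of rank splits
mann_whitney_enum <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  splits <- utils::combn(n + m, n)
  us <- apply(splits, 2, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# sliding-window strand trinucleotide tally, independent of the package
strand_freq_oracle <- function(genome, genes, k = 3L) {
  rc <- function(s) uvspectra::revcomp(s)
  acc <- list()
  add <- function(key, col) {
    if (is.null(acc[[key]])) acc[[key]] <<- c(f_NTS = 0L, f_TS = 0L)
    acc[[key]][col] <<- acc[[key]][col] + 1L
  }
  for (i in seq_len(nrow(genes))) {
    s <- min(genes$tss[i], genes$tes[i])
    e <- max(genes$tss[i], genes$tes[i])
    seqstr <- genome[[genes$chrom[i]]]
    opp <- genes[genes$strand != genes$strand[i] &
                   genes$chrom == genes$chrom[i], , drop = FALSE]
    opp_pos <- unlist(lapply(seq_len(nrow(opp)), function(j) {
      seq(min(opp$tss[j], opp$tes[j]), max(opp$tss[j], opp$tes[j]))
    }))
    if (k == 3L) {
      for (p in seq(max(s, 2L), min(e, nchar(seqstr) - 1L))) {
        if (p %in% opp_pos) next
        mer <- substr(seqstr, p - 1L, p + 1L)
        if (grepl("N", mer)) next
        central <- substr(mer, 2, 2)
        pyr_on_plus <- central %in% c("C", "T")
        key <- if (pyr_on_plus) mer else rc(mer)
        on_nts <- pyr_on_plus == (genes$strand[i] == "+")
        add(key, if (on_nts) "f_NTS" else "f_TS")
      }
    }
  }
  keys <- sort(names(acc))
  data.frame(kmer = keys,
             f_NTS = vapply(keys, function(kk) acc[[kk]][["f_NTS"]], 1L),
             f_TS = vapply(keys, function(kk) acc[[kk]][["f_TS"]], 1L),
             row.names = NULL, stringsAsFactors = FALSE)
}
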