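test_that("panel dimensions and subpopulation split follow the configuration", {
  cfg <- sim_config(n_accessions = 174, subpop_proportions = c(109, 65) / 174,
                    n_markers = 50, seed = 1)
  sim <- simulate_genotypes(cfg)
  expect_equal(dim(sim$panel), c(174, 51))  # accession column + 50 markers
  expect_equal(unname(table(sim$truth$subpops$subpop)[c("indica", "japonica")]),
               c(109L, 65L), ignore_attr = TRUE)
  expect_equal(nrow(sim$map), 50)
  expect_true(all(sim$map$pos_bp >= 1))
  # positions sorted within chromosome
  expect_true(all(unlist(tapply(sim$map$pos_bp, sim$map$chrom,
                                function(p) diff(p) >= 0))))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(alleles_per_marker = 1, seed = 1), "at least 2")
  expect_error(sim_config(seed = NULL), "seed")
  expect_error(sim_config(subpop_proportions = c(0.6, 0.5), seed = 1), "sum to 1")
  expect_error(sim_config(missing_rate = 1, seed = 1), "missing_rate")
  expect_error(sim_config(qtl_spec = data.frame(marker = 1, allele = 1,
                                                measure = "SSvR", effect = Inf,
                                                scope = "both"), seed = 1),
               "finite")
})

test_that("the same seed gives bit-identical output", {
  cfg <- sim_config(n_accessions = 40, n_markers = 15, seed = 99)
  a <- simulate_cold_panel(cfg)
  b <- simulate_cold_panel(cfg)
  expect_identical(a, b)
})

test_that("missing cells appear at the configured rate", {
  cfg <- sim_config(n_accessions = 200, n_markers = 50, missing_rate = 0.1,
                    seed = 3)
  sim <- simulate_genotypes(cfg)
  frac <- mean(is.na(as.matrix(sim$panel[, -1])))
  expect_lt(abs(frac - 0.1), 0.01)
})

test_that("near-zero divergence yields near-fixed subpopulations and large frequency contrasts", {
  freq_stats <- function(divergence, seed) {
    cfg <- sim_config(n_accessions = 300, subpop_proportions = c(0.5, 0.5),
                      n_markers = 30, alleles_per_marker = 3,
                      divergence = divergence, ld_block_span = 0,
                      missing_rate = 0, seed = seed)
    sim <- simulate_genotypes(cfg)
    sp <- sim$truth$subpops$subpop
    res <- vapply(names(sim$panel)[-1], function(mk) {
      g <- sim$panel[[mk]]
      lv <- unique(g)
      f1 <- vapply(lv, function(a) mean(g[sp == "indica"] == a), numeric(1))
      f2 <- vapply(lv, function(a) mean(g[sp == "japonica"] == a), numeric(1))
      c(diff = max(abs(f1 - f2)), fix = mean(c(max(f1), max(f2))))
    }, numeric(2))
    rowMeans(res)
  }
  low <- freq_stats(0.01, seed = 5)
  # each subpopulation is near-fixed for a single allele ...
  expect_gt(low[["fix"]], 0.95)
  # ... and when different alleles fix, they are private: the mean frequency
  # contrast is far above the well-mixed case
  high <- freq_stats(100, seed = 5)
  expect_gt(low[["diff"]], 0.4)
  expect_gt(low[["diff"]], 3 * high[["diff"]])
})

test_that("subpopulation genotype frequencies match the drawn Dirichlet frequencies", {
  cfg <- sim_config(n_accessions = 5000, subpop_proportions = c(0.5, 0.5),
                    n_markers = 8, alleles_per_marker = 4, ld_block_span = 0,
                    missing_rate = 0, seed = 11)
  sim <- simulate_genotypes(cfg)
  sp <- sim$truth$subpops$subpop
  pvals <- vapply(seq_len(8), function(j) {
    mk <- names(sim$panel)[j + 1]
    g <- sim$panel[[mk]][sp == "indica"]
    expected <- sim$truth$allele_freqs[[mk]][1, ]
    labels <- sim$truth$allele_labels[[mk]]
    obs <- vapply(labels, function(a) sum(g == a), numeric(1))
    suppressWarnings(stats::chisq.test(obs, p = expected)$p.value)
  }, numeric(1))
  # goodness-of-fit non-rejection at alpha = 0.01 (joint check across markers)
  expect_gt(min(pvals), 0.01 / 8)
  expect_gt(mean(pvals > 0.01), 0.7)
})

test_that("zero effects and zero noise reproduce the subpopulation baselines", {
  base <- rbind(c(23.39, 18.88, 14.71, 85), c(79.11, 29.89, 16.87, 85))
  colnames(base) <- c("SSvR", "SStR_NL", "SStR_CW", "SStR_N")
  cfg <- sim_config(n_accessions = 20, n_markers = 5, baseline_means = base,
                    noise_sd = base * 0, missing_rate = 0, seed = 2)
  sim <- simulate_cold_panel(cfg)
  sp <- sim$pheno$subspecies
  for (s in 1:2) {
    rows <- sp == c("indica", "japonica")[s]
    expect_equal(unique(sim$pheno$SSvR[rows]), unname(base[s, "SSvR"]))
    expect_equal(unique(sim$pheno$SStR_CW[rows]), unname(base[s, "SStR_CW"]))
    expect_equal(unique(sim$pheno$RSStR_CW[rows]),
                 unname(100 * base[s, "SStR_CW"] / base[s, "SStR_N"]))
  }
})

test_that("simulated subgroup means land within 2 SE of the configured baselines", {
  cfg <- sim_config(n_accessions = 174, subpop_proportions = c(109, 65) / 174,
                    n_markers = 5, missing_rate = 0, seed = 8)
  sim <- simulate_cold_panel(cfg)
  summ <- pheno_summary(sim$pheno)
  row <- summ[summ$measure == "SSvR" & summ$subspecies == "indica", ]
  # clamping to [0, 100] shifts the mean slightly upward for a baseline of 23
  expect_lt(abs(row$mean - 23.39), 2 * 18.03 / sqrt(109) + 2)
  row <- summ[summ$measure == "SSvR" & summ$subspecies == "japonica", ]
  expect_lt(abs(row$mean - 79.11), 2 * 28.67 / sqrt(65) + 2)
})

test_that("a planted allele effect shifts carriers by the configured amount", {
  diffs <- vapply(1:30, function(r) {
    cfg <- sim_config(n_accessions = 100, subpop_proportions = c(0.5, 0.5),
                      n_markers = 4, alleles_per_marker = 2,
                      ld_block_span = 0, missing_rate = 0, seed = 1000 + r,
                      baseline_means = matrix(50, 2, 4, dimnames = list(
                        NULL, c("SSvR", "SStR_NL", "SStR_CW", "SStR_N"))),
                      noise_sd = matrix(5, 2, 4, dimnames = list(
                        NULL, c("SSvR", "SStR_NL", "SStR_CW", "SStR_N"))),
                      qtl_spec = data.frame(marker = 1, allele = 1,
                                            measure = "SSvR", effect = 15,
                                            scope = "both"))
    sim <- simulate_cold_panel(cfg)
    lab <- sim$truth$qtl_spec$allele_label
    carrier <- sim$panel[[2]] == lab
    if (sum(carrier) < 5 || sum(!carrier) < 5) return(NA_real_)
    mean(sim$pheno$SSvR[carrier]) - mean(sim$pheno$SSvR[!carrier])
  }, numeric(1))
  expect_gt(sum(!is.na(diffs)), 15)
  expect_lt(abs(mean(diffs, na.rm = TRUE) - 15), 1)
})

test_that("cold-water and relative seed set are strongly correlated, as in real screens", {
  cfg <- sim_config(n_accessions = 174, n_markers = 5, seed = 12)
  sim <- simulate_cold_panel(cfg)
  r <- pheno_correlation(sim$pheno, "indica")$r["SStR_CW", "RSStR_CW"]
  expect_gt(r, 0.85)
})

test_that("phenotypes require a subpopulation assignment for every accession", {
  cfg <- sim_config(n_accessions = 20, n_markers = 3, seed = 4)
  sim <- simulate_genotypes(cfg)
  truth <- sim$truth
  truth$subpops <- truth$subpops[-1, ]
  expect_error(simulate_phenotypes(sim$panel, truth, cfg),
               "absent from subpopulation")
})
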