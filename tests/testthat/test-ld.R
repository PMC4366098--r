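test_that("perfect association gives r2 = 1 and hand haplotype algebra is reproduced", {
  # RM1 and RM2 co-occur exactly in the tiny panel
  ld <- ld_pairwise(tiny_panel(), tiny_map())
  expect_equal(ld$r2[ld$marker1 == "RM1" & ld$marker2 == "RM2"], 1)

  # haplotype counts AB=40, Ab=10, aB=10, ab=40 -> D = 0.15, r2 = 0.36
  panel <- tibble::tibble(
    accession = sprintf("H%03d", 1:100),
    L1 = rep(c("L1_A", "L1_A", "L1_a", "L1_a"), c(40, 10, 10, 40)),
    L2 = rep(c("L2_B", "L2_b", "L2_B", "L2_b"), c(40, 10, 10, 40)))
  ld <- ld_pairwise(panel)
  expect_equal(ld$r2, 0.36)
  expect_equal(ld$n, 100L)
})

test_that("multi-allelic r2 reduces exactly to classical biallelic r2", {
  set.seed(31)
  for (i in 1:20) {
    a <- paste0("M1_", sample(c(100, 102), 40, replace = TRUE))
    b <- paste0("M2_", sample(c(150, 152), 40, replace = TRUE,
                              prob = c(0.3, 0.7)))
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    panel <- tibble::tibble(accession = sprintf("X%02d", 1:40), M1 = a, M2 = b)
    expect_equal(ld_pairwise(panel)$r2, biallelic_r2_oracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("r2 is invariant to allele label permutation", {
  set.seed(32)
  a <- paste0("M1_", sample(c(100, 102, 104), 60, replace = TRUE))
  b <- paste0("M2_", sample(c(150, 152, 154, 156), 60, replace = TRUE))
  panel <- tibble::tibble(accession = sprintf("X%02d", 1:60), M1 = a, M2 = b)
  r2 <- ld_pairwise(panel)$r2
  # permute labels at both markers
  relab <- c(M1_100 = "M1_900", M1_102 = "M1_100", M1_104 = "M1_102")
  panel2 <- dplyr::mutate(panel, M1 = unname(relab[M1]),
                          M2 = sub("M2_150", "M2_999", M2))
  expect_equal(ld_pairwise(panel2)$r2, r2, tolerance = 1e-12)
})

test_that("missing cells are deleted pairwise and monomorphic pairs are skipped", {
  panel <- tiny_panel()
  panel$RM1[1:2] <- NA
  ld <- ld_pairwise(panel, tiny_map())
  expect_equal(ld$n[ld$marker1 == "RM1" & ld$marker2 == "RM2"], 6L)
  # monomorphic marker after subsetting
  panel$RM3 <- "RM3_200"
  ld <- ld_pairwise(panel, tiny_map())
  expect_false(any(ld$marker2 == "RM3" | ld$marker1 == "RM3"))
  expect_equal(attr(ld, "n_skipped"), 2L)
})

test_that("distance bins are half-open with boundaries at 50/150/500/1000 kb", {
  rec <- tibble::tibble(marker1 = "a", marker2 = "b", same_chrom = TRUE,
                        dist_bp = c(49999, 50000, 149999, 150000,
                                    999999, 1e6, 10, 20),
                        r2 = c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.5, 0.5), n = 100L)
  b <- ld_bin(rec)
  expect_equal(b$n[b$bin == "[0,50)"], 3L)       # 49999, 10, 20
  expect_equal(b$n[b$bin == "[50,150)"], 2L)     # 50000, 149999
  expect_equal(b$n[b$bin == "[150,500)"], 1L)
  expect_equal(b$n[b$bin == "[500,1000)"], 1L)
  expect_equal(b$n[b$bin == "[1000,Inf)"], 1L)
  expect_equal(b$mean_r2[b$bin == "[0,50)"], mean(c(0.1, 0.5, 0.5)))
})

test_that("constant-r2 pairs give the exact bin mean with zero SD, empty bins report n = 0", {
  rec <- tibble::tibble(marker1 = "a", marker2 = "b", same_chrom = TRUE,
                        dist_bp = rep(10000, 5), r2 = rep(0.5, 5), n = 50L)
  b <- ld_bin(rec)
  expect_equal(b$mean_r2[b$bin == "[0,50)"], 0.5)
  expect_equal(b$sd_r2[b$bin == "[0,50)"], 0)
  expect_equal(b$n[b$bin == "[500,1000)"], 0L)
  expect_true(is.na(b$mean_r2[b$bin == "[500,1000)"]))
})

test_that("inter-chromosomal pairs enter the genome-wide summary but no distance bin", {
  ld <- ld_pairwise(tiny_panel(), tiny_map())
  b <- ld_bin(ld)
  inter <- sum(!ld$same_chrom)
  expect_gt(inter, 0)
  expect_equal(b$n[b$bin == "genome-wide"], nrow(ld))
  expect_equal(sum(b$n[b$bin != "genome-wide"]), nrow(ld) - inter)
})

test_that("within-subgroup LD is lower than whole-population LD for distant pairs", {
  distal_means <- function(panel, map, accessions = NULL) {
    b <- ld_bin(ld_pairwise(panel, map, accessions))
    mean(b$mean_r2[b$bin %in% c("[500,1000)", "[1000,Inf)")], na.rm = TRUE)
  }
  ok <- vapply(1:3, function(s) {
    cfg <- sim_config(n_accessions = 150, subpop_proportions = c(0.5, 0.5),
                      n_markers = 60, alleles_per_marker = 4, divergence = 0.5,
                      ld_block_span = 0, chrom_lengths = rep(3e6, 3),
                      missing_rate = 0, seed = 400 + s)
    sim <- simulate_genotypes(cfg)
    sp <- sim$truth$subpops
    whole <- distal_means(sim$panel, sim$map)
    within <- mean(vapply(c("indica", "japonica"), function(ss) {
      distal_means(sim$panel, sim$map, sp$accession[sp$subpop == ss])
    }, numeric(1)))
    within < whole
  }, logical(1))
  expect_true(all(ok))
})

test_that("delta-K reproduces the hand second-difference example", {
  lnpd <- tibble::tibble(K = rep(1:3, each = 2), rep = rep(c("r1", "r2"), 3),
                         lnpd = c(-100, -100, -49, -51, -45, -45))
  dk <- evanno_delta_k(lnpd)
  expect_equal(dk$delta_k[dk$K == 2], 45 / sd(c(-49, -51)), tolerance = 1e-12)
  expect_equal(dk$delta_k[dk$K == 2], 31.82, tolerance = 1e-3)
  expect_true(is.na(dk$delta_k[dk$K == 1]))
})

test_that("delta-K of a linear LnP(D) profile is near zero and a knee is located", {
  set.seed(33)
  # linear in K: second difference of the means ~ 0
  lin <- tidyr::expand_grid(K = 1:6, rep = as.character(1:10)) |>
    dplyr::mutate(lnpd = -1000 + 50 * K + rnorm(dplyr::n(), 0, 0.5))
  dk <- evanno_delta_k(lin)
  expect_true(all(dk$delta_k[2:5] < 3, na.rm = TRUE))
  # sharp knee at K = 2
  knee <- tidyr::expand_grid(K = 1:6, rep = as.character(1:10)) |>
    dplyr::mutate(lnpd = ifelse(K <= 2, -2000 + 500 * K, -1000 - 5 * (K - 2)) +
                    rnorm(dplyr::n(), 0, 2))
  dk <- evanno_delta_k(knee)
  expect_equal(dk$K[which.max(dk$delta_k)], 2L)
})

test_that("delta-K input validation and zero-SD flagging work", {
  expect_error(evanno_delta_k(tibble::tibble(K = c(1, 2), rep = "a",
                                             lnpd = 1:2)), "three consecutive")
  expect_error(evanno_delta_k(tibble::tibble(K = rep(c(1, 3, 4), each = 2),
                                             rep = rep(c("a", "b"), 3),
                                             lnpd = 1:6)), "consecutive")
  lnpd <- tibble::tibble(K = rep(1:3, each = 2), rep = rep(c("a", "b"), 3),
                         lnpd = c(-10, -10, -5, -5, -4, -4))
  expect_warning(dk <- evanno_delta_k(lnpd), "zero replicate SD")
  expect_true(is.nan(dk$delta_k[dk$K == 2]))
})
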