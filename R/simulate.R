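#' Simulation configuration for a structured SSR panel
#'
#' Builds the configuration object consumed by [simulate_genotypes()] and
#' [simulate_phenotypes()]. Defaults describe a rice mini-core-style diversity
#' panel: 174 fully inbred accessions split into two diverged subpopulations
#' (109 indica-like, 65 japonica-like), 273 multi-allelic SSR markers spread
#' over 12 chromosomes, and four percent-scale cold-tolerance measures whose
#' subpopulation baselines and residual spreads follow the magnitudes typical
#' of germination- and booting-stage cold screens (indica seedling survival
#' around 23%, japonica around 79%, booting-stage seed set below 30% with
#' coefficients of variation near or above 100%).
#'
#' @param n_accessions Number of accessions (inbred lines).
#' @param subpop_proportions Two fractions summing to 1; accessions are split
#'   deterministically (`round(n * p1)` in subpopulation 1, rest in 2).
#' @param subpop_names Labels for the two subpopulations.
#' @param n_markers Number of SSR markers.
#' @param alleles_per_marker Alleles per marker (scalar or length-`n_markers`
#'   vector); must be at least 2.
#' @param divergence Dirichlet concentration scaler for subpopulation allele
#'   frequencies around a common ancestral frequency vector. Smaller values
#'   give stronger differentiation (near-private alleles as it approaches 0);
#'   the default 1.5 produces divergence on the indica/japonica scale.
#' @param ld_block_span Distance (bp) within which a marker is generated by
#'   copy-with-mutation from its left neighbour, inducing LD that decays with
#'   distance. 0 disables linkage entirely.
#' @param ld_mutation Per-marker probability that the copied allele index is
#'   replaced by a fresh draw; controls how fast LD decays along a block.
#' @param chrom_lengths Chromosome lengths in bp. Defaults to approximate rice
#'   chromosome sizes.
#' @param qtl_spec Planted allele effects: a data frame with columns
#'   `marker` (index or name), `allele` (index), `measure`, `effect`
#'   (percent points added to carriers) and `scope` (a subpopulation name or
#'   `"both"`). `NULL` for no planted effects.
#' @param baseline_means Per-subpopulation baseline means (percent) for the
#'   measures `SSvR`, `SStR_NL`, `SStR_CW` and the normal-condition seed
#'   setting rate `SStR_N` used to derive `RSStR_CW`; a 2-row matrix
#'   (subpopulations) with those column names.
#' @param noise_sd Per-subpopulation residual standard deviations (percent),
#'   same shape as `baseline_means`.
#' @param missing_rate Fraction of genotype cells set to missing.
#' @param seed Integer seed; all draws flow from one RNG stream.
#'
#' @return A list of class `cold_sim_config`.
#' @export
sim_config <- function(n_accessions = 174,
                       subpop_proportions = c(109, 65) / 174,
                       subpop_names = c("indica", "japonica"),
                       n_markers = 273,
                       alleles_per_marker = 5,
                       divergence = 1.5,
                       ld_block_span = 150e3,
                       ld_mutation = 0.1,
                       chrom_lengths = rice_chrom_lengths(),
                       qtl_spec = NULL,
                       baseline_means = NULL,
                       noise_sd = NULL,
                       missing_rate = 0.02,
                       seed = NULL) {
  stopifnot(length(subpop_proportions) == 2)
  if (abs(sum(subpop_proportions) - 1) > 1e-12)
    stop("subpop_proportions must sum to 1", call. = FALSE)
  if (n_accessions < 2 || n_markers < 1)
    stop("counts must be positive", call. = FALSE)
  if (any(alleles_per_marker < 2))
    stop("alleles_per_marker must be at least 2", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  if (is.null(seed)) stop("a seed is required for reproducibility", call. = FALSE)

  if (is.null(baseline_means)) baseline_means <- default_baselines()
  if (is.null(noise_sd)) noise_sd <- default_noise_sd()
  stopifnot(identical(colnames(baseline_means), colnames(default_baselines())),
            identical(dim(noise_sd), dim(baseline_means)))
  if (!is.null(qtl_spec)) {
    qtl_spec <- tibble::as_tibble(qtl_spec)
    stopifnot(all(c("marker", "allele", "measure", "effect", "scope") %in%
                    names(qtl_spec)))
    if (any(!is.finite(qtl_spec$effect)))
      stop("planted effect sizes must be finite", call. = FALSE)
  }

  structure(list(
    n_accessions = as.integer(n_accessions),
    subpop_proportions = subpop_proportions,
    subpop_names = subpop_names,
    n_markers = as.integer(n_markers),
    alleles_per_marker = rep_len(as.integer(alleles_per_marker), n_markers),
    divergence = divergence,
    ld_block_span = ld_block_span,
    ld_mutation = ld_mutation,
    chrom_lengths = chrom_lengths,
    qtl_spec = qtl_spec,
    baseline_means = baseline_means,
    noise_sd = noise_sd,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "cold_sim_config")
}

# Approximate IRGSP rice chromosome lengths (bp), chromosomes 1-12.
rice_chrom_lengths <- function() {
  c(43.3, 35.9, 36.4, 35.5, 29.9, 31.2,
    29.7, 28.4, 23.0, 23.2, 29.0, 27.5) * 1e6
}

# Subpopulation baselines (percent) matched to the magnitudes of published
# indica/japonica cold screens; SStR_N is the normal-condition seed set used
# only to form the RSStR_CW ratio.
default_baselines <- function() {
  m <- rbind(c(23.39, 18.88, 14.71, 85),
             c(79.11, 29.89, 16.87, 85))
  dimnames(m) <- list(NULL, c("SSvR", "SStR_NL", "SStR_CW", "SStR_N"))
  m
}

default_noise_sd <- function() {
  m <- rbind(c(18.03, 21.33, 21.24, 10),
             c(28.67, 26.41, 19.54, 10))
  dimnames(m) <- list(NULL, c("SSvR", "SStR_NL", "SStR_CW", "SStR_N"))
  m
}

#' Simulate a structured, LD-patterned SSR genotype panel
#'
#' Draws a fully homozygous genotype panel for two diverged subpopulations.
#' Each marker has an ancestral allele-frequency vector drawn from a symmetric
#' Dirichlet; each subpopulation's frequencies are drawn from a Dirichlet
#' centred on the ancestral vector with total concentration controlled by
#' `divergence` (a Balding-Nichols-style model, so small `divergence` gives
#' near-fixed private alleles). Marker positions are uniform per chromosome and
#' sorted; a marker closer than `ld_block_span` to its left neighbour is
#' generated per accession by copying the neighbour's allele index with
#' probability `1 - ld_mutation`, which induces LD decaying with distance.
#' Missing cells are inserted completely at random at `missing_rate`.
#'
#' @param config A [sim_config()] object.
#' @return A list with `panel` (tibble: `accession` plus one column per marker,
#'   cells are allele labels `marker_size` or `NA`), `map` (tibble: `marker`,
#'   `chrom`, `pos_bp`) and `truth` (list: `subpops` tibble, realized
#'   `qtl_spec`, per-subpopulation `allele_freqs`, and `allele_labels`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "cold_sim_config"))
  set.seed(config$seed)
  n <- config$n_accessions
  m <- config$n_markers
  n1 <- as.integer(round(n * config$subpop_proportions[1]))
  n2 <- n - n1
  subpop <- rep(config$subpop_names, c(n1, n2))
  acc <- sprintf("ACC%03d", seq_len(n))

  # marker map: positions uniform per chromosome, sorted, 1-based
  chrom_of <- sort(sample.int(length(config$chrom_lengths), m, replace = TRUE))
  pos <- vapply(chrom_of, function(ch) {
    ceiling(runif(1) * config$chrom_lengths[ch])
  }, numeric(1))
  ord <- order(chrom_of, pos)
  chrom_of <- chrom_of[ord]
  pos <- pos[ord]
  marker <- sprintf("M%03d", seq_len(m))
  map <- tibble::tibble(marker = marker,
                        chrom = as.integer(chrom_of),
                        pos_bp = as.numeric(pos))

  # allele frequencies per subpopulation
  freqs <- vector("list", m)
  labels <- vector("list", m)
  for (j in seq_len(m)) {
    k <- config$alleles_per_marker[j]
    anc <- rdirichlet1(rep(1, k))
    f1 <- rdirichlet1(config$divergence * k * anc)
    f2 <- rdirichlet1(config$divergence * k * anc)
    freqs[[j]] <- rbind(f1, f2)
    labels[[j]] <- paste0(marker[j], "_", 100 + 2L * seq_len(k))
  }

  # allele indices, chained within LD blocks
  idx <- matrix(0L, nrow = n, ncol = m)
  for (j in seq_len(m)) {
    k <- config$alleles_per_marker[j]
    fresh <- integer(n)
    for (s in 1:2) {
      rows <- which(subpop == config$subpop_names[s])
      fresh[rows] <- sample.int(k, length(rows), replace = TRUE,
                                prob = freqs[[j]][s, ])
    }
    linked <- j > 1 &&
      chrom_of[j] == chrom_of[j - 1] &&
      (pos[j] - pos[j - 1]) <= config$ld_block_span &&
      config$ld_block_span > 0
    if (linked) {
      keep <- runif(n) >= config$ld_mutation
      copied <- pmin(idx[, j - 1], k)  # neighbour may have more alleles
      idx[, j] <- ifelse(keep, copied, fresh)
    } else {
      idx[, j] <- fresh
    }
  }

  cells <- matrix(NA_character_, nrow = n, ncol = m, dimnames = list(NULL, marker))
  for (j in seq_len(m)) cells[, j] <- labels[[j]][idx[, j]]
  if (config$missing_rate > 0) {
    cells[matrix(runif(n * m) < config$missing_rate, n, m)] <- NA_character_
  }

  panel <- dplyr::bind_cols(tibble::tibble(accession = acc),
                            tibble::as_tibble(cells))

  qtl <- config$qtl_spec
  if (!is.null(qtl)) {
    midx <- if (is.numeric(qtl$marker)) as.integer(qtl$marker)
            else match(qtl$marker, marker)
    if (any(is.na(midx)) || any(midx < 1 | midx > m))
      stop("qtl_spec references a marker outside the panel", call. = FALSE)
    bad <- qtl$allele > config$alleles_per_marker[midx]
    if (any(bad))
      stop("qtl_spec references an allele outside the marker's range", call. = FALSE)
    qtl <- dplyr::mutate(qtl,
      marker = .env$marker[midx],
      allele_label = purrr::map2_chr(midx, .data$allele, ~ labels[[.x]][.y]))
  }

  truth <- list(
    subpops = tibble::tibble(accession = acc, subpop = subpop),
    qtl_spec = qtl,
    allele_freqs = setNames(freqs, marker),
    allele_labels = setNames(labels, marker)
  )
  list(panel = panel, map = map, truth = truth)
}

# one Dirichlet draw via gammas
rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = pmax(alpha, 1e-8))
  if (sum(x) == 0) x[sample.int(length(x), 1)] <- 1
  x / sum(x)
}

#' Simulate cold-tolerance phenotypes for a genotype panel
#'
#' Each measure is subpopulation baseline + the sum of planted allele effects
#' carried by the accession (restricted to the effect's subpopulation scope) +
#' Gaussian noise, clamped to \[0, 100\]. `RSStR_CW` is formed as
#' `100 * SStR_CW / SStR_N` where `SStR_N` is a simulated normal-condition
#' seed setting rate, so cold-water and relative seed set are strongly
#' correlated as in real booting-stage screens; planted effects targeting
#' `RSStR_CW` are added after the ratio.
#'
#' @param panel,truth Output of [simulate_genotypes()].
#' @param config The same [sim_config()] object.
#' @return A tibble `accession`, `subspecies`, `SSvR`, `SStR_NL`, `SStR_CW`,
#'   `RSStR_CW`.
#' @export
simulate_phenotypes <- function(panel, truth, config) {
  stopifnot(inherits(config, "cold_sim_config"))
  if (!all(panel$accession %in% truth$subpops$accession))
    stop("accession present in panel but absent from subpopulation assignment",
         call. = FALSE)
  sp <- truth$subpops$subpop[match(panel$accession, truth$subpops$accession)]
  s <- match(sp, config$subpop_names)
  n <- nrow(panel)

  base_measures <- c("SSvR", "SStR_NL", "SStR_CW", "SStR_N")
  vals <- sapply(base_measures, function(ms) {
    config$baseline_means[s, ms] + rnorm(n, 0, config$noise_sd[s, ms])
  })
  vals <- vals + planted_effects(panel, truth, config, sp, base_measures)
  vals <- pmin(pmax(vals, 0), 100)

  rel <- 100 * vals[, "SStR_CW"] / pmax(vals[, "SStR_N"], 1e-9)
  rel <- rel + planted_effects(panel, truth, config, sp, "RSStR_CW")
  rel <- pmin(pmax(rel, 0), 100)

  tibble::tibble(accession = panel$accession, subspecies = sp,
                 SSvR = vals[, "SSvR"], SStR_NL = vals[, "SStR_NL"],
                 SStR_CW = vals[, "SStR_CW"], RSStR_CW = as.numeric(rel))
}

# sum of planted allele effects per accession for each measure column
planted_effects <- function(panel, truth, config, sp, measures) {
  out <- matrix(0, nrow = nrow(panel), ncol = length(measures),
                dimnames = list(NULL, measures))
  qtl <- truth$qtl_spec
  if (is.null(qtl)) return(out)
  for (i in seq_len(nrow(qtl))) {
    ms <- qtl$measure[i]
    if (!ms %in% measures) next
    carrier <- !is.na(panel[[qtl$marker[i]]]) &
      panel[[qtl$marker[i]]] == qtl$allele_label[i]
    if (qtl$scope[i] != "both") carrier <- carrier & sp == qtl$scope[i]
    out[carrier, ms] <- out[carrier, ms] + qtl$effect[i]
  }
  out
}

#' Simulate a complete panel: genotypes, map, phenotypes and ground truth
#'
#' @param config A [sim_config()] object.
#' @return A list with `panel`, `map`, `pheno` and `truth`.
#' @export
simulate_cold_panel <- function(config) {
  g <- simulate_genotypes(config)
  pheno <- simulate_phenotypes(g$panel, g$truth, config)
  list(panel = g$panel, map = g$map, pheno = pheno, truth = g$truth)
}
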