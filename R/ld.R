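#' Pairwise multi-allelic linkage disequilibrium r-squared
#'
#' Computes LD between every pair of markers on a panel of fully homozygous
#' inbred accessions, treating each accession as one known-phase haplotype.
#' For markers A and B with alleles a, b the per-pair disequilibrium is
#' `D_ab = p_ab - p_a * p_b` and
#' `r2_ab = D_ab^2 / (p_a (1 - p_a) p_b (1 - p_b))`; the marker-level
#' statistic is the frequency-weighted average `sum_ab p_a p_b r2_ab`
#' (the convention used by standard association-mapping software). For
#' biallelic markers this reduces exactly to the classical r-squared.
#' Missing cells are removed pairwise; pairs that are monomorphic after
#' deletion are skipped (counted in the `n_skipped` attribute).
#'
#' @param panel Genotype tibble (`accession` + one column per marker, allele
#'   labels in cells).
#' @param map Optional marker map tibble (`marker`, `chrom`, `pos_bp`); when
#'   supplied each record carries the chromosome flag and bp distance.
#' @param accessions Optional character vector restricting the panel (e.g. one
#'   subspecies).
#' @return Tibble with `marker1`, `marker2`, `same_chrom`, `dist_bp` (NA for
#'   inter-chromosomal pairs), `r2`, `n` (haplotypes used); attribute
#'   `n_skipped` counts monomorphic-pair skips.
#' @export
ld_pairwise <- function(panel, map = NULL, accessions = NULL) {
  if (!is.null(accessions)) panel <- panel[panel$accession %in% accessions, ]
  markers <- setdiff(names(panel), "accession")
  if (length(markers) < 2) stop("need at least two markers", call. = FALSE)
  if (nrow(panel) < 2) stop("need at least two accessions", call. = FALSE)
  geno <- as.matrix(panel[, markers, drop = FALSE])

  combos <- utils::combn(length(markers), 2)
  res <- vector("list", ncol(combos))
  skipped <- 0L
  for (q in seq_len(ncol(combos))) {
    i <- combos[1, q]; j <- combos[2, q]
    ok <- !is.na(geno[, i]) & !is.na(geno[, j])
    if (sum(ok) < 2) { skipped <- skipped + 1L; next }
    r2 <- multiallelic_r2(geno[ok, i], geno[ok, j])
    if (is.na(r2)) { skipped <- skipped + 1L; next }
    res[[q]] <- c(i, j, r2, sum(ok))
  }
  res <- res[!vapply(res, is.null, logical(1))]
  out <- tibble::tibble(
    marker1 = markers[vapply(res, `[`, numeric(1), 1)],
    marker2 = markers[vapply(res, `[`, numeric(1), 2)],
    r2 = vapply(res, `[`, numeric(1), 3),
    n = as.integer(vapply(res, `[`, numeric(1), 4))
  )
  if (!is.null(map)) {
    m1 <- match(out$marker1, map$marker)
    m2 <- match(out$marker2, map$marker)
    if (anyNA(m1) || anyNA(m2))
      stop("panel contains markers absent from the map", call. = FALSE)
    same <- map$chrom[m1] == map$chrom[m2]
    out$same_chrom <- same
    out$dist_bp <- ifelse(same, abs(map$pos_bp[m1] - map$pos_bp[m2]), NA_real_)
  } else {
    out$same_chrom <- NA
    out$dist_bp <- NA_real_
  }
  out <- out[, c("marker1", "marker2", "same_chrom", "dist_bp", "r2", "n")]
  attr(out, "n_skipped") <- skipped
  out
}

# frequency-weighted multi-allelic r2 for two complete haplotype vectors
multiallelic_r2 <- function(a, b) {
  fa <- table(a) / length(a)
  fb <- table(b) / length(b)
  if (length(fa) < 2 || length(fb) < 2) return(NA_real_)
  joint <- table(a, b) / length(a)
  pa <- as.numeric(fa)[match(rownames(joint), names(fa))]
  pb <- as.numeric(fb)[match(colnames(joint), names(fb))]
  D <- joint - outer(pa, pb)
  r2ab <- D^2 / outer(pa * (1 - pa), pb * (1 - pb))
  sum(outer(pa, pb) * r2ab)
}

#' Bin LD records by physical distance
#'
#' Groups intra-chromosomal marker pairs into the half-open distance bins
#' \[0, 50), \[50, 150), \[150, 500), \[500, 1000) and \[1000, Inf) kb and
#' reports the mean and SD of r-squared per bin. Inter-chromosomal pairs are
#' excluded from the bins but contribute to the genome-wide summary row.
#'
#' @param records Output of [ld_pairwise()] (needs `dist_bp`, `r2`).
#' @param breaks_kb Bin edges in kb (half-open on the right).
#' @return Tibble with `bin`, `n`, `mean_r2`, `sd_r2`; the final row
#'   (`bin == "genome-wide"`) summarises all pairs including
#'   inter-chromosomal ones.
#' @export
ld_bin <- function(records, breaks_kb = c(0, 50, 150, 500, 1000, Inf)) {
  stopifnot(all(c("dist_bp", "r2") %in% names(records)))
  labs <- paste0("[", breaks_kb[-length(breaks_kb)], ",",
                 breaks_kb[-1], ")")
  intra <- records[!is.na(records$dist_bp), ]
  bin <- cut(intra$dist_bp / 1000, breaks = breaks_kb, labels = labs,
             right = FALSE, include.lowest = FALSE)
  per_bin <- tibble::tibble(bin = factor(labs, levels = labs)) |>
    dplyr::left_join(
      tibble::tibble(bin = bin, r2 = intra$r2) |>
        dplyr::group_by(.data$bin) |>
        dplyr::summarise(n = dplyr::n(), mean_r2 = mean(.data$r2),
                         sd_r2 = sd(.data$r2), .groups = "drop"),
      by = "bin") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  bin = as.character(.data$bin))
  genome <- tibble::tibble(bin = "genome-wide", n = nrow(records),
                           mean_r2 = mean(records$r2), sd_r2 = sd(records$r2))
  dplyr::bind_rows(per_bin, genome)
}

#' Evanno delta-K from STRUCTURE LnP(D) replicates
#'
#' Post-processes replicated STRUCTURE log-probabilities to locate the knee in
#' LnP(D): for each interior K,
#' `deltaK = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))`,
#' where means and the (n-1 denominator) SD are over replicates. The K with
#' the largest delta-K is the supported number of clusters.
#'
#' @param lnpd Tibble with columns `K`, `rep`, `lnpd`.
#' @return Tibble with `K`, `n_rep`, `mean_lnpd`, `sd_lnpd` and `delta_k`
#'   (NA at the boundary K values; NaN-flagged when `sd_lnpd` is 0).
#' @export
evanno_delta_k <- function(lnpd) {
  stopifnot(all(c("K", "rep", "lnpd") %in% names(lnpd)))
  agg <- lnpd |>
    dplyr::group_by(.data$K) |>
    dplyr::summarise(n_rep = dplyr::n(), mean_lnpd = mean(.data$lnpd),
                     sd_lnpd = sd(.data$lnpd), .groups = "drop") |>
    dplyr::arrange(.data$K)
  if (nrow(agg) < 3)
    stop("delta-K needs at least three consecutive K values", call. = FALSE)
  if (any(diff(agg$K) != 1))
    stop("K values must be consecutive integers", call. = FALSE)
  if (any(agg$n_rep < 2))
    stop("at least two replicates per K are required", call. = FALSE)
  kk <- nrow(agg)
  dk <- rep(NA_real_, kk)
  for (i in 2:(kk - 1)) {
    num <- abs(agg$mean_lnpd[i + 1] - 2 * agg$mean_lnpd[i] + agg$mean_lnpd[i - 1])
    dk[i] <- if (agg$sd_lnpd[i] == 0) NaN else num / agg$sd_lnpd[i]
  }
  if (any(is.nan(dk)))
    warning("delta-K undefined (zero replicate SD) at K = ",
            paste(agg$K[is.nan(dk)], collapse = ", "), call. = FALSE)
  agg$delta_k <- dk
  agg
}
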