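#' Count positive genotypes carried by each accession
#'
#' The pyramiding screen: take the set of positive (cold-tolerant) genotype
#' labels discovered for one measure in a reference subspecies, and count how
#' many each accession of the whole panel carries. Genotype identity is the
#' full allele label (marker + fragment size): a different allele at the same
#' marker never counts, and a missing genotype contributes zero. Negative
#' genotypes carried are listed alongside with their RGE.
#'
#' @param panel Genotype tibble.
#' @param pheno Phenotype tibble (supplies each accession's subspecies and the
#'   measure value).
#' @param effects Classified effects tibble from [rge_effects()].
#' @param reference_subspecies Subspecies whose discovery set defines the
#'   positive genotypes.
#' @param measure Measure the screen targets.
#' @return Tibble: `accession`, `subspecies`, `measure`, `value` (the
#'   accession's measure), `n_positive`, `n_negative`, and a list-column
#'   `negatives` (tibbles `allele`, `rge`). The positive set size is attached
#'   as attribute `n_positive_set`.
#' @export
count_positive_genotypes <- function(panel, pheno, effects,
                                     reference_subspecies, measure) {
  pos <- effects[effects$class == "positive" &
                   effects$subspecies == reference_subspecies &
                   effects$measure == measure, ]
  neg <- effects[effects$class == "negative" &
                   effects$subspecies == reference_subspecies &
                   effects$measure == measure, ]
  if (nrow(pos) == 0)
    warning("empty positive genotype set for ", measure, " in ",
            reference_subspecies, "; all counts are 0", call. = FALSE)
  out <- dplyr::inner_join(
    pheno[, c("accession", "subspecies", measure)],
    panel, by = "accession")
  carried <- function(set) {
    if (nrow(set) == 0) return(rep(0L, nrow(out)))
    hits <- vapply(seq_len(nrow(set)), function(i) {
      col <- out[[set$marker[i]]]
      !is.na(col) & col == set$allele[i]
    }, logical(nrow(out)))
    as.integer(rowSums(matrix(hits, nrow = nrow(out))))
  }
  neg_list <- lapply(seq_len(nrow(out)), function(r) {
    if (nrow(neg) == 0) return(tibble::tibble(allele = character(),
                                              rge = numeric()))
    carry <- vapply(seq_len(nrow(neg)), function(i) {
      v <- out[[neg$marker[i]]][r]
      !is.na(v) && v == neg$allele[i]
    }, logical(1))
    tibble::tibble(allele = neg$allele[carry], rge = neg$rge[carry])
  })
  vals <- out[[measure]]
  res <- tibble::tibble(
    accession = out$accession,
    subspecies = out$subspecies,
    measure = measure,
    value = vals,
    n_positive = carried(pos),
    n_negative = carried(neg),
    negatives = neg_list)
  attr(res, "n_positive_set") <- nrow(pos)
  res
}

#' Phenotype-by-pyramiding-count summary
#'
#' Groups accessions of one subspecies by the number of positive genotypes
#' carried and summarises the measure per count class. Count classes with
#' fewer than `min_class_size` accessions are merged into the nearest count
#' class (ties toward the smaller count) so summaries stay stable.
#'
#' @param profiles Output of [count_positive_genotypes()].
#' @param subspecies Subspecies to summarise.
#' @param min_class_size Smallest count class kept unmerged (default 3).
#' @return Tibble: `count_class` (label, possibly merged), `count` (numeric
#'   representative used for ordering), `n`, `mean`, `sd`.
#' @export
summarize_pyramiding <- function(profiles, subspecies, min_class_size = 3) {
  dat <- profiles[profiles$subspecies == subspecies & !is.na(profiles$value), ]
  if (nrow(dat) == 0) stop("no accessions for ", subspecies, call. = FALSE)
  counts <- sort(unique(dat$n_positive))
  grp <- stats::setNames(counts, counts)
  repeat {
    sizes <- table(factor(grp[as.character(dat$n_positive)],
                          levels = unique(grp)))
    small <- names(sizes)[sizes < min_class_size & sizes > 0]
    if (length(small) == 0 || length(unique(grp)) == 1) break
    # merge the sparsest class first (ties: the largest count, i.e. the tail)
    small <- small[order(sizes[small], -as.numeric(small))]
    tgt <- as.numeric(small[1])
    others <- setdiff(unique(grp), tgt)
    dist <- abs(others - tgt)
    nearest <- min(others[dist == min(dist)])  # tie toward the smaller count
    grp[grp == tgt] <- nearest
  }
  dat$count_grp <- grp[as.character(dat$n_positive)]
  dat |>
    dplyr::group_by(count = .data$count_grp) |>
    dplyr::summarise(
      count_class = paste(sort(unique(.data$n_positive)), collapse = "+"),
      n = dplyr::n(), mean = mean(.data$value), sd = sd(.data$value),
      .groups = "drop") |>
    dplyr::arrange(.data$count) |>
    dplyr::select("count_class", "count", "n", "mean", "sd")
}

#' Flag accessions carrying strong negative genotypes
#'
#' An accession carrying any negative (cold-sensitive) genotype whose RGE is
#' at or below `-threshold_rge` is flagged, with the offending genotype and
#' its effect listed — these are the lines whose favourable alleles elsewhere
#' can be cancelled in a marker-assisted selection programme.
#'
#' @param profiles Output of [count_positive_genotypes()].
#' @param threshold_rge Magnitude threshold on the negative RGE (default 0.5,
#'   i.e. a 50% reduction relative to the subspecies mean).
#' @return Tibble: `accession`, `subspecies`, `measure`, `value`, `allele`,
#'   `rge` — one row per strong negative genotype carried.
#' @export
flag_strong_negatives <- function(profiles, threshold_rge = 0.5) {
  profiles |>
    dplyr::select("accession", "subspecies", "measure", "value", "negatives") |>
    tidyr::unnest("negatives") |>
    dplyr::filter(.data$rge <= -threshold_rge)
}

#' Top accessions by a measure, with genotype presence/absence
#'
#' Ranks accessions of one subspecies by a measure (descending; ties broken
#' by accession id ascending), keeps the top `k`, and reports
#' presence/absence of every positive and negative genotype discovered for
#' that (measure, subspecies), plus two summary booleans per accession: does
#' it carry at least one positive genotype, and does it carry zero strong
#' negatives.
#'
#' @param pheno,panel Phenotype and genotype tibbles.
#' @param effects Classified effects tibble.
#' @param measure,subspecies Screen coordinates.
#' @param k Number of top accessions (default 5); truncated with a warning if
#'   the subspecies has fewer scored accessions.
#' @param threshold_rge Strong-negative threshold (default 0.5).
#' @return Tibble: `rank`, `accession`, `value`, one logical column per
#'   genotype (named `<allele> [pos]` / `<allele> [neg]`),
#'   `any_positive`, `no_strong_negative`.
#' @export
top_accessions <- function(pheno, panel, effects, measure, subspecies,
                           k = 5, threshold_rge = 0.5) {
  sub <- pheno[pheno$subspecies == subspecies & !is.na(pheno[[measure]]), ]
  if (nrow(sub) == 0) stop("no scored accessions in ", subspecies, call. = FALSE)
  if (nrow(sub) < k) {
    warning("only ", nrow(sub), " accessions available; k truncated",
            call. = FALSE)
    k <- nrow(sub)
  }
  sub <- sub[order(-sub[[measure]], sub$accession), ][seq_len(k), ]
  eff <- effects[effects$measure == measure &
                   effects$subspecies == subspecies &
                   effects$class %in% c("positive", "negative"), ]
  eff <- eff[order(eff$class, decreasing = TRUE), ]  # positives first
  geno <- panel[match(sub$accession, panel$accession), ]
  pres <- lapply(seq_len(nrow(eff)), function(i) {
    col <- geno[[eff$marker[i]]]
    !is.na(col) & col == eff$allele[i]
  })
  names(pres) <- paste0(eff$allele, " [",
                        substr(eff$class, 1, 3), "]")
  strong_neg <- eff$class == "negative" & eff$rge <= -threshold_rge
  out <- tibble::tibble(rank = seq_len(k),
                        accession = sub$accession,
                        value = sub[[measure]])
  out <- dplyr::bind_cols(out, tibble::as_tibble(pres, .name_repair = "minimal"))
  pres_mat <- if (length(pres)) do.call(cbind, pres) else
    matrix(FALSE, nrow = k, ncol = 0)
  out$any_positive <- if (any(eff$class == "positive"))
    rowSums(pres_mat[, eff$class == "positive", drop = FALSE]) > 0 else FALSE
  out$no_strong_negative <- if (any(strong_neg))
    rowSums(pres_mat[, strong_neg, drop = FALSE]) == 0 else TRUE
  out
}
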