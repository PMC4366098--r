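#' Relative genotypic effect of each genotype class
#'
#' For every genotype class (allele) of every association record, computes the
#' relative genotypic effect
#' `RGE = (class mean - subspecies mean) / subspecies mean`, its variance
#' `MS_RGE = (MS_E / n_i) / subspecies mean^2` built from the marker's error
#' mean square, the z statistic `RGE / sqrt(MS_RGE)` and its two-sided normal
#' p-value. A class with `RGE = -0.6`, say, reduces the measure by 60%
#' relative to the subspecies mean. By default only markers that survived the
#' sequential adjustment (called QTLs) are scored.
#'
#' @param scan A `cold_scan` object from [assoc_scan()], or a tibble of
#'   association records with columns `marker`, `measure`, `subspecies`,
#'   `ms_e`, `grand_mean`, `classes` (and `rejected` unless
#'   `all_markers = TRUE`).
#' @param alpha Two-sided level for the z classification (default 0.05).
#' @param all_markers If `TRUE`, score every fitted marker, not only called
#'   QTLs.
#' @return Tibble of class effects: `marker`, `allele` (full genotype label),
#'   `measure`, `subspecies`, `n_i`, `class_mean`, `subsp_mean`, `rge`,
#'   `ms_rge`, `z`, `p`, `class` (`"positive"`, `"negative"`, `"neutral"`).
#' @export
rge_effects <- function(scan, alpha = 0.05, all_markers = FALSE) {
  records <- if (inherits(scan, "cold_scan")) scan$records else scan
  stopifnot(all(c("marker", "measure", "subspecies", "ms_e",
                  "grand_mean", "classes") %in% names(records)))
  if (!all_markers) {
    if (!"rejected" %in% names(records))
      stop("records carry no `rejected` column; use all_markers = TRUE",
           call. = FALSE)
    records <- records[records$rejected, ]
  }
  if (nrow(records) == 0) return(empty_effects())
  bad <- records$grand_mean <= 0
  if (any(bad)) {
    warning("subspecies mean is 0 for ",
            paste(unique(paste(records$measure[bad], records$subspecies[bad],
                               sep = "/")), collapse = ", "),
            "; effects undefined and dropped", call. = FALSE)
    records <- records[!bad, ]
  }
  if (nrow(records) == 0) return(empty_effects())
  eff <- records |>
    dplyr::mutate(.row = dplyr::row_number()) |>
    tidyr::unnest("classes") |>
    dplyr::transmute(
      .data$marker, allele = .data$allele, .data$measure, .data$subspecies,
      n_i = .data$n, class_mean = .data$mean, subsp_mean = .data$grand_mean,
      rge = (.data$mean - .data$grand_mean) / .data$grand_mean,
      ms_rge = (.data$ms_e / .data$n) / .data$grand_mean^2,
      z = .data$rge / sqrt(.data$ms_rge),
      p = 2 * pnorm(-abs(.data$z)))
  classify_genotypes(eff, alpha = alpha)
}

empty_effects <- function() {
  tibble::tibble(marker = character(), allele = character(),
                 measure = character(), subspecies = character(),
                 n_i = integer(), class_mean = numeric(),
                 subsp_mean = numeric(), rge = numeric(), ms_rge = numeric(),
                 z = numeric(), p = numeric(), class = character())
}

#' Classify genotype effects as cold-tolerant or cold-sensitive
#'
#' Labels each effect `"positive"` (cold-tolerant allele: RGE significantly
#' above zero), `"negative"` (cold-sensitive: significantly below) or
#' `"neutral"`, using the two-sided z-test at level `alpha`.
#'
#' @param effects Tibble with `rge` and `p` columns (from [rge_effects()]).
#' @param alpha Significance level (default 0.05).
#' @return The input with a (re)computed `class` column; per-subspecies counts
#'   are attached as the `counts` attribute.
#' @export
classify_genotypes <- function(effects, alpha = 0.05) {
  effects$class <- dplyr::case_when(
    effects$p < alpha & effects$rge > 0 ~ "positive",
    effects$p < alpha & effects$rge < 0 ~ "negative",
    TRUE ~ "neutral")
  counts <- effects |>
    dplyr::count(.data$subspecies, .data$class) |>
    tidyr::pivot_wider(names_from = "class", values_from = "n",
                       values_fill = 0L)
  attr(effects, "counts") <- counts
  effects
}

#' Asymmetry of positive vs negative genotype effects
#'
#' Summarises, per subspecies, the mean and maximum absolute RGE of the
#' positive and negative classes — the pattern of interest being whether
#' cold-sensitive (negative) alleles act more strongly than cold-tolerant
#' ones.
#'
#' @param effects Classified effects tibble (see [rge_effects()]).
#' @return Tibble: `subspecies`, `class`, `n`, `mean_abs_rge`, `max_abs_rge`.
#'   Subspecies with an empty positive or negative class get an `NA` row with
#'   a note attribute.
#' @export
effect_asymmetry <- function(effects) {
  base <- tidyr::expand_grid(
    subspecies = unique(effects$subspecies),
    class = c("positive", "negative"))
  got <- effects |>
    dplyr::filter(.data$class %in% c("positive", "negative")) |>
    dplyr::group_by(.data$subspecies, .data$class) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_abs_rge = mean(abs(.data$rge)),
                     max_abs_rge = max(abs(.data$rge)), .groups = "drop")
  out <- dplyr::left_join(base, got, by = c("subspecies", "class")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))
  missing <- out[out$n == 0, c("subspecies", "class")]
  if (nrow(missing) > 0)
    attr(out, "note") <- paste0("no ", missing$class, " effects in ",
                                missing$subspecies, collapse = "; ")
  out
}
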