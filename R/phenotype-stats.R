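#' Descriptive statistics per measure and subspecies
#'
#' Summarises each percent-scale measure within each subspecies: mean, range,
#' sample SD (n-1 denominator) and coefficient of variation
#' `CV% = 100 * SD / mean`. Missing values are dropped per
#' (measure, subspecies) group.
#'
#' @param pheno Phenotype tibble with columns `accession`, `subspecies` and
#'   one column per measure (default the four cold-tolerance measures).
#' @param measures Character vector of measure columns to summarise.
#' @return A tibble with `measure`, `subspecies`, `n`, `mean`, `min`, `max`,
#'   `sd`, `cv` (all percents).
#' @export
pheno_summary <- function(pheno, measures = intersect(measure_names(), names(pheno))) {
  stopifnot(all(c("accession", "subspecies") %in% names(pheno)),
            length(measures) > 0)
  long <- tidyr::pivot_longer(pheno[, c("subspecies", measures)],
                              dplyr::all_of(measures),
                              names_to = "measure", values_to = "value")
  out <- long |>
    dplyr::group_by(measure = factor(.data$measure, levels = measures),
                    .data$subspecies) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      min = suppressWarnings(min(.data$value, na.rm = TRUE)),
      max = suppressWarnings(max(.data$value, na.rm = TRUE)),
      sd = sd(.data$value, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(measure = as.character(.data$measure))
  if (any(out$n == 0)) {
    bad <- out[out$n == 0, ]
    stop("all values missing for ", paste(bad$measure, bad$subspecies,
         sep = "/", collapse = ", "), call. = FALSE)
  }
  if (any(out$n < 2))
    stop("fewer than 2 non-missing values in some (measure, subspecies) group",
         call. = FALSE)
  out$cv <- ifelse(out$mean > 0, 100 * out$sd / out$mean, NA_real_)
  if (anyNA(out$cv))
    warning("CV undefined for groups with non-positive mean", call. = FALSE)
  out
}

#' Subspecies contrast for one measure
#'
#' Welch (unequal-variance) two-sample t-test of a measure between the two
#' subspecies, with the conventional star code: `"*"` for p < 0.05, `"**"`
#' for p < 0.01.
#'
#' @param pheno Phenotype tibble (see [pheno_summary()]).
#' @param measure Name of the measure column.
#' @return One-row tibble: `measure`, `t`, `df`, `p`, `stars`.
#' @export
pheno_contrast <- function(pheno, measure) {
  stopifnot(measure %in% names(pheno))
  groups <- split(pheno[[measure]], pheno$subspecies)
  groups <- lapply(groups, function(x) x[!is.na(x)])
  if (length(groups) != 2)
    stop("exactly two subspecies required, found ", length(groups), call. = FALSE)
  if (sd(unlist(groups)) == 0) {
    tt <- list(statistic = c(t = 0), parameter = c(df = NA_real_), p.value = 1)
  } else {
    tt <- stats::t.test(groups[[1]], groups[[2]])
  }
  tibble::tibble(measure = measure,
                 t = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p = tt$p.value,
                 stars = star_code(tt$p.value))
}

star_code <- function(p, levels = c(0.05, 0.01)) {
  dplyr::case_when(p < levels[2] ~ "**", p < levels[1] ~ "*", TRUE ~ "")
}

#' Pearson correlation matrix among measures within one subspecies
#'
#' Pairwise-complete Pearson correlations among the measures, with two-sided
#' p-values and a star marking p < 0.01 (the usual convention for such
#' tables). Zero-variance measures yield missing correlations with a warning.
#'
#' @param pheno Phenotype tibble.
#' @param subspecies Which subspecies to subset to; `NULL` uses all rows.
#' @param measures Measure columns to correlate.
#' @return A list with `r` (matrix), `p` (matrix) and `stars` (matrix), plus a
#'   tidy tibble under `$pairs`.
#' @export
pheno_correlation <- function(pheno, subspecies = NULL,
                              measures = intersect(measure_names(), names(pheno))) {
  dat <- if (is.null(subspecies)) pheno else
    pheno[pheno$subspecies == subspecies, , drop = FALSE]
  x <- as.matrix(dat[, measures, drop = FALSE])
  vars <- apply(x, 2, function(v) sd(v, na.rm = TRUE))
  if (any(!is.na(vars) & vars == 0))
    warning("zero-variance measure(s): ",
            paste(measures[!is.na(vars) & vars == 0], collapse = ", "),
            "; correlations reported as NA", call. = FALSE)
  k <- length(measures)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(measures, measures))
  diag(r) <- 1
  diag(p) <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- stats::complete.cases(x[, c(i, j)])
    if (sum(ok) < 3 || vars[i] == 0 || vars[j] == 0) next
    ct <- stats::cor.test(x[ok, i], x[ok, j], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  stars <- matrix(ifelse(!is.na(p) & p < 0.01 & row(p) != col(p), "**", ""),
                  k, k, dimnames = dimnames(p))
  pairs <- tidyr::expand_grid(m1 = measures, m2 = measures) |>
    dplyr::filter(.data$m1 < .data$m2) |>
    dplyr::mutate(r = r[cbind(.data$m1, .data$m2)],
                  p = p[cbind(.data$m1, .data$m2)],
                  stars = stars[cbind(.data$m1, .data$m2)])
  list(r = r, p = p, stars = stars, pairs = pairs)
}
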