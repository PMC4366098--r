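#' Per-marker one-way GLM association test
#'
#' Fits the fixed-effect general linear model `measure ~ genotype class` for
#' one SSR marker within one subspecies: a one-way ANOVA over the allele
#' classes observed at the marker. Accessions with missing genotype or
#' phenotype are dropped, then classes smaller than `min_class_size` are
#' removed (not merged) before fitting. The record carries everything the
#' downstream relative-genotypic-effect step needs: per-class sizes and
#' means, the subspecies mean over retained accessions, the error mean
#' square, and the model R-squared (the marker's contribution to phenotypic
#' variation, CPV).
#'
#' @param panel Genotype tibble (`accession` + marker columns).
#' @param pheno Phenotype tibble (`accession`, `subspecies`, measures).
#' @param marker Marker column name.
#' @param measure Measure column name.
#' @param subspecies Subspecies to analyse, or `NULL` for all accessions.
#' @param min_class_size Minimum genotype-class size retained (default 5).
#' @return One-row tibble: `marker`, `measure`, `subspecies`, `k`, `N`, `F`,
#'   `p`, `r2` (model SS / total SS), `ms_e`, `grand_mean`, and a list-column
#'   `classes` (tibble `allele`, `n`, `mean`). `NULL` (with a message) when
#'   fewer than two eligible classes remain.
#' @export
fit_marker_glm <- function(panel, pheno, marker, measure,
                           subspecies = NULL, min_class_size = 5) {
  stopifnot(marker %in% names(panel), measure %in% names(pheno))
  dat <- dplyr::inner_join(
    panel[, c("accession", marker)],
    pheno[, c("accession", "subspecies", measure)],
    by = "accession")
  if (!is.null(subspecies)) dat <- dat[dat$subspecies == subspecies, ]
  names(dat)[names(dat) == marker] <- ".g"
  names(dat)[names(dat) == measure] <- ".y"
  dat <- dat[!is.na(dat$.g) & !is.na(dat$.y), ]
  keep <- names(which(table(dat$.g) >= min_class_size))
  dat <- dat[dat$.g %in% keep, ]
  if (length(keep) < 2) {
    message("marker ", marker, " (", measure, ", ",
            subspecies %||% "all", "): fewer than 2 eligible classes; skipped")
    return(NULL)
  }
  g <- factor(dat$.g)
  # lm warns on an exactly perfect fit; that case is handled explicitly below
  suppressWarnings({
    fit <- lm(.y ~ g, data = dat)
    an <- anova(fit)
  })
  ss_model <- an$`Sum Sq`[1]
  ss_e <- an$`Sum Sq`[2]
  ss_tot <- ss_model + ss_e
  Fst <- an$`F value`[1]
  p <- an$`Pr(>F)`[1]
  # treat residual SS as zero at floating-point resolution of the total SS
  if (ss_e <= 1e-12 * max(ss_tot, 1e-300)) {
    if (ss_model > 0) {
      warning("zero residual sum of squares at ", marker,
              "; p reported as 0", call. = FALSE)
      Fst <- Inf; p <- 0
    } else {  # constant phenotype: no association signal
      Fst <- 0; p <- 1
    }
  }
  cls <- dat |>
    dplyr::group_by(allele = as.character(.data$.g)) |>
    dplyr::summarise(n = dplyr::n(), mean = mean(.data$.y), .groups = "drop")
  tibble::tibble(
    marker = marker, measure = measure,
    subspecies = subspecies %||% NA_character_,
    k = nlevels(g), N = nrow(dat),
    F = Fst, p = p,
    r2 = if (ss_tot > 0) ss_model / ss_tot else 0,
    ms_e = an$`Mean Sq`[2],
    grand_mean = mean(dat$.y),
    classes = list(cls))
}

#' Sequential significance-level adjustment
#'
#' Step-down multiple-testing rule applied to one scan's p-values: sort
#' ascending, compare the j-th smallest p-value with `alpha * (1-alpha)^R`
#' where R is the number of hypotheses already rejected, reject and increment
#' R on success, and stop at the first failure. With `alpha = 0.05` the
#' thresholds are 0.05, 0.0475, 0.045125, ... Ties are broken by name for
#' determinism. Note this rule's first comparison is the raw `alpha`, so it
#' does not control the family-wise error rate in the strong sense; it bounds
#' the expected fraction of false rejections per scan (see the package
#' vignette).
#'
#' @param p Numeric p-values in \[0, 1\].
#' @param alpha Base significance level (default 0.05).
#' @param names Optional identifiers for tie-breaking and reporting.
#' @return Tibble in the original order: `name`, `p`, `threshold` (the level
#'   each p-value faced, NA for p-values never reached), `rejected`.
#' @export
sequential_adjust <- function(p, alpha = 0.05, names = NULL) {
  if (length(p) == 0)
    return(tibble::tibble(name = character(), p = numeric(),
                          threshold = numeric(), rejected = logical()))
  stopifnot(all(p >= 0 & p <= 1), alpha > 0, alpha < 1)
  if (is.null(names)) names <- sprintf("test%04d", seq_along(p))
  ord <- order(p, names)
  thr <- rep(NA_real_, length(p))
  rej <- logical(length(p))
  R <- 0L
  for (j in ord) {
    cutoff <- alpha * (1 - alpha)^R
    thr[j] <- cutoff
    if (p[j] <= cutoff) { rej[j] <- TRUE; R <- R + 1L } else break
  }
  tibble::tibble(name = names, p = p, threshold = thr, rejected = rej)
}

#' Genome scan: per-marker GLM association across measures and subspecies
#'
#' Runs [fit_marker_glm()] for every marker in the panel, for each requested
#' measure within each subspecies, then applies [sequential_adjust()]
#' separately to each (subspecies, measure) scan and names the significant
#' markers as QTLs via [call_qtls()].
#'
#' @param panel,pheno Genotype and phenotype tibbles.
#' @param map Marker map tibble (`marker`, `chrom`, `pos_bp`) for QTL naming.
#' @param measures Measure columns to scan (default all four).
#' @param subspecies Subspecies levels to scan (default both observed).
#' @param alpha Base significance level for the sequential adjustment.
#' @param min_class_size Minimum genotype-class size (see [fit_marker_glm()]).
#' @return An object of class `cold_scan`: list with `records` (association
#'   tibble including `threshold` and `rejected`), `qtls` (QTL call tibble)
#'   and the scan parameters.
#' @export
assoc_scan <- function(panel, pheno, map = NULL,
                       measures = intersect(measure_names(), names(pheno)),
                       subspecies = sort(unique(pheno$subspecies)),
                       alpha = 0.05, min_class_size = 5) {
  markers <- setdiff(names(panel), "accession")
  grid <- tidyr::expand_grid(subspecies = subspecies, measure = measures)
  records <- purrr::pmap(grid, function(subspecies, measure) {
    recs <- purrr::map(markers, function(mk) {
      suppressMessages(fit_marker_glm(panel, pheno, mk, measure,
                                      subspecies, min_class_size))
    })
    recs <- dplyr::bind_rows(recs)
    if (nrow(recs) == 0) return(recs)
    adj <- sequential_adjust(recs$p, alpha, names = recs$marker)
    recs$threshold <- adj$threshold
    recs$rejected <- adj$rejected
    recs
  }) |> dplyr::bind_rows()
  qtls <- call_qtls(records, map)
  structure(list(records = records, qtls = qtls, map = map,
                 alpha = alpha, min_class_size = min_class_size),
            class = "cold_scan")
}

#' Name significant markers as QTLs
#'
#' Markers surviving the sequential adjustment become QTL calls named
#' `q<prefix><chromosome>-<ordinal>`, with `LT` + the measure tag as prefix
#' (e.g. `qLTSSvR6-2` for the second SSvR QTL on chromosome 6), ordinals
#' assigned by position within each (measure, chromosome). A cross-tabulation
#' of markers called for multiple measures or subspecies is attached as the
#' `shared` attribute.
#'
#' @param records Association tibble with `rejected` (from [assoc_scan()] or
#'   [sequential_adjust()] applied per scan).
#' @param map Marker map; calls for unmapped markers keep `chrom = NA` with a
#'   warning.
#' @return Tibble: `qtl`, `marker`, `chrom`, `pos_bp`, `measure`,
#'   `subspecies`, `p`, `cpv` (percent), `ms_e`, `threshold`.
#' @export
call_qtls <- function(records, map = NULL) {
  empty <- tibble::tibble(qtl = character(), marker = character(),
                          chrom = integer(), pos_bp = numeric(),
                          measure = character(), subspecies = character(),
                          p = numeric(), cpv = numeric(), ms_e = numeric(),
                          threshold = numeric())
  if (is.null(records) || nrow(records) == 0 || !any(records$rejected))
    return(empty)
  hits <- records[records$rejected, ]
  if (!is.null(map)) {
    idx <- match(hits$marker, map$marker)
    if (anyNA(idx))
      warning("marker(s) missing from map: ",
              paste(unique(hits$marker[is.na(idx)]), collapse = ", "),
              call. = FALSE)
    hits$chrom <- map$chrom[idx]
    hits$pos_bp <- map$pos_bp[idx]
  } else {
    hits$chrom <- NA_integer_
    hits$pos_bp <- NA_real_
  }
  # ordinal by position within (measure, chromosome), shared across subspecies
  key <- hits |>
    dplyr::distinct(.data$measure, .data$chrom, .data$marker, .data$pos_bp) |>
    dplyr::arrange(.data$measure, .data$chrom, .data$pos_bp, .data$marker) |>
    dplyr::group_by(.data$measure, .data$chrom) |>
    dplyr::mutate(ord = dplyr::row_number()) |>
    dplyr::ungroup()
  hits <- dplyr::left_join(hits, key[, c("measure", "chrom", "marker", "ord")],
                           by = c("measure", "chrom", "marker"))
  hits$qtl <- paste0("qLT", gsub("_", "", hits$measure),
                     ifelse(is.na(hits$chrom), "NA", hits$chrom),
                     "-", hits$ord)
  out <- hits |>
    dplyr::transmute(.data$qtl, .data$marker, .data$chrom, .data$pos_bp,
                     .data$measure, .data$subspecies, .data$p,
                     cpv = 100 * .data$r2, .data$ms_e, .data$threshold) |>
    dplyr::arrange(.data$measure, .data$subspecies, .data$chrom, .data$pos_bp)
  shared <- out |>
    dplyr::count(.data$marker, name = "n_calls") |>
    dplyr::filter(.data$n_calls > 1)
  attr(out, "shared") <- shared
  out
}

#' @export
print.cold_scan <- function(x, ...) {
  cat("<cold_scan>\n")
  cat("  records:", nrow(x$records), "marker-measure-subspecies fits\n")
  cat("  QTL calls:", nrow(x$qtls), "\n")
  cat("  alpha:", x$alpha, " min class size:", x$min_class_size, "\n")
  invisible(x)
}

#' @rdname tidy
#' @title Tidy and summarise association scans
#' @description `tidy()` returns the per-fit association records of a
#'   [assoc_scan()] object; `glance()` returns one row of scan-level counts.
#' @param x A `cold_scan` object.
#' @param ... Unused.
#' @method tidy cold_scan
#' @export
tidy.cold_scan <- function(x, ...) {
  dplyr::select(x$records, -"classes")
}

#' @rdname tidy
#' @method glance cold_scan
#' @export
glance.cold_scan <- function(x, ...) {
  tibble::tibble(
    n_fits = nrow(x$records),
    n_markers = dplyr::n_distinct(x$records$marker),
    n_qtls = nrow(x$qtls),
    n_qtl_markers = dplyr::n_distinct(x$qtls$marker),
    mean_cpv = if (nrow(x$qtls)) mean(x$qtls$cpv) else NA_real_,
    alpha = x$alpha)
}
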