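#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates simulate (optional) -> phenotype statistics -> LD -> GLM
#' association scan -> relative genotypic effects -> pyramiding screens, with
#' a single reproducibility seed, writing every stage table as CSV plus a run
#' manifest (stage, file, md5, parameters, seed). The same configuration and
#' seed yield byte-identical outputs.
#'
#' @param config A named list, or path to a YAML file, with elements:
#'   either `simulate` (a list of [sim_config()] arguments) or `geno`,
#'   `pheno`, `map` (CSV paths); optional `alpha` (default 0.05),
#'   `min_class_size` (5), `threshold_rge` (0.5), `k_top` (5),
#'   `reference_subspecies` (first level), `seed` (overridden by the `seed`
#'   argument), `lnpd` (CSV path for the delta-K helper).
#' @param out_dir Output directory (created if absent).
#' @param seed Optional integer overriding `config$seed`.
#' @return Invisibly, a list with all stage results and the manifest tibble.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  alpha <- config$alpha %||% 0.05
  stopifnot(alpha > 0, alpha < 1)
  min_class_size <- config$min_class_size %||% 5
  threshold_rge <- config$threshold_rge %||% 0.5
  k_top <- config$k_top %||% 5
  seed <- seed %||% config$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  stages <- character()
  emit <- function(x, stage, name) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    write_stage_csv(x, path)
    files <<- c(files, path)
    stages <<- c(stages, stage)
    path
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- inputs ---------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim <- run_stage("simulate", {
      args <- config$simulate
      if (!is.null(seed)) args$seed <- seed
      cfg <- do.call(sim_config, args)
      simulate_cold_panel(cfg)
    })
    panel <- sim$panel; map <- sim$map; pheno <- sim$pheno
    emit(panel, "simulate", "genotypes")
    emit(map, "simulate", "marker_map")
    emit(pheno, "simulate", "phenotypes")
    emit(sim$truth$subpops, "simulate", "truth_subpops")
    if (!is.null(sim$truth$qtl_spec))
      emit(sim$truth$qtl_spec, "simulate", "truth_qtls")
  } else {
    panel <- run_stage("input", read_genotypes(config$geno))
    pheno <- run_stage("input", read_phenotypes(config$pheno))
    map <- run_stage("input", read_marker_map(config$map))
    sim <- NULL
  }
  if (isTRUE(config$simulate_only %||% FALSE)) {
    manifest <- pipeline_manifest(stages, files, alpha, min_class_size,
                                  threshold_rge, k_top, seed)
    emit_manifest(manifest, out_dir)
    return(invisible(list(sim = sim, manifest = manifest)))
  }

  # --- stats ----------------------------------------------------------------
  stats_tab <- run_stage("stats", pheno_summary(pheno))
  emit(stats_tab, "stats", "phenotype_summary")
  contrasts <- run_stage("stats", dplyr::bind_rows(
    lapply(intersect(measure_names(), names(pheno)),
           function(ms) pheno_contrast(pheno, ms))))
  emit(contrasts, "stats", "subspecies_contrasts")
  cors <- run_stage("stats", {
    dplyr::bind_rows(lapply(sort(unique(pheno$subspecies)), function(sp) {
      dplyr::mutate(pheno_correlation(pheno, sp)$pairs, subspecies = sp,
                    .before = 1)
    }))
  })
  emit(cors, "stats", "correlations")

  # --- LD -------------------------------------------------------------------
  ld <- run_stage("ld", ld_pairwise(panel, map))
  bins <- run_stage("ld", ld_bin(ld))
  emit(bins, "ld", "ld_bins")
  if (!is.null(config$lnpd)) {
    dk <- run_stage("ld", evanno_delta_k(read_lnpd(config$lnpd)))
    emit(dk, "ld", "evanno_delta_k")
  }

  # --- association ----------------------------------------------------------
  scan <- run_stage("assoc", assoc_scan(panel, pheno, map, alpha = alpha,
                                        min_class_size = min_class_size))
  emit(tidy(scan), "assoc", "association_records")
  emit(scan$qtls, "assoc", "qtl_calls")

  # --- RGE ------------------------------------------------------------------
  effects <- run_stage("rge", rge_effects(scan, alpha = alpha))
  emit(effects, "rge", "genotype_effects")
  asym <- run_stage("rge", if (nrow(effects)) effect_asymmetry(effects)
                    else NULL)
  if (!is.null(asym)) emit(asym, "rge", "effect_asymmetry")

  # --- screening ------------------------------------------------------------
  ref <- config$reference_subspecies %||% sort(unique(pheno$subspecies))[1]
  screens <- run_stage("screen", {
    out <- list()
    for (ms in unique(effects$measure[effects$class == "positive"])) {
      prof <- count_positive_genotypes(panel, pheno, effects, ref, ms)
      out[[ms]] <- prof
    }
    out
  })
  if (length(screens)) {
    prof_all <- dplyr::bind_rows(lapply(screens, dplyr::select, -"negatives"))
    emit(prof_all, "screen", "pyramiding_profiles")
    flags <- dplyr::bind_rows(lapply(screens, flag_strong_negatives,
                                     threshold_rge = threshold_rge))
    emit(flags, "screen", "strong_negative_flags")
    tops <- dplyr::bind_rows(lapply(names(screens), function(ms) {
      if (!any(effects$measure == ms & effects$subspecies == ref)) return(NULL)
      tt <- top_accessions(pheno, panel, effects, ms, ref, k = k_top,
                           threshold_rge = threshold_rge)
      keep <- c("rank", "accession", "value", "any_positive",
                "no_strong_negative")
      dplyr::mutate(tt[, keep], measure = ms, subspecies = ref, .before = 1)
    }))
    if (!is.null(tops) && nrow(tops)) emit(tops, "screen", "top_accessions")
  }

  manifest <- pipeline_manifest(stages, files, alpha, min_class_size,
                                threshold_rge, k_top, seed)
  emit_manifest(manifest, out_dir)
  invisible(list(sim = sim, stats = stats_tab, contrasts = contrasts,
                 correlations = cors, ld_bins = bins, scan = scan,
                 effects = effects, screens = screens, manifest = manifest))
}

pipeline_manifest <- function(stages, files, alpha, min_class_size,
                              threshold_rge, k_top, seed) {
  tibble::tibble(
    stage = stages,
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    alpha = alpha, min_class_size = min_class_size,
    threshold_rge = threshold_rge, k_top = k_top,
    seed = seed %||% NA_integer_)
}

emit_manifest <- function(manifest, out_dir) {
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"), na = "")
}
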