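#' LD decay plot
#'
#' Mean r-squared per distance bin, the standard LD-decay summary for a
#' marker panel.
#'
#' @param bins Output of [ld_bin()].
#' @return A ggplot object.
#' @export
plot_ld_decay <- function(bins) {
  dat <- bins[bins$bin != "genome-wide" & bins$n > 0, ]
  dat$bin <- factor(dat$bin, levels = dat$bin)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin, y = .data$mean_r2,
                                    group = 1)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(.data$mean_r2 - .data$sd_r2, 0),
                                        ymax = .data$mean_r2 + .data$sd_r2),
                           width = 0.15, colour = "grey60") +
    ggplot2::labs(x = "distance bin (kb)", y = expression(mean~r^2)) +
    ggplot2::theme_minimal()
}

#' Manhattan-style view of an association scan
#'
#' Plots -log10(p) by genomic position for each (subspecies, measure) scan,
#' marking markers that survived the sequential adjustment.
#'
#' @param object A `cold_scan` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cold_scan
#' @export
autoplot.cold_scan <- function(object, ...) {
  recs <- tidy(object)
  if (!is.null(object$map)) {
    idx <- match(recs$marker, object$map$marker)
    recs$chrom <- object$map$chrom[idx]
    recs$pos_bp <- object$map$pos_bp[idx]
  } else {
    recs$chrom <- 1L
    recs$pos_bp <- as.numeric(factor(recs$marker))
  }
  ggplot2::ggplot(recs, ggplot2::aes(x = .data$pos_bp / 1e6,
                                     y = -log10(pmax(.data$p, 1e-300)),
                                     colour = .data$rejected)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(measure + subspecies ~ chrom, scales = "free_x",
                        space = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p)),
                  colour = "called") +
    ggplot2::theme_minimal()
}

#' Phenotype by pyramiding count
#'
#' Shows the distribution of a measure across positive-genotype count classes
#' (boxplot of raw accession values with the class mean overlaid), the
#' standard view of a pyramiding screen.
#'
#' @param profiles Output of [count_positive_genotypes()].
#' @param subspecies Subspecies to display.
#' @param min_class_size Count classes smaller than this are merged (see
#'   [summarize_pyramiding()]).
#' @return A ggplot object.
#' @export
plot_pyramiding <- function(profiles, subspecies, min_class_size = 3) {
  summ <- summarize_pyramiding(profiles, subspecies, min_class_size)
  dat <- profiles[profiles$subspecies == subspecies & !is.na(profiles$value), ]
  lab <- vapply(dat$n_positive, function(cnt) {
    summ$count_class[vapply(strsplit(summ$count_class, "\\+"),
                            function(s) as.character(cnt) %in% s, logical(1))][1]
  }, character(1))
  dat$count_class <- factor(lab, levels = summ$count_class)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$count_class, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.8, fill = "grey90") +
    ggplot2::geom_point(data = summ,
                        ggplot2::aes(x = .data$count_class, y = .data$mean),
                        colour = "firebrick", size = 2) +
    ggplot2::labs(x = "positive genotypes carried",
                  y = paste0(dat$measure[1], " (%)")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
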