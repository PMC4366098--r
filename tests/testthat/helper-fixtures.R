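# Small in-code fixtures shared across test files.

# A tiny hand-built panel: 8 inbred accessions, 3 markers.
tiny_panel <- function() {
  tibble::tibble(
    accession = sprintf("A%02d", 1:8),
    RM1 = c("RM1_100", "RM1_100", "RM1_102", "RM1_102",
            "RM1_100", "RM1_102", "RM1_100", "RM1_102"),
    RM2 = c("RM2_150", "RM2_150", "RM2_152", "RM2_152",
            "RM2_150", "RM2_152", "RM2_150", "RM2_152"),
    RM3 = c("RM3_200", "RM3_202", "RM3_200", "RM3_202",
            "RM3_202", "RM3_200", "RM3_202", "RM3_200"))
}

tiny_map <- function() {
  tibble::tibble(marker = c("RM1", "RM2", "RM3"),
                 chrom = c(1L, 1L, 2L),
                 pos_bp = c(1e5, 1.4e5, 2e5))
}

tiny_pheno <- function(values = NULL) {
  tibble::tibble(
    accession = sprintf("A%02d", 1:8),
    subspecies = rep(c("indica", "japonica"), each = 4),
    SSvR = values %||% c(20, 25, 30, 22, 70, 80, 85, 75),
    SStR_NL = c(10, 15, 12, 18, 25, 30, 35, 28),
    SStR_CW = c(5, 12, 9, 14, 15, 18, 22, 17),
    RSStR_CW = c(6, 14, 10, 16, 18, 22, 26, 20))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a phenotype vector with an exact sample mean and SD from two points.
two_point_sample <- function(mean, sd) mean + c(-1, 1) * sd / sqrt(2)

# First-principles one-way ANOVA oracle: explicit group-mean sums of squares.
anova_oracle <- function(y, g) {
  g <- as.character(g)
  grand <- mean(y)
  cls <- split(y, g)
  ni <- lengths(cls)
  mi <- vapply(cls, mean, numeric(1))
  ss_model <- sum(ni * (mi - grand)^2)
  ss_e <- sum(unlist(lapply(cls, function(v) (v - mean(v))^2)))
  k <- length(cls); N <- length(y)
  Fst <- (ss_model / (k - 1)) / (ss_e / (N - k))
  list(F = Fst, p = stats::pf(Fst, k - 1, N - k, lower.tail = FALSE),
       r2 = ss_model / (ss_model + ss_e), ms_e = ss_e / (N - k),
       k = k, N = N, means = mi, ni = ni)
}

# Classical biallelic r2 oracle from 0/1 indicator correlation.
biallelic_r2_oracle <- function(a, b) {
  stats::cor(as.integer(a == sort(unique(a))[1]),
             as.integer(b == sort(unique(b))[1]))^2
}
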