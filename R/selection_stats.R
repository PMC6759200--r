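#' Likelihood-ratio test of neutral vs. positive-selection site models
#'
#' Compares two nested codon site models (beta-distributed omega, "M7",
#' against beta plus a positive-selection omega class, "M8") from their
#' maximized log-likelihoods: the statistic 2(lnL_selection -
#' lnL_neutral), clipped at zero when the selection model scores lower,
#' is referred to the upper tail of a chi-square distribution. The
#' conventional 2 degrees of freedom for this model pair is the default.
#'
#' @param lnL_neutral,lnL_selection Finite maximized log-likelihoods.
#' @param df Degrees of freedom (default 2).
#' @param gene Label carried into the result.
#' @param n_tests,family_alpha Multiple-testing context used to set the
#'   Bonferroni significance flag (see
#'   \code{\link{bonferroni_threshold}}); \code{n_tests = NULL} flags
#'   against \code{family_alpha} uncorrected.
#' @return List of class \code{lrt_result}: gene, lnL_neutral,
#'   lnL_selection, statistic, df, p_value, significant_bonferroni.
#' @export
lrt_m7_m8 <- function(lnL_neutral, lnL_selection, df = 2L, gene = "gene",
                      n_tests = 12L, family_alpha = 0.05) {
  if (!is.finite(lnL_neutral) || !is.finite(lnL_selection)) {
    stop("log-likelihoods must be finite")
  }
  stat <- max(0, 2 * (lnL_selection - lnL_neutral))
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  thr <- if (is.null(n_tests)) family_alpha else bonferroni_threshold(family_alpha, n_tests)
  structure(list(gene = gene, lnL_neutral = lnL_neutral,
                 lnL_selection = lnL_selection, statistic = stat,
                 df = as.integer(df), p_value = p,
                 significant_bonferroni = p < thr),
            class = "lrt_result")
}

#' Bonferroni-corrected significance threshold
#'
#' @param family_alpha Family-wise error rate in (0, 1).
#' @param n_tests Number of tests (>= 1). The default of 12 tests at
#'   alpha = 0.05 gives the threshold 0.00417 used when screening a
#'   dozen complex subunits; whether distinct subunits constitute
#'   multiple tests of one hypothesis is debatable, so the uncorrected
#'   mode is available by setting \code{n_tests = 1}.
#' @param display_sf Significant figures for the display value.
#' @return The threshold \code{family_alpha / n_tests}, with attribute
#'   \code{display} holding the value rounded to \code{display_sf}
#'   significant figures.
#' @export
bonferroni_threshold <- function(family_alpha = 0.05, n_tests = 12L,
                                 display_sf = 3L) {
  if (length(n_tests) != 1L || is.na(n_tests) || n_tests < 1L) {
    stop("n_tests must be a positive integer")
  }
  if (family_alpha <= 0 || family_alpha >= 1) stop("family_alpha must be in (0,1)")
  thr <- family_alpha / n_tests
  attr(thr, "display") <- signif(thr, display_sf)
  thr
}

#' Batch LRTs from a table of per-gene log-likelihoods
#'
#' @param tab Data frame (or path to a TSV) with columns gene, lnL_M7,
#'   lnL_M8.
#' @param df,n_tests,family_alpha See \code{\link{lrt_m7_m8}};
#'   \code{n_tests} defaults to the number of rows.
#' @return Data frame: gene, lnL_M7, lnL_M8, statistic, p_value,
#'   significant_bonferroni.
#' @export
lrt_table <- function(tab, df = 2L, n_tests = NULL, family_alpha = 0.05) {
  if (is.character(tab)) {
    tab <- utils::read.table(tab, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  }
  need <- c("gene", "lnL_M7", "lnL_M8")
  if (!all(need %in% names(tab))) {
    stop("table must have columns: ", paste(need, collapse = ", "))
  }
  if (is.null(n_tests)) n_tests <- max(1L, nrow(tab))
  out <- lapply(seq_len(nrow(tab)), function(i) {
    r <- lrt_m7_m8(tab$lnL_M7[i], tab$lnL_M8[i], df = df, gene = tab$gene[i],
                   n_tests = n_tests, family_alpha = family_alpha)
    data.frame(gene = r$gene, lnL_M7 = r$lnL_neutral, lnL_M8 = r$lnL_selection,
               statistic = r$statistic, p_value = r$p_value,
               significant_bonferroni = r$significant_bonferroni)
  })
  do.call(rbind, out)
}
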