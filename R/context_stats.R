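# Comparative statistics of readthrough determinants: grouped median
# differences with Wilcoxon/BH, chi-squared association of stop codon and
# nt +4, Spearman correlations, and context frequency tables.

#' Group-vs-sample median comparison of readthrough efficiency
#'
#' For each level of a grouping (stop codon, a nucleotide position, the
#' stop/nt+4 quadruplet, P-site codon, or the negative-control letter),
#' reports the difference between the group median log2 readthrough
#' efficiency and the median of the whole sample (which includes the
#' group), with a two-tailed Wilcoxon rank-sum test of group vs sample and
#' Benjamini-Hochberg correction across the grouping's levels.
#'
#' @param log2_re Numeric log2 readthrough efficiencies.
#' @param groups Category per record.
#' @param grouping_name Label recorded in the output.
#' @param min_n Levels with fewer records are still reported but flagged
#'   (`small_group = TRUE`); default 5.
#' @param complement Compare each group against its complement instead of
#'   the full sample (default `FALSE`, the sample-median convention).
#' @return Data frame: `grouping`, `level`, `n`, `delta_median`, `p`, `q`,
#'   `small_group`.
#' @export
group_median_analysis <- function(log2_re, groups, grouping_name = "group",
                                  min_n = 5L, complement = FALSE) {
  keep <- is.finite(log2_re) & !is.na(groups)
  log2_re <- log2_re[keep]
  groups <- as.character(groups)[keep]
  if (!length(log2_re)) stop("no finite readthrough values")
  levels_ <- sort(unique(groups))
  if (length(levels_) < 1L) stop("no grouping levels")
  sample_median <- median(log2_re)
  rows <- lapply(levels_, function(lv) {
    in_grp <- groups == lv
    ref <- if (complement) log2_re[!in_grp] else log2_re
    ref_median <- median(ref)
    grp <- log2_re[in_grp]
    p <- if (length(grp) >= 1L && length(ref) >= 1L) {
      suppressWarnings(wilcox.test(grp, ref, alternative = "two.sided")$p.value)
    } else {
      NA_real_
    }
    data.frame(grouping = grouping_name, level = lv, n = length(grp),
               delta_median = median(grp) - ref_median,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out$small_group <- out$n < min_n
  out
}

#' Chi-squared association between stop codon and nt +4
#'
#' Tests independence of the stop codon and the nucleotide immediately
#' downstream over the 3 x 4 contingency table, reporting adjusted
#' standardized residuals: `(observed - expected) /
#' sqrt(expected * (1 - row_prop) * (1 - col_prop))`. A positive residual
#' means the pair occurs together more often than expected (attraction).
#' With `expectation = "equal_nt4"`, expected counts assume the four
#' nt +4 bases are equally frequent within each stop codon (goodness of
#' fit rather than independence); residuals are then Pearson residuals.
#'
#' @param stop Stop codon per record (UAA/UAG/UGA).
#' @param nt4 nt +4 base per record (A/C/G/U).
#' @param expectation `"independence"` (default) or `"equal_nt4"`.
#' @return List of class `chi2_result`: `observed`, `expected`,
#'   `std_residuals`, `pearson_residuals`, `chi2`, `df`, `p`, `cell_p`
#'   (two-tailed per-cell normal p-values on the standardized residuals).
#' @export
chi2_stop_nt4 <- function(stop, nt4,
                          expectation = c("independence", "equal_nt4")) {
  expectation <- match.arg(expectation)
  stop_f <- factor(as.character(stop), levels = intersect(STOP_CODONS,
                                                          unique(stop)))
  nt4_f <- factor(as.character(nt4), levels = intersect(RNA_BASES,
                                                        unique(nt4)))
  tab <- table(stop_codon = stop_f, nt4 = nt4_f)
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    stop("need at least 2 stop-codon and 2 nt+4 levels")
  }
  if (any(rowSums(tab) == 0)) {
    stop("empty stop-codon margin: ",
         rownames(tab)[rowSums(tab) == 0][1])
  }
  if (any(colSums(tab) == 0)) {
    stop("empty nt+4 margin: ", colnames(tab)[colSums(tab) == 0][1])
  }
  if (expectation == "independence") {
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    res <- list(observed = unclass(tab), expected = ct$expected,
                std_residuals = ct$stdres,
                pearson_residuals = ct$residuals,
                chi2 = unname(ct$statistic), df = unname(ct$parameter),
                p = ct$p.value)
  } else {
    expected <- matrix(rowSums(tab) / ncol(tab), nrow(tab), ncol(tab),
                       dimnames = dimnames(tab))
    pearson <- (unclass(tab) - expected) / sqrt(expected)
    chi2 <- sum(pearson^2)
    df <- nrow(tab) * (ncol(tab) - 1)
    res <- list(observed = unclass(tab), expected = expected,
                std_residuals = pearson, pearson_residuals = pearson,
                chi2 = chi2, df = df,
                p = stats::pchisq(chi2, df, lower.tail = FALSE))
  }
  res$cell_p <- 2 * pnorm(-abs(res$std_residuals))
  class(res) <- "chi2_result"
  res
}

#' @export
print.chi2_result <- function(x, ...) {
  cat("chi-squared = ", signif(x$chi2, 5), ", df = ", x$df,
      ", p = ", signif(x$p, 3), "\nstandardized residuals:\n", sep = "")
  print(round(x$std_residuals, 2))
  invisible(x)
}

#' Spearman correlation with optional range filter on x
#'
#' @param x,y Paired numeric vectors (e.g. 3'-UTR length and log2
#'   readthrough efficiency).
#' @param filter Optional `c(lo, hi)`: keep pairs with `lo < x < hi`
#'   (strict), e.g. `c(100, 5000)` for the length-restricted analysis.
#' @return List `rho`, `p` (two-tailed), `n`.
#' @export
correlate <- function(x, y, filter = NULL) {
  keep <- is.finite(x) & is.finite(y)
  if (!is.null(filter)) {
    keep <- keep & x > filter[1] & x < filter[2]
  }
  x <- x[keep]
  y <- y[keep]
  if (length(x) < 4) stop("need at least 4 paired values after filtering")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman",
                                  alternative = "two.sided", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Frequency tables of stop codon, nt +4, and quadruplet usage
#'
#' @param features Feature data frame containing `stop_codon` and `nt_p4`
#'   columns (e.g. from [extract_features()]), or an [mrna_catalog()].
#' @return List of data frames `stop`, `nt4`, `quadruplet`, each with
#'   `level`, `count`, `proportion` (proportions sum to 1 per family).
#' @export
context_frequency_table <- function(features) {
  if (!"stop_codon" %in% names(features)) {
    features <- extract_features(features)
  }
  stop_v <- features$stop_codon
  nt4_v <- features$nt_p4
  if (is.null(nt4_v)) stop("features must contain nt_p4")
  keep <- nt4_v %in% RNA_BASES
  quad <- paste0(stop_v, nt4_v)[keep]
  tab_df <- function(v) {
    tab <- table(v)
    data.frame(level = names(tab), count = as.integer(tab),
               proportion = as.numeric(tab) / sum(tab),
               stringsAsFactors = FALSE)
  }
  list(stop = tab_df(stop_v), nt4 = tab_df(nt4_v[keep]),
       quadruplet = tab_df(quad))
}
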