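# Dual-luciferase reporter assay processing: per-well readthrough levels,
# replicate outlier exclusion, drug-response fold changes, and stop-codon
# group comparisons.

#' Per-well readthrough level
#'
#' Firefly activity normalized to Renilla activity, as a percentage:
#' `firefly / renilla * 100`.
#'
#' @param firefly,renilla Luminescence readings; `renilla` must be
#'   positive.
#' @return Numeric percentage(s).
#' @export
readthrough_level <- function(firefly, renilla) {
  if (any(renilla <= 0)) stop("renilla units must be positive")
  if (any(firefly < 0)) stop("firefly units must be non-negative")
  firefly / renilla * 100
}

#' Exclude outlier wells from a replicate set
#'
#' While the relative dispersion SD/mean exceeds `threshold` percent and
#' more than two wells remain, the single well farthest from the current
#' mean is removed and the dispersion recomputed (`iterative = FALSE`
#' performs at most one removal). Every exclusion is reported with the
#' dispersion before and after. If the floor of two wells is reached while
#' the dispersion still exceeds the threshold, the result is flagged
#' `unresolved`.
#'
#' @param values Readthrough percentages for the replicate wells (>= 3).
#' @param threshold Maximum SD/mean in percent (default 25).
#' @param iterative Repeat removals until resolved (default `TRUE`).
#' @return List: `retained`, `excluded` (data frame `value`,
#'   `sd_ave_before`, `sd_ave_after`), `unresolved`.
#' @export
exclude_outlier_wells <- function(values, threshold = 25, iterative = TRUE) {
  if (length(values) < 3) stop("need at least 3 wells")
  sd_ave <- function(v) {
    m <- mean(v)
    if (m == 0) return(NA_real_)
    sd(v) / m * 100
  }
  excluded <- data.frame(value = numeric(0), sd_ave_before = numeric(0),
                         sd_ave_after = numeric(0))
  retained <- sort(values)  # order-invariant processing
  unresolved <- FALSE
  repeat {
    disp <- sd_ave(retained)
    if (is.na(disp)) {
      unresolved <- TRUE  # all-zero wells: dispersion undefined
      break
    }
    if (disp <= threshold) break
    if (length(retained) <= 2) {
      unresolved <- TRUE
      break
    }
    far <- which.max(abs(retained - mean(retained)))
    after <- retained[-far]
    excluded <- rbind(excluded,
                      data.frame(value = retained[far],
                                 sd_ave_before = disp,
                                 sd_ave_after = sd_ave(after)))
    retained <- after
    if (!iterative) {
      unresolved <- !is.na(sd_ave(retained)) && sd_ave(retained) > threshold
      break
    }
  }
  list(retained = retained, excluded = excluded, unresolved = unresolved)
}

#' Response to readthrough-drug treatment per allele
#'
#' Wells are technical replicates within an experiment: per experiment and
#' condition, readthrough levels are computed, outlier wells excluded, and
#' the retained wells averaged. Each experiment's response is
#' `log2(mean treated / mean untreated)`; the allele's response is the
#' mean over experiments.
#'
#' @param plate Data frame with columns `allele`, `experiment`,
#'   `condition` (`"untreated"` / `"G418"`), `firefly`, `renilla`.
#' @param threshold Outlier threshold passed to
#'   [exclude_outlier_wells()].
#' @return Data frame per allele: `allele`, `mean_untreated`,
#'   `mean_treated` (percent), `response` (mean log2 fold-change),
#'   `n_experiments`, `n_excluded_wells`, `n_skipped_experiments`.
#' @export
g418_response <- function(plate, threshold = 25) {
  required <- c("allele", "experiment", "condition", "firefly", "renilla")
  missing_cols <- setdiff(required, names(plate))
  if (length(missing_cols)) {
    stop("plate table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  bad_cond <- setdiff(unique(plate$condition), c("untreated", "G418"))
  if (length(bad_cond)) stop("unknown condition: ", bad_cond[1])
  out <- lapply(split(plate, plate$allele), function(pa) {
    resp <- numeric(0)
    means_u <- numeric(0)
    means_t <- numeric(0)
    n_excl <- 0L
    n_skip <- 0L
    for (pe in split(pa, pa$experiment)) {
      cond_mean <- function(cond) {
        w <- pe[pe$condition == cond, , drop = FALSE]
        if (!nrow(w)) return(NA_real_)
        lv <- readthrough_level(w$firefly, w$renilla)
        if (length(lv) >= 3) {
          ex <- exclude_outlier_wells(lv, threshold = threshold)
          n_excl <<- n_excl + nrow(ex$excluded)
          lv <- ex$retained
        }
        mean(lv)
      }
      mu <- cond_mean("untreated")
      mt <- cond_mean("G418")
      if (is.na(mu) || is.na(mt) || mu == 0) {
        n_skip <- n_skip + 1L
        next
      }
      resp <- c(resp, log2(mt / mu))
      means_u <- c(means_u, mu)
      means_t <- c(means_t, mt)
    }
    data.frame(allele = pa$allele[1],
               mean_untreated = if (length(means_u)) mean(means_u) else NA_real_,
               mean_treated = if (length(means_t)) mean(means_t) else NA_real_,
               response = if (length(resp)) mean(resp) else NA_real_,
               n_experiments = length(resp),
               n_excluded_wells = n_excl,
               n_skipped_experiments = n_skip,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Pairwise stop-codon group comparison of drug response
#'
#' Two-sample two-tailed Student's t-tests between the three stop-codon
#' groups (UGA-UAG, UGA-UAA, UAG-UAA) on per-allele responses, with
#' Benjamini-Hochberg correction over the three p-values. Pairs where a
#' group has fewer than 2 alleles are skipped with a flag.
#'
#' @param results Output of [g418_response()] (or any data frame with
#'   `allele` and `response`).
#' @param stops Named character vector or data frame mapping allele to its
#'   stop codon.
#' @return List: `tests` (data frame `group1`, `group2`, `n1`, `n2`,
#'   `mean1`, `mean2`, `p`, `q`, `skipped`), `group_means` (named, sorted
#'   decreasing).
#' @export
compare_response_by_stop <- function(results, stops) {
  if (is.data.frame(stops)) {
    stops <- setNames(stops$stop, stops$allele)
  }
  stop_per <- stops[results$allele]
  if (anyNA(stop_per)) {
    stop("missing stop codon for allele(s): ",
         paste(results$allele[is.na(stop_per)], collapse = ", "))
  }
  groups <- split(results$response, factor(stop_per, levels = STOP_CODONS))
  pairs <- list(c("UGA", "UAG"), c("UGA", "UAA"), c("UAG", "UAA"))
  rows <- lapply(pairs, function(pr) {
    g1 <- groups[[pr[1]]]
    g2 <- groups[[pr[2]]]
    skipped <- length(g1) < 2 || length(g2) < 2
    p <- if (skipped) NA_real_ else {
      tryCatch(
        t.test(g1, g2, var.equal = TRUE, alternative = "two.sided")$p.value,
        error = function(e) {
          # zero within-group variance: degenerate but well-defined cases
          if (isTRUE(all.equal(mean(g1), mean(g2)))) 1 else 0
        })
    }
    data.frame(group1 = pr[1], group2 = pr[2],
               n1 = length(g1), n2 = length(g2),
               mean1 = if (length(g1)) mean(g1) else NA_real_,
               mean2 = if (length(g2)) mean(g2) else NA_real_,
               p = p, skipped = skipped, stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, rows)
  tests$q <- p.adjust(tests$p, method = "BH")
  tests <- tests[, c("group1", "group2", "n1", "n2", "mean1", "mean2",
                     "p", "q", "skipped")]
  gm <- vapply(groups, function(g) if (length(g)) mean(g) else NA_real_,
               numeric(1))
  list(tests = tests, group_means = sort(gm, decreasing = TRUE,
                                         na.last = TRUE))
}
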