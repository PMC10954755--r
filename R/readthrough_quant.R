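# Region-count quantification: RPKM, log2 readthrough efficiency,
# detectability filtering, and extreme-group labeling.

#' Reads per kilobase of region per million mapped reads
#'
#' @param count Non-negative read count(s).
#' @param region_len Region length(s) in nt; must be positive.
#' @param library_size Mapped reads in the sample; must be positive.
#' @return Numeric RPKM value(s).
#' @export
rpkm <- function(count, region_len, library_size) {
  if (any(region_len <= 0)) stop("region_len must be positive")
  if (any(library_size <= 0)) stop("library_size must be positive")
  count / (region_len / 1000) / (library_size / 1e6)
}

#' Compute RPKMs and log2 readthrough efficiency from region counts
#'
#' Readthrough efficiency (RE) is the ratio of extension-region RPKM to
#' CDS RPKM, log2-transformed. Records with an empty extension region or a
#' zero RPKM on either side get `log2_re = NA` and are flagged
#' non-quantifiable.
#'
#' @param counts Data frame with columns `transcript_id`, `cds_count`,
#'   `ext_count`, `cds_len`, `ext_len`, `library_size`.
#' @return Data frame: `transcript_id`, `rpkm_cds`, `rpkm_ext`, `log2_re`,
#'   `quantifiable`.
#' @export
compute_readthrough <- function(counts) {
  required <- c("transcript_id", "cds_count", "ext_count", "cds_len",
                "ext_len", "library_size")
  missing_cols <- setdiff(required, names(counts))
  if (length(missing_cols)) {
    stop("counts table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(counts$cds_len <= 0)) stop("cds_len must be positive")
  rc <- rpkm(counts$cds_count, counts$cds_len, counts$library_size)
  ok_ext <- counts$ext_len > 0
  re <- rep(NA_real_, nrow(counts))
  re[ok_ext] <- rpkm(counts$ext_count[ok_ext], counts$ext_len[ok_ext],
                     counts$library_size[ok_ext])
  log2_re <- ifelse(!is.na(re) & re > 0 & rc > 0, log2(re / rc), NA_real_)
  data.frame(transcript_id = counts$transcript_id,
             rpkm_cds = rc,
             rpkm_ext = ifelse(ok_ext, re, NA_real_),
             log2_re = log2_re,
             quantifiable = !is.na(log2_re),
             stringsAsFactors = FALSE)
}

#' Filter to transcripts with detectable readthrough
#'
#' Retains records with CDS RPKM at or above `rpkm_cds_min` and extension
#' RPKM at or above `rpkm_ext_min`; everything else (including
#' non-quantifiable records) is discarded. Discard counts by reason are
#' attached as the `"discarded"` attribute.
#'
#' @param table Output of [compute_readthrough()].
#' @param rpkm_cds_min,rpkm_ext_min Detection thresholds (defaults 5 and
#'   0.5).
#' @return The retained subset, with attribute `"discarded"`.
#' @export
filter_detectable <- function(table, rpkm_cds_min = 5, rpkm_ext_min = 0.5) {
  low_cds <- table$rpkm_cds < rpkm_cds_min
  low_ext <- is.na(table$rpkm_ext) | table$rpkm_ext < rpkm_ext_min
  keep <- !low_cds & !low_ext & !is.na(table$log2_re)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "discarded") <- c(
    low_cds_only = sum(low_cds & !low_ext),
    low_ext_only = sum(low_ext & !low_cds),
    both = sum(low_cds & low_ext),
    unquantifiable_only = sum(!low_cds & !low_ext & is.na(table$log2_re)))
  out
}

#' Label extreme high/low readthrough transcripts
#'
#' The top and bottom `fraction` of records ranked by `log2_re` are
#' labeled `"high"` and `"low"`; everything else `"none"`. Exactly
#' `floor(fraction * n)` records receive each label; ties are broken
#' deterministically by `(log2_re, transcript_id)`.
#'
#' @param table Detectable readthrough table (with finite `log2_re`).
#' @param fraction Tail fraction in (0, 0.5); default 0.15.
#' @return `table` with an added `extreme_label` column.
#' @export
label_extremes <- function(table, fraction = 0.15) {
  if (fraction <= 0 || fraction >= 0.5) {
    stop("fraction must be in (0, 0.5)")
  }
  if (any(!is.finite(table$log2_re))) {
    stop("label_extremes requires finite log2_re; filter first")
  }
  n <- nrow(table)
  k <- floor(fraction * n)
  if (k < 1) stop("too few records (", n, ") for fraction ", fraction)
  ord <- order(table$log2_re, table$transcript_id)
  lab <- rep("none", n)
  lab[ord[seq_len(k)]] <- "low"
  lab[ord[seq.int(n - k + 1L, n)]] <- "high"
  table$extreme_label <- lab
  table
}

#' Read a region-count table
#'
#' Accepts either a full count table (`transcript_id`, `cds_count`,
#' `ext_count`, `cds_len`, `ext_len`, `library_size`) or a pre-computed
#' efficiency table (`transcript_id`, `log2_re`).
#'
#' @param path TSV path.
#' @return Data frame; pre-computed tables gain `quantifiable = TRUE`.
#' @export
read_region_counts <- function(path) {
  df <- read_tsv_meta(path)
  if (all(c("transcript_id", "log2_re") %in% names(df)) &&
      !"cds_count" %in% names(df)) {
    df$quantifiable <- is.finite(df$log2_re)
    return(df)
  }
  required <- c("transcript_id", "cds_count", "ext_count", "cds_len",
                "ext_len", "library_size")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("count table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df
}
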