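# Premature termination codon (PTC) readthrough prediction.
#
# A nonsense allele is specified in transcript space (codon index plus the
# stop codon it introduces). Two sequence contexts can be built for it:
#   native   - the PTC embedded in the gene's own mRNA; the CDS is
#              truncated at the PTC and everything downstream (the former
#              CDS remainder plus the native 3'-UTR) becomes the new
#              3'-UTR.
#   reporter - the PTC plus `flank_codons` codons of native context on
#              each side inserted between an upstream stop-less gene and a
#              downstream start-less gene (the dual-luciferase design), so
#              every feature outside the insert derives from the reporter
#              backbone and is constant across alleles.

#' Specify a nonsense (PTC) allele
#'
#' @param name Allele name (e.g. `"G542X-UGA"`).
#' @param gene_cds RNA string of the full coding sequence including the
#'   native stop codon.
#' @param utr3_native RNA string of the native 3'-UTR (downstream of the
#'   native stop codon).
#' @param ptc_codon_index 1-based codon number replaced by the stop.
#' @param ptc_stop One of `"UAA"`, `"UAG"`, `"UGA"`.
#' @return List of class `ptc_allele`.
#' @export
ptc_allele <- function(name, gene_cds, utr3_native, ptc_codon_index,
                       ptc_stop) {
  gene_cds <- normalize_rna(gene_cds)
  utr3_native <- normalize_rna(utr3_native)
  if (nchar(gene_cds) %% 3L != 0L) stop("gene_cds length must be a multiple of 3")
  n_codons <- nchar(gene_cds) %/% 3L
  if (!ptc_stop %in% STOP_CODONS) stop("ptc_stop must be a stop codon")
  if (ptc_codon_index < 1L || ptc_codon_index >= n_codons) {
    stop("ptc_codon_index must be in [1, ", n_codons - 1L,
         ") (before the native stop)")
  }
  structure(list(name = name, gene_cds = gene_cds,
                 utr3_native = utr3_native,
                 ptc_codon_index = as.integer(ptc_codon_index),
                 ptc_stop = ptc_stop, n_codons = n_codons),
            class = "ptc_allele")
}

#' Build the native-context transcript record for a PTC allele
#'
#' The CDS is truncated immediately before the PTC (the PTC becomes the
#' stop codon) and the new 3'-UTR is the remainder of the coding sequence
#' plus the native 3'-UTR; all feature positions are re-anchored to the
#' PTC.
#'
#' @param allele A [ptc_allele()].
#' @return A one-row [mrna_catalog()].
#' @export
build_native_record <- function(allele) {
  k <- allele$ptc_codon_index
  if (k < 2L) stop("PTC at codon 1 leaves no P-site codon")
  upstream <- substr(allele$gene_cds, 1L, 3L * (k - 1L))
  downstream <- substr(allele$gene_cds, 3L * k + 1L, nchar(allele$gene_cds))
  seq <- paste0(upstream, allele$ptc_stop, downstream, allele$utr3_native)
  mrna_catalog(data.frame(
    transcript_id = allele$name, sequence = seq,
    utr5_len = 0L, cds_len = 3L * (k - 1L),
    utr3_len = 3L + nchar(downstream) + nchar(allele$utr3_native),
    stringsAsFactors = FALSE))
}

#' Specify a dual-reporter construct backbone
#'
#' @param upstream_gene RNA string of the stop-less upstream reporter CDS
#'   (length a multiple of 3, no in-frame stop codon).
#' @param downstream_gene RNA string of the start-less downstream reporter
#'   CDS.
#' @param utr3_trailer RNA string appended after the downstream gene
#'   (vector sequence up to the poly(A) signal); may be empty.
#' @param flank_codons Native codons kept on each side of the PTC
#'   (default 3).
#' @return List of class `reporter_spec`. The construct's 3'-UTR length
#'   (PTC to the end of the trailer) is constant across alleles.
#' @export
reporter_spec <- function(upstream_gene, downstream_gene, utr3_trailer = "",
                          flank_codons = 3L) {
  upstream_gene <- normalize_rna(upstream_gene)
  downstream_gene <- normalize_rna(downstream_gene)
  utr3_trailer <- normalize_rna(utr3_trailer)
  if (nchar(upstream_gene) %% 3L != 0L) {
    stop("upstream_gene length must be a multiple of 3")
  }
  if (any(seq_codons(upstream_gene) %in% STOP_CODONS)) {
    stop("upstream_gene must not contain an in-frame stop codon")
  }
  if (flank_codons < 0L) stop("flank_codons must be >= 0")
  structure(list(upstream_gene = upstream_gene,
                 downstream_gene = downstream_gene,
                 utr3_trailer = utr3_trailer,
                 flank_codons = as.integer(flank_codons),
                 utr3_reporter_len = 3L + 3L * flank_codons +
                   nchar(downstream_gene) + nchar(utr3_trailer)),
            class = "reporter_spec")
}

#' Build the reporter-embedded transcript record for a PTC allele
#'
#' The insert is `flank_codons` native codons upstream of the PTC, the PTC
#' itself, and `flank_codons` native codons downstream, placed between the
#' reporter genes. The record's CDS is the upstream gene plus the upstream
#' flank; everything from the PTC on is the 3'-UTR, whose length is
#' constant across alleles under one spec.
#'
#' @param allele A [ptc_allele()].
#' @param spec A [reporter_spec()].
#' @return A one-row [mrna_catalog()].
#' @export
build_reporter_record <- function(allele, spec) {
  k <- allele$ptc_codon_index
  fl <- spec$flank_codons
  if (k - fl < 1L || k + fl > allele$n_codons) {
    stop("allele needs at least ", fl, " codons on each side of the PTC")
  }
  up_flank <- substr(allele$gene_cds, 3L * (k - fl) - 2L, 3L * (k - 1L))
  down_flank <- substr(allele$gene_cds, 3L * k + 1L, 3L * (k + fl))
  seq <- paste0(spec$upstream_gene, up_flank, allele$ptc_stop, down_flank,
                spec$downstream_gene, spec$utr3_trailer)
  mrna_catalog(data.frame(
    transcript_id = allele$name, sequence = seq,
    utr5_len = 0L,
    cds_len = nchar(spec$upstream_gene) + 3L * fl,
    utr3_len = spec$utr3_reporter_len,
    stringsAsFactors = FALSE))
}

#' Predict readthrough of PTC alleles under a prediction scheme
#'
#' Builds the per-allele transcript records (native or reporter-embedded),
#' extracts the model's features, and predicts readthrough with a trained
#' forest. The feature table used is attached as the `"features"`
#' attribute for audit.
#'
#' @param model An `rt_model` (see [train_regressor()]).
#' @param alleles List of [ptc_allele()] objects.
#' @param scheme `"native"` or `"reporter"`.
#' @param spec A [reporter_spec()]; required for the reporter scheme.
#' @param schema Feature schema used for extraction; default
#'   [default_schema()].
#' @param seed Seed for the negative-control feature assignment
#'   (default 1).
#' @return Data frame `name`, `scheme`, `predicted_log2_re`.
#' @export
predict_alleles <- function(model, alleles, scheme = c("native", "reporter"),
                            spec = NULL, schema = default_schema(),
                            seed = 1L) {
  scheme <- match.arg(scheme)
  if (scheme == "reporter" && is.null(spec)) {
    stop("the reporter scheme requires a reporter_spec")
  }
  records <- lapply(alleles, function(a) {
    if (scheme == "native") build_native_record(a)
    else build_reporter_record(a, spec)
  })
  catalog <- do.call(rbind, lapply(records, as.data.frame))
  class(catalog) <- c("mrna_catalog", "data.frame")
  features <- extract_features(catalog, schema)
  if (nrow(features) < nrow(catalog)) {
    stop("feature extraction excluded allele(s): ",
         paste(attr(features, "excluded")$transcript_id, collapse = ", "))
  }
  features <- attach_negative_controls(features, seed)
  out <- data.frame(name = features$transcript_id, scheme = scheme,
                    predicted_log2_re = predict_readthrough(model, features),
                    stringsAsFactors = FALSE)
  attr(out, "features") <- features
  out
}

#' Compare two prediction schemes (or predictions vs measurements)
#'
#' Spearman correlation between paired per-allele values, with an optional
#' leave-k-out outlier report listing the k alleles whose joint removal
#' most increases the correlation (all subsets of size k are searched).
#'
#' @param pred_a,pred_b Paired numeric vectors; names (or the `name`
#'   column if data frames from [predict_alleles()]) identify alleles.
#' @param leave_k Size of the outlier subset to search (default 0 = off).
#' @return List `rho`, `p`, `n`, and when `leave_k > 0`: `outliers`
#'   (character), `rho_without`.
#' @export
compare_prediction_schemes <- function(pred_a, pred_b, leave_k = 0L) {
  get_vals <- function(x) {
    if (is.data.frame(x)) setNames(x$predicted_log2_re, x$name) else x
  }
  a <- get_vals(pred_a)
  b <- get_vals(pred_b)
  if (length(a) != length(b)) stop("paired vectors of equal length required")
  if (length(a) < 4) stop("need at least 4 paired alleles")
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  base <- correlate(unname(a), unname(b))
  out <- list(rho = base$rho, p = base$p, n = base$n)
  if (leave_k > 0L) {
    ids <- if (!is.null(names(a))) names(a) else as.character(seq_along(a))
    combos <- utils::combn(length(a), leave_k)
    rhos <- apply(combos, 2, function(drop_idx) {
      suppressWarnings(cor(a[-drop_idx], b[-drop_idx], method = "spearman"))
    })
    best <- which.max(rhos)
    out$outliers <- ids[combos[, best]]
    out$rho_without <- rhos[best]
  }
  out
}

#' Read PTC allele specifications from a TSV plus gene FASTA
#'
#' The allele table has columns `name`, `gene`, `ptc_codon_index`,
#' `ptc_stop`; the FASTA provides, per gene, entries `<gene>_cds` (coding
#' sequence including the native stop) and `<gene>_utr3`.
#'
#' @param alleles_path Allele TSV path.
#' @param genes_fasta Gene FASTA path.
#' @return List of [ptc_allele()] objects.
#' @export
read_alleles <- function(alleles_path, genes_fasta) {
  tab <- read_tsv_meta(alleles_path)
  required <- c("name", "gene", "ptc_codon_index", "ptc_stop")
  if (!all(required %in% names(tab))) {
    stop("allele table must have columns: ", paste(required, collapse = ", "))
  }
  seqs <- Biostrings::readBStringSet(genes_fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  lapply(seq_len(nrow(tab)), function(i) {
    gene <- tab$gene[i]
    cds_id <- paste0(gene, "_cds")
    utr_id <- paste0(gene, "_utr3")
    if (!cds_id %in% ids) stop("missing FASTA entry: ", cds_id)
    utr3 <- if (utr_id %in% ids) as.character(seqs[[match(utr_id, ids)]]) else ""
    ptc_allele(tab$name[i], as.character(seqs[[match(cds_id, ids)]]),
               utr3, tab$ptc_codon_index[i], tab$ptc_stop[i])
  })
}
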