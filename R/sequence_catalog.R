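# Transcript catalog ingestion and extension-region location.
#
# A catalog is a plain data.frame (class "mrna_catalog") with one row per
# spliced transcript: transcript_id, sequence (RNA, 5'->3'), utr5_len,
# cds_len (excluding the stop codon), utr3_len (including the stop codon).
# All internal coordinates are 0-based half-open; user-facing tables are
# 1-based inclusive.

#' Construct and validate an mRNA catalog
#'
#' Validates each row against the transcript invariants: region lengths sum
#' to the sequence length, the CDS is a nonempty multiple of 3, the codon
#' following the CDS is a stop codon, the 3'-UTR (which includes the stop
#' codon) is at least 3 nt, and the sequence uses the A/C/G/U/N alphabet.
#' Rows failing any invariant are dropped and reported in the `"excluded"`
#' attribute as a data.frame of `transcript_id`, `reason`.
#'
#' @param df Data frame with columns `transcript_id`, `sequence`,
#'   `utr5_len`, `cds_len`, `utr3_len`. T bases are converted to U.
#' @return Data frame of class `mrna_catalog` containing the valid rows.
#' @export
mrna_catalog <- function(df) {
  required <- c("transcript_id", "sequence", "utr5_len", "cds_len", "utr3_len")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("catalog is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  df$sequence <- normalize_rna(df$sequence)
  for (col in c("utr5_len", "cds_len", "utr3_len")) {
    df[[col]] <- as.integer(df[[col]])
  }
  reasons <- validate_mrna_rows(df)
  bad <- reasons != ""
  excluded <- data.frame(transcript_id = df$transcript_id[bad],
                         reason = reasons[bad], stringsAsFactors = FALSE)
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  if (anyDuplicated(out$transcript_id)) {
    stop("duplicated transcript_id in catalog")
  }
  class(out) <- c("mrna_catalog", "data.frame")
  attr(out, "excluded") <- excluded
  out
}

# One reason string per row; "" means the row satisfies all invariants.
validate_mrna_rows <- function(df) {
  n <- nrow(df)
  reason <- character(n)
  len <- nchar(df$sequence)
  set <- function(bad, msg) reason[bad & reason == ""] <<- msg
  set(!is_valid_rna(df$sequence), "invalid character in sequence")
  set(is.na(df$utr5_len) | is.na(df$cds_len) | is.na(df$utr3_len),
      "missing region length")
  ok <- reason == ""
  set(ok & df$utr5_len + df$cds_len + df$utr3_len != len,
      "region lengths do not sum to sequence length")
  set(ok & df$cds_len %% 3L != 0L, "CDS not multiple of 3")
  set(ok & df$cds_len < 3L, "CDS shorter than 3 nt")
  set(ok & df$utr3_len < 3L, "3'-UTR shorter than stop codon")
  ok <- reason == ""
  stop_cod <- substr(df$sequence, df$utr5_len + df$cds_len + 1L,
                     df$utr5_len + df$cds_len + 3L)
  set(ok & !(stop_cod %in% STOP_CODONS), "no stop codon at CDS end")
  reason
}

#' Read a transcript catalog from FASTA plus a region-length table
#'
#' The regions table is tab-separated with header
#' `transcript_id  utr5_len  cds_len  utr3_len`; `utr3_len` includes the
#' stop codon. DNA input is transcribed to RNA. Identifiers present in only
#' one of the two files, and records violating the transcript invariants,
#' are excluded (not fatal) and reported in the `"excluded"` attribute.
#'
#' @param fasta_path FASTA file of spliced transcript sequences.
#' @param regions_path Region-length TSV.
#' @return An [mrna_catalog()] data frame.
#' @export
read_catalog <- function(fasta_path, regions_path) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  if (!file.exists(regions_path)) stop("regions file not found: ", regions_path)
  seqs <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  regions <- read_tsv_meta(regions_path)
  required <- c("transcript_id", "utr5_len", "cds_len", "utr3_len")
  if (!all(required %in% names(regions))) {
    stop("regions table must have columns: ", paste(required, collapse = ", "))
  }
  for (col in c("utr5_len", "cds_len", "utr3_len")) {
    v <- suppressWarnings(as.integer(regions[[col]]))
    bad <- which(is.na(v) & !is.na(regions[[col]]))
    if (length(bad)) {
      stop("malformed regions row at line ", bad[1] + 1L,
           ": non-integer ", col)
    }
    regions[[col]] <- v
  }
  only_fasta <- setdiff(ids, regions$transcript_id)
  only_regions <- setdiff(regions$transcript_id, ids)
  common <- intersect(ids, regions$transcript_id)
  regions <- regions[match(common, regions$transcript_id), , drop = FALSE]
  df <- data.frame(transcript_id = common,
                   sequence = as.character(seqs[match(common, ids)]),
                   utr5_len = regions$utr5_len,
                   cds_len = regions$cds_len,
                   utr3_len = regions$utr3_len,
                   stringsAsFactors = FALSE)
  cat_out <- mrna_catalog(df)
  extra <- data.frame(
    transcript_id = c(only_fasta, only_regions),
    reason = c(rep("missing from regions table", length(only_fasta)),
               rep("missing from FASTA", length(only_regions))),
    stringsAsFactors = FALSE)
  excluded <- rbind(extra, attr(cat_out, "excluded"))
  attr(cat_out, "excluded") <- excluded
  if (nrow(excluded)) {
    message(nrow(excluded), " record(s) excluded from catalog")
  }
  cat_out
}

#' Write a catalog back to FASTA plus regions TSV
#'
#' @param catalog An [mrna_catalog()].
#' @param fasta_path,regions_path Output paths.
#' @param meta Optional named metadata written into the regions TSV header.
#' @return Invisibly, the two paths.
#' @export
write_catalog <- function(catalog, fasta_path, regions_path, meta = character()) {
  seqs <- Biostrings::BStringSet(setNames(catalog$sequence,
                                          catalog$transcript_id))
  Biostrings::writeXStringSet(seqs, fasta_path, width = 80L)
  write_tsv_meta(catalog[, c("transcript_id", "utr5_len", "cds_len",
                             "utr3_len")],
                 regions_path, meta = meta)
  invisible(c(fasta_path, regions_path))
}

#' Locate the in-frame extension region downstream of the stop codon
#'
#' The extension region runs from the first nucleotide after the canonical
#' stop codon to the next in-frame stop codon (which is itself excluded).
#' When no in-frame downstream stop exists, the region extends to the last
#' complete in-frame codon boundary of the transcript and the record is
#' flagged via `has_downstream_stop = FALSE`.
#'
#' @param catalog An [mrna_catalog()] (or any data frame with the catalog
#'   columns).
#' @return Data frame with one row per transcript: `transcript_id`,
#'   `start`, `end` (0-based, half-open), `length` (nt, a multiple of 3),
#'   and `has_downstream_stop`.
#' @export
find_extension_region <- function(catalog) {
  n <- nrow(catalog)
  start <- catalog$utr5_len + catalog$cds_len + 3L
  end <- integer(n)
  has_stop <- logical(n)
  seq_len_all <- nchar(catalog$sequence)
  for (i in seq_len(n)) {
    tail_len <- seq_len_all[i] - start[i]
    if (tail_len < 3L) {
      end[i] <- start[i]
      has_stop[i] <- FALSE
      next
    }
    tail_seq <- substr(catalog$sequence[i], start[i] + 1L, seq_len_all[i])
    codons <- seq_codons(tail_seq)
    hit <- match(TRUE, codons %in% STOP_CODONS)
    if (is.na(hit)) {
      end[i] <- start[i] + 3L * length(codons)
      has_stop[i] <- FALSE
    } else {
      end[i] <- start[i] + 3L * (hit - 1L)
      has_stop[i] <- TRUE
    }
  }
  data.frame(transcript_id = catalog$transcript_id,
             start = start, end = end, length = end - start,
             has_downstream_stop = has_stop,
             stringsAsFactors = FALSE)
}
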