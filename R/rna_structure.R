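# Lowest local minimum-free-energy structure per 3'-UTR.
#
# Two backends:
#   "builtin"     - span-limited dynamic program over a simple base-pair
#                   energy model (GC -3, AU -2, GU -1 kcal/mol, hairpin
#                   loop >= 3). Deterministic and dependency-free; it does
#                   not reproduce nearest-neighbor thermodynamics and is
#                   intended for structure-vs-length-vs-readthrough
#                   correlation analyses, not for energy accuracy.
#   "viennalocal" - parses the output of an external local-folding tool
#                   (RNALfold) when it is on the PATH.
# In both backends a sequence with no favorable structure is assigned an
# MFE of zero.

#' Lowest local MFE of an RNA sequence
#'
#' @param sequence RNA string (A/C/G/U; N allowed but never pairs).
#' @param window Maximum base-pair span in nt (default 150).
#' @param backend `"builtin"` (default) or `"viennalocal"`.
#' @return List: `lowest_mfe` (kcal/mol, `<= 0`; 0 when no structure),
#'   `n_structures`, `backend`.
#' @export
lowest_local_mfe <- function(sequence, window = 150L,
                             backend = c("builtin", "viennalocal")) {
  backend <- match.arg(backend)
  sequence <- normalize_rna(sequence)
  if (!is_valid_rna(sequence)) {
    stop("sequence contains non-RNA characters")
  }
  if (window < 3) stop("window must be >= 3")
  if (backend == "builtin") {
    codes <- rna_codes(sequence)
    mfe <- .fold_lowest_mfe(codes, as.integer(window))
    list(lowest_mfe = mfe, n_structures = if (mfe < 0) 1L else 0L,
         backend = "builtin")
  } else {
    fold_viennalocal(sequence, window)
  }
}

rna_codes <- function(sequence) {
  m <- match(strsplit(sequence, "", fixed = TRUE)[[1]], RNA_BASES)
  m[is.na(m)] <- 0L
  m - 1L  # A=0, C=1, G=2, U=3, N=-1
}

fold_viennalocal <- function(sequence, window) {
  exe <- Sys.which("RNALfold")
  if (exe == "") {
    stop("backend 'viennalocal' requires RNALfold on the PATH; ",
         "install the ViennaRNA package or use backend = 'builtin'")
  }
  out <- system2(exe, args = c("-L", as.character(window)),
                 input = sequence, stdout = TRUE, stderr = FALSE)
  # local-structure lines look like: ".((....)). ( -1.20)  3"
  struct_lines <- out[grepl("^[.()]+ ", out)]
  hits <- regmatches(struct_lines,
                     regexpr("\\(\\s*-?[0-9]+\\.[0-9]+\\)", struct_lines))
  energies <- as.numeric(gsub("[() ]", "", hits))
  energies <- energies[is.finite(energies) & energies < 0]
  if (!length(energies)) {
    list(lowest_mfe = 0, n_structures = 0L, backend = "viennalocal")
  } else {
    list(lowest_mfe = min(energies), n_structures = length(energies),
         backend = "viennalocal")
  }
}

#' Fold every 3'-UTR in a catalog
#'
#' Extracts each transcript's 3'-UTR (including the stop codon by default,
#' consistent with the catalog's region definition) and reports its lowest
#' local MFE.
#'
#' @param catalog An [mrna_catalog()].
#' @param window Maximum base-pair span (default 150 nt).
#' @param backend See [lowest_local_mfe()].
#' @param include_stop Include the stop codon in the folded sequence
#'   (default `TRUE`).
#' @return Data frame: `transcript_id`, `lowest_mfe`, `n_structures`,
#'   `backend`.
#' @export
fold_utr3 <- function(catalog, window = 150L, backend = "builtin",
                      include_stop = TRUE) {
  seq_len_all <- nchar(catalog$sequence)
  from <- seq_len_all - catalog$utr3_len + 1L + if (include_stop) 0L else 3L
  utrs <- substr(catalog$sequence, from, seq_len_all)
  res <- lapply(utrs, lowest_local_mfe, window = window, backend = backend)
  data.frame(transcript_id = catalog$transcript_id,
             lowest_mfe = vapply(res, `[[`, numeric(1), "lowest_mfe"),
             n_structures = vapply(res, `[[`, integer(1), "n_structures"),
             backend = vapply(res, `[[`, character(1), "backend"),
             stringsAsFactors = FALSE)
}
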