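# Shared low-level helpers: RNA alphabet handling, translation, seeded
# substreams, and metadata-carrying TSV input/output.

RNA_BASES <- c("A", "C", "G", "U")
STOP_CODONS <- c("UAA", "UAG", "UGA")

.rt_cache <- new.env(parent = emptyenv())

# Genetic code keyed by RNA codons, "*" for stops.
rt_genetic_code <- function() {
  if (is.null(.rt_cache$gc)) {
    gc <- Biostrings::GENETIC_CODE
    names(gc) <- chartr("T", "U", names(gc))
    .rt_cache$gc <- gc
  }
  .rt_cache$gc
}

sense_codons <- function() setdiff(names(rt_genetic_code()), STOP_CODONS)

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and converts T to U. Characters outside A/C/G/U/N are left in
#' place; use [is_valid_rna()] to detect them.
#'
#' @param x Character vector of nucleotide strings (DNA or RNA).
#' @return Character vector in the RNA alphabet.
#' @export
normalize_rna <- function(x) {
  chartr("T", "U", toupper(x))
}

is_valid_rna <- function(x, allow_n = TRUE) {
  pattern <- if (allow_n) "^[ACGUN]*$" else "^[ACGU]*$"
  grepl(pattern, x)
}

# Split a sequence into consecutive codons; trailing partial codon dropped.
seq_codons <- function(s) {
  n <- nchar(s)
  if (n < 3L) return(character(0))
  starts <- seq.int(1L, n - 2L, by = 3L)
  substring(s, starts, starts + 2L)
}

# Translate RNA codons to one-letter amino acids ("*" for stop, NA for
# codons containing N or of wrong length).
translate_codons <- function(codons) {
  unname(rt_genetic_code()[codons])
}

# Deterministic per-module seed derivation so that one top-level seed drives
# all randomness through named substreams. Result is always in [1, 2^31 - 2].
substream_seed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  chars <- utf8ToInt(name)
  h <- sum(chars * seq_along(chars)) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483646) + 1L
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_rt_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Write a table as TSV with `#`-prefixed metadata header lines
#'
#' @param df Data frame to write.
#' @param path Output path.
#' @param meta Named character vector written as `# name: value` lines.
#' @return `path`, invisibly.
#' @export
write_tsv_meta <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(meta)) {
    writeLines(sprintf("# %s: %s", names(meta), as.character(meta)), con)
  }
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv_meta()]
#'
#' @param path Input path.
#' @return Data frame with attribute `"meta"` holding the header lines.
#' @export
read_tsv_meta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 200L)
  n_meta <- match(FALSE, startsWith(lines, "#"), nomatch = length(lines) + 1L) - 1L
  df <- read.delim(path, skip = n_meta, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  meta <- character()
  if (n_meta > 0L) {
    raw <- sub("^#\\s*", "", lines[seq_len(n_meta)])
    keys <- sub(":.*$", "", raw)
    vals <- sub("^[^:]*:\\s*", "", raw)
    meta <- setNames(vals, keys)
  }
  attr(df, "meta") <- meta
  df
}
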