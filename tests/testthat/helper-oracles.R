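# Independent oracles used by the test suite. These deliberately share no
# code with the package implementation.

# Brute-force in-frame scan for the extension region: walk the sequence
# character by character in codon steps starting right after the stop.
oracle_extension <- function(sequence, utr5_len, cds_len) {
  start <- utr5_len + cds_len + 3L  # 0-based
  pos <- start
  n <- nchar(sequence)
  repeat {
    if (pos + 3L > n) break
    codon <- substr(sequence, pos + 1L, pos + 3L)
    if (codon %in% c("UAA", "UAG", "UGA")) {
      return(list(start = start, end = pos, has_stop = TRUE))
    }
    pos <- pos + 3L
  }
  list(start = start, end = pos, has_stop = FALSE)
}

# All-pairs concordance AUROC with half credit for ties.
oracle_auroc <- function(scores, labels) {
  hi <- scores[labels == "high"]
  lo <- scores[labels == "low"]
  total <- 0
  for (a in hi) {
    for (b in lo) {
      total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
    }
  }
  total / (length(hi) * length(lo))
}

# Exact two-sided Wilcoxon rank-sum p-value by exhaustive enumeration of
# all assignments of the pooled ranks to the first group (no ties).
oracle_wilcoxon_p <- function(x, y) {
  m <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  combos <- utils::combn(length(pooled), m)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(p, 1)
}

# Base-pair energies of the builtin folding model (duplicated on purpose).
oracle_pair_e <- function(a, b) {
  pr <- paste0(sort(c(a, b)), collapse = "")
  switch(pr, "CG" = -3, "AU" = -2, "GU" = -1, NA_real_)
}

# Minimum energy over all nested structures within [a, b] (1-based,
# inclusive), explored by plain recursion without memoization.
oracle_best_inside <- function(bases, a, b) {
  if (b - a < 4L) return(0)
  best <- oracle_best_inside(bases, a + 1L, b)  # a unpaired
  for (k in seq.int(a + 4L, b)) {
    e <- oracle_pair_e(bases[a], bases[k])
    if (!is.na(e)) {
      cand <- e + oracle_best_inside(bases, a + 1L, k - 1L) +
        oracle_best_inside(bases, k + 1L, b)
      if (cand < best) best <- cand
    }
  }
  min(best, 0)
}

# Lowest energy over single locally closed structures (one outer pair of
# span <= window enclosing any nested structure).
oracle_lowest_mfe <- function(sequence, window) {
  bases <- strsplit(sequence, "", fixed = TRUE)[[1]]
  n <- length(bases)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i < 4L || j - i + 1L > window) next
      e <- oracle_pair_e(bases[i], bases[j])
      if (is.na(e)) next
      cand <- e + oracle_best_inside(bases, i + 1L, j - 1L)
      if (cand < best) best <- cand
    }
  }
  best
}

# Random valid transcript records built independently of the package's
# simulator: uniform random bases with a planted stop codon, optional
# forced downstream stop structure.
random_records <- function(n, seed) {
  set.seed(seed)
  stops <- c("UAA", "UAG", "UGA")
  bases <- c("A", "C", "G", "U")
  sense <- setdiff(
    apply(expand.grid(bases, bases, bases), 1, paste, collapse = ""),
    stops)
  data.frame(
    transcript_id = sprintf("RND%05d", seq_len(n)),
    sequence = vapply(seq_len(n), function(i) {
      utr5 <- paste(sample(bases, sample(3:40, 1), TRUE), collapse = "")
      ncod <- sample(2:60, 1)
      cds <- paste(c("AUG", sample(sense, ncod - 1L, TRUE)), collapse = "")
      tail_nt <- paste(sample(bases, sample(0:120, 1), TRUE), collapse = "")
      paste0(utr5, cds, sample(stops, 1), tail_nt)
    }, character(1)),
    stringsAsFactors = FALSE
  ) -> df
  # region lengths recovered from the construction
  df$utr5_len <- NA_integer_
  df$cds_len <- NA_integer_
  df$utr3_len <- NA_integer_
  df
}

# Construct a catalog data frame with known region lengths.
build_record <- function(id, utr5, cds, stop, utr3_tail) {
  data.frame(transcript_id = id,
             sequence = paste0(utr5, cds, stop, utr3_tail),
             utr5_len = nchar(utr5), cds_len = nchar(cds),
             utr3_len = 3L + nchar(utr3_tail),
             stringsAsFactors = FALSE)
}

# Random valid catalogs (known lengths) for property tests.
random_catalog <- function(n, seed, min_cds_codons = 2L,
                           max_tail = 120L) {
  set.seed(seed)
  stops <- c("UAA", "UAG", "UGA")
  bases <- c("A", "C", "G", "U")
  sense <- setdiff(
    apply(expand.grid(bases, bases, bases), 1, paste, collapse = ""),
    stops)
  rows <- lapply(seq_len(n), function(i) {
    utr5 <- paste(sample(bases, sample(3:40, 1), TRUE), collapse = "")
    ncod <- sample(min_cds_codons:60, 1)
    cds <- paste(c("AUG", sample(sense, ncod - 1L, TRUE)), collapse = "")
    tail_nt <- paste(sample(bases, sample(0:max_tail, 1), TRUE),
                     collapse = "")
    build_record(sprintf("RND%05d", i), utr5, cds, sample(stops, 1),
                 tail_nt)
  })
  mrna_catalog(do.call(rbind, rows))
}
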