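# Synthetic data with planted, configurable context effects.
#
# The generator emulates the statistical structure of a transcriptome-wide
# readthrough dataset: a catalog with realistic stop-codon / nt +4 usage,
# log2 readthrough efficiency driven by planted effects of the stop codon
# (UGA > UAG > UAA), nt +4 (C > U > A/G), 3'-UTR length (positive,
# log10 scale), and a sparse set of P-site codons, plus Gaussian noise;
# negative-binomial region counts over the quantification pipeline; and
# replicate dual-luciferase plates with multiplicative noise.

#' Configuration for the synthetic readthrough generator
#'
#' Defaults encode the planted ground truth used throughout the package's
#' validation: stop-codon frequencies 0.49/0.27/0.24 (UGA/UAG/UAA),
#' per-stop nt +4 frequencies with purines common and U depleted (and
#' mild UGA-G and UAA-A attraction), log-normal region lengths, effect
#' sizes `beta_stop` (UGA +0.6, UAG -0.2, UAA -0.4 log2 units),
#' `beta_nt4` (C +0.3, U +0.1, A/G -0.2), `beta_len` +0.75 per log10(nt)
#' of 3'-UTR length, sparse `beta_psite` (UGG +0.15, AAG -0.15,
#' GCU -0.10), and residual SD `sigma = 1`.
#'
#' @param n_transcripts Catalog size.
#' @param stop_freqs Named probabilities over UGA/UAG/UAA.
#' @param nt4_freqs 3 x 4 matrix (rows UGA/UAG/UAA, columns A/C/G/U) of
#'   nt +4 probabilities per stop codon.
#' @param utr5_meanlog,utr5_sdlog Log-normal parameters of 5'-UTR length.
#' @param cds_meanlog_codons,cds_sdlog Log-normal parameters of CDS length
#'   in codons (minimum 33 codons).
#' @param utr3_meanlog,utr3_sdlog Log-normal parameters of the 3'-UTR tail
#'   beyond the stop codon (minimum 9 nt).
#' @param intercept Baseline log2 readthrough efficiency.
#' @param beta_stop,beta_nt4,beta_psite Named effect sizes (log2 units).
#' @param beta_len Effect per log10(nt) of 3'-UTR length.
#' @param sigma Residual SD of log2 readthrough efficiency.
#' @param coverage Expected CDS reads per kb in the count model.
#' @param dispersion Negative-binomial size parameter (`Inf` = Poisson).
#' @param ext_multiplier Scales the extension-region count mean (0 turns
#'   extension signal off entirely).
#' @param seed Integer seed; all generator randomness derives from it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 3000L,
                       stop_freqs = c(UGA = 0.49, UAG = 0.27, UAA = 0.24),
                       nt4_freqs = rbind(
                         UGA = c(A = 0.27, C = 0.24, G = 0.35, U = 0.14),
                         UAG = c(A = 0.30, C = 0.27, G = 0.28, U = 0.15),
                         UAA = c(A = 0.36, C = 0.24, G = 0.26, U = 0.14)),
                       utr5_meanlog = log(150), utr5_sdlog = 0.5,
                       cds_meanlog_codons = log(400), cds_sdlog = 0.4,
                       utr3_meanlog = 6, utr3_sdlog = 1.1,
                       intercept = -4.5,
                       beta_stop = c(UGA = 0.6, UAG = -0.2, UAA = -0.4),
                       beta_nt4 = c(A = -0.2, C = 0.3, G = -0.2, U = 0.1),
                       beta_len = 0.75,
                       beta_psite = c(UGG = 0.15, AAG = -0.15, GCU = -0.10),
                       sigma = 1,
                       coverage = 1000,
                       dispersion = 5,
                       ext_multiplier = 1,
                       seed = 1L) {
  stopifnot(abs(sum(stop_freqs) - 1) < 1e-8,
            all(abs(rowSums(nt4_freqs) - 1) < 1e-8),
            sigma >= 0, dispersion > 0, n_transcripts >= 1)
  structure(as.list(environment()), class = "sim_config")
}

# Paste sampled elements into per-transcript strings (zero-length chunks
# preserved as "").
paste_chunks <- function(pool, lens) {
  idx <- factor(rep.int(seq_along(lens), lens), levels = seq_along(lens))
  unname(vapply(split(pool, idx), paste, character(1), collapse = ""))
}

#' Simulate a transcript catalog with planted readthrough effects
#'
#' Sequences are drawn uniformly over bases (UTRs) and sense codons (CDS)
#' except at the planted context positions: the stop codon, nt +4, and the
#' P-site codon follow the configured frequencies. The true log2
#' readthrough efficiency of each transcript is
#' `intercept + beta_stop + beta_nt4 + beta_len * log10(utr3_len) +
#' beta_psite + N(0, sigma)` and is returned in the `true_log2_re`
#' column.
#'
#' @param config A [sim_config()].
#' @return An [mrna_catalog()] with an extra `true_log2_re` column.
#' @export
simulate_catalog <- function(config) {
  n <- config$n_transcripts
  with_rt_seed(substream_seed(config$seed, "catalog"), {
    utr5_len <- pmax(3L, as.integer(round(rlnorm(n, config$utr5_meanlog,
                                                 config$utr5_sdlog))))
    ncod <- pmax(33L, as.integer(round(rlnorm(n, config$cds_meanlog_codons,
                                              config$cds_sdlog))))
    tail_len <- pmax(9L, as.integer(round(rlnorm(n, config$utr3_meanlog,
                                                 config$utr3_sdlog))))
    utr3_len <- tail_len + 3L
    stops <- sample(names(config$stop_freqs), n, replace = TRUE,
                    prob = config$stop_freqs)
    nt4 <- character(n)
    for (s in rownames(config$nt4_freqs)) {
      idx <- which(stops == s)
      nt4[idx] <- sample(colnames(config$nt4_freqs), length(idx),
                         replace = TRUE, prob = config$nt4_freqs[s, ])
    }
    sense <- sense_codons()
    psite <- sample(sense, n, replace = TRUE)
    # CDS: AUG + (ncod - 2) uniform sense codons + P-site codon
    mid <- paste_chunks(sample(sense, sum(ncod - 2L), replace = TRUE),
                        ncod - 2L)
    cds <- paste0("AUG", mid, psite)
    utr5 <- paste_chunks(sample(RNA_BASES, sum(utr5_len), replace = TRUE),
                         utr5_len)
    utr3_rest <- paste_chunks(sample(RNA_BASES, sum(tail_len - 1L),
                                     replace = TRUE), tail_len - 1L)
    sequence <- paste0(utr5, cds, stops, nt4, utr3_rest)
    bs <- config$beta_stop[stops]
    bn <- config$beta_nt4[nt4]
    bp <- config$beta_psite[psite]
    bp[is.na(bp)] <- 0
    truth <- config$intercept + unname(bs) + unname(bn) +
      config$beta_len * log10(utr3_len) + unname(bp) +
      rnorm(n, 0, config$sigma)
    df <- data.frame(
      transcript_id = sprintf("TX%05d", seq_len(n)),
      sequence = sequence,
      utr5_len = utr5_len, cds_len = 3L * ncod, utr3_len = utr3_len,
      true_log2_re = truth, stringsAsFactors = FALSE)
  })
  out <- mrna_catalog(df)
  if (nrow(attr(out, "excluded"))) {
    stop("internal error: simulated records violated catalog invariants")
  }
  out
}

#' Simulate region read counts for a catalog
#'
#' CDS counts are negative binomial with mean
#' `coverage * cds_len / 1000`; extension-region counts have mean
#' `coverage * 2^true_log2_re * ext_len / 1000 * ext_multiplier`, so the
#' expected RPKM ratio equals the planted readthrough efficiency. The
#' library size is the total of all simulated counts.
#'
#' @param catalog Output of [simulate_catalog()] (must carry
#'   `true_log2_re`).
#' @param config The same [sim_config()].
#' @return Data frame: `transcript_id`, `cds_count`, `ext_count`,
#'   `cds_len`, `ext_len`, `library_size`.
#' @export
simulate_counts <- function(catalog, config) {
  if (!"true_log2_re" %in% names(catalog)) {
    stop("catalog must carry true_log2_re (from simulate_catalog)")
  }
  ext <- find_extension_region(catalog)
  n <- nrow(catalog)
  mu_cds <- config$coverage * catalog$cds_len / 1000
  mu_ext <- config$coverage * 2^catalog$true_log2_re * ext$length / 1000 *
    config$ext_multiplier
  with_rt_seed(substream_seed(config$seed, "counts"), {
    draw <- function(mu) {
      if (is.infinite(config$dispersion)) rpois(n, mu)
      else rnbinom(n, mu = mu, size = config$dispersion)
    }
    cds_count <- draw(mu_cds)
    ext_count <- ifelse(mu_ext > 0, draw(mu_ext), 0L)
  })
  data.frame(transcript_id = catalog$transcript_id,
             cds_count = cds_count, ext_count = as.integer(ext_count),
             cds_len = catalog$cds_len, ext_len = ext$length,
             library_size = sum(cds_count) + sum(ext_count),
             stringsAsFactors = FALSE)
}

#' Simulate PTC alleles with random gene backgrounds
#'
#' Each allele gets its own random gene (uniform sense codons, a native
#' stop, and a random 3'-UTR), a PTC position away from both gene ends,
#' and a stop codon drawn from the configured frequencies.
#'
#' @param n_alleles Number of alleles.
#' @param config A [sim_config()] (stop frequencies and seed are used).
#' @param gene_codons Gene length in codons including the native stop.
#' @param utr3_len Native 3'-UTR length in nt.
#' @param flank_min Minimum distance (codons) of the PTC from either gene
#'   end (default 5, enough for 3-codon reporter flanks).
#' @return List of [ptc_allele()] objects.
#' @export
simulate_alleles <- function(n_alleles, config = sim_config(),
                             gene_codons = 500L, utr3_len = 600L,
                             flank_min = 5L) {
  sense <- sense_codons()
  with_rt_seed(substream_seed(config$seed, "alleles"), {
    lapply(seq_len(n_alleles), function(i) {
      cds <- paste0("AUG",
                    paste(sample(sense, gene_codons - 2L, replace = TRUE),
                          collapse = ""),
                    "UAA")
      utr3 <- paste(sample(RNA_BASES, utr3_len, replace = TRUE),
                    collapse = "")
      k <- sample(seq.int(flank_min + 1L, gene_codons - flank_min - 1L), 1L)
      stop_c <- sample(names(config$stop_freqs), 1L,
                       prob = config$stop_freqs)
      ptc_allele(sprintf("ALLELE%03d-%s", i, stop_c), cds, utr3, k, stop_c)
    })
  })
}

#' Synthetic dual-reporter backbone
#'
#' A randomly generated stand-in for a dual-luciferase construct: a
#' stop-less upstream ORF, a downstream ORF, and a vector trailer, with
#' sizes comparable to Renilla (~311 codons) and firefly (~550 codons)
#' luciferase. Purely synthetic sequence; no real reporter sequence is
#' included.
#'
#' @param seed Integer seed.
#' @param upstream_codons,downstream_codons,trailer_len Construct sizes.
#' @param flank_codons Native codons kept around the PTC (default 3).
#' @return A [reporter_spec()].
#' @export
synth_reporter_spec <- function(seed = 1L, upstream_codons = 311L,
                                downstream_codons = 550L, trailer_len = 200L,
                                flank_codons = 3L) {
  sense <- sense_codons()
  with_rt_seed(substream_seed(seed, "reporter"), {
    up <- paste0("AUG", paste(sample(sense, upstream_codons - 1L,
                                     replace = TRUE), collapse = ""))
    down <- paste(sample(sense, downstream_codons, replace = TRUE),
                  collapse = "")
    trailer <- paste(sample(RNA_BASES, trailer_len, replace = TRUE),
                     collapse = "")
  })
  reporter_spec(up, down, trailer, flank_codons = flank_codons)
}

#' Simulate dual-luciferase plates with known readthrough truth
#'
#' Renilla signals are log-normal around a plate constant; firefly equals
#' `renilla * truth / 100` times multiplicative log-normal noise.
#' Optionally, planted outlier wells have their firefly signal multiplied
#' by `outlier_fold`.
#'
#' @param truth Data frame `allele`, `condition`, `readthrough_pct`
#'   (true percent readthrough per condition; must be positive).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0.1).
#' @param n_experiments Independent experiments per allele (default 6).
#' @param n_wells Wells per condition per experiment (default 4).
#' @param outlier_rate Fraction of wells planted as outliers (default 0).
#' @param outlier_fold Fold displacement of outlier wells (default 5).
#' @param renilla_mean,renilla_cv Plate-level Renilla signal model.
#' @param seed Integer seed.
#' @return Plate data frame (`allele`, `experiment`, `condition`, `well`,
#'   `firefly`, `renilla`) with attribute `"outlier_wells"`.
#' @export
simulate_dualluc <- function(truth, noise_cv = 0.1, n_experiments = 6L,
                             n_wells = 4L, outlier_rate = 0,
                             outlier_fold = 5, renilla_mean = 1e5,
                             renilla_cv = 0.3, seed = 1L) {
  stopifnot(all(truth$readthrough_pct > 0))
  sdlog_noise <- sqrt(log(1 + noise_cv^2))
  sdlog_ren <- sqrt(log(1 + renilla_cv^2))
  rows <- vector("list", nrow(truth) * n_experiments)
  ri <- 0L
  with_rt_seed(substream_seed(seed, "dualluc"), {
    for (i in seq_len(nrow(truth))) {
      for (e in seq_len(n_experiments)) {
        renilla <- rlnorm(n_wells, log(renilla_mean) - sdlog_ren^2 / 2,
                          sdlog_ren)
        noise <- rlnorm(n_wells, -sdlog_noise^2 / 2, sdlog_noise)
        firefly <- renilla * truth$readthrough_pct[i] / 100 * noise
        is_out <- runif(n_wells) < outlier_rate
        firefly[is_out] <- firefly[is_out] * outlier_fold
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          allele = truth$allele[i], experiment = e,
          condition = truth$condition[i], well = seq_len(n_wells),
          firefly = firefly, renilla = renilla, outlier = is_out,
          stringsAsFactors = FALSE)
      }
    }
  })
  out <- do.call(rbind, rows)
  outliers <- out[out$outlier, c("allele", "experiment", "condition", "well")]
  out$outlier <- NULL
  rownames(out) <- NULL
  attr(out, "outlier_wells") <- outliers
  out
}
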