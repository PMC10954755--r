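# Stop-codon context feature engineering.
#
# The full schema ("full-v1") carries 75 mRNA features plus 2 randomized
# negative controls:
#   context (21): stop codon, nt -1..-9, nt +4..+12, P-site codon,
#     P-site amino acid.
#   tunnel (10): aggregate physicochemical properties of the last 30
#     encoded residues (the nascent peptide segment spanning the exit
#     tunnel when the stop codon is decoded).
#   other (44): nt -10..-30, nt +13..+30, 5'-UTR/CDS/3'-UTR lengths,
#     E-site codon and amino acid.
#   negative_control (2): nc_number (uniform 1..100), nc_letter
#     (uniform A/C/G/U).
# Stop codon bases are numbered +1..+3, so nt +4 is the first 3'-UTR base
# after the stop; nt -1 is the last CDS base.

KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
                   Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
                   L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
                   S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
AA_POSITIVE <- c("K", "R", "H")
AA_NEGATIVE <- c("D", "E")
AA_AROMATIC <- c("F", "W", "Y")
AA_POLAR <- c("S", "T", "N", "Q", "C", "Y")
AA_SMALL <- c("A", "G", "S", "C", "T", "P")

TUNNEL_FEATURES <- c("tun_frac_positive", "tun_frac_negative",
                     "tun_net_charge", "tun_mean_hydropathy",
                     "tun_frac_aromatic", "tun_frac_proline",
                     "tun_frac_glycine", "tun_frac_polar",
                     "tun_frac_small", "tun_cterm_charge")
TUNNEL_WINDOW <- 30L

#' Construct a feature schema
#'
#' @param name Schema name.
#' @param feature_names Ordered character vector of unique feature names.
#' @param groups Named character vector mapping each feature to one of
#'   `"context"`, `"tunnel"`, `"other"`, `"negative_control"`.
#' @return List of class `feature_schema`.
#' @export
feature_schema <- function(name, feature_names, groups) {
  if (anyDuplicated(feature_names)) stop("duplicated feature names")
  if (!all(feature_names %in% names(groups))) {
    stop("every feature needs a group tag")
  }
  groups <- groups[feature_names]
  ok <- groups %in% c("context", "tunnel", "other", "negative_control")
  if (!all(ok)) stop("unknown group tag: ", paste(unique(groups[!ok]), collapse = ", "))
  structure(list(name = name, feature_names = feature_names,
                 groups = groups),
            class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  cat("feature_schema '", x$name, "': ", length(x$feature_names),
      " features (", paste(sprintf("%s=%d", names(table(x$groups)),
                                   table(x$groups)), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' The full default feature schema
#'
#' Returns schema `"full-v1"`: 75 mRNA features (21 context, 10 exit
#' tunnel, 44 other) plus the 2 negative-control features.
#'
#' @return A [feature_schema()].
#' @export
default_schema <- function() {
  context <- c("stop_codon", paste0("nt_m", 1:9), paste0("nt_p", 4:12),
               "p_site_codon", "p_site_aa")
  tunnel <- TUNNEL_FEATURES
  other <- c(paste0("nt_m", 10:30), paste0("nt_p", 13:30),
             "utr5_len", "cds_len", "utr3_len",
             "e_site_codon", "e_site_aa")
  nc <- c("nc_number", "nc_letter")
  feats <- c(context, tunnel, other, nc)
  groups <- setNames(c(rep("context", length(context)),
                       rep("tunnel", length(tunnel)),
                       rep("other", length(other)),
                       rep("negative_control", length(nc))), feats)
  feature_schema("full-v1", feats, groups)
}

# Which features in a schema hold numeric values.
numeric_features <- function(schema) {
  intersect(schema$feature_names,
            c("utr5_len", "cds_len", "utr3_len", "nc_number",
              setdiff(TUNNEL_FEATURES, "tun_cterm_charge")))
}

#' Extract stop-codon context features for every transcript in a catalog
#'
#' Positions that fall outside the transcript (upstream of the CDS start or
#' downstream of the transcript end) are encoded as the explicit missing
#' level `"NA_short"`. Records with an N inside any requested window are
#' excluded from the result and reported in the `"excluded"` attribute.
#' Negative-control slots are present but `NA` until
#' [attach_negative_controls()] fills them.
#'
#' @param catalog An [mrna_catalog()].
#' @param schema A [feature_schema()]; default [default_schema()].
#' @return Data frame: `transcript_id` plus one column per schema feature.
#' @export
extract_features <- function(catalog, schema = default_schema()) {
  n <- nrow(catalog)
  seqs <- catalog$sequence
  s1 <- catalog$utr5_len + catalog$cds_len + 1L  # first stop base, 1-based
  seq_len_all <- nchar(seqs)
  out <- list(transcript_id = catalog$transcript_id)

  base_at <- function(pos, lower_ok, upper_ok) {
    v <- substr(seqs, pos, pos)
    v[!lower_ok | !upper_ok] <- "NA_short"
    v
  }
  for (f in schema$feature_names) {
    if (grepl("^nt_m[0-9]+$", f)) {
      k <- as.integer(sub("nt_m", "", f))
      pos <- s1 - k
      out[[f]] <- base_at(pos, pos > catalog$utr5_len, pos <= seq_len_all)
    } else if (grepl("^nt_p[0-9]+$", f)) {
      m <- as.integer(sub("nt_p", "", f))
      pos <- s1 + m - 1L
      out[[f]] <- base_at(pos, pos >= 1L, pos <= seq_len_all)
    }
  }
  if ("stop_codon" %in% schema$feature_names) {
    out$stop_codon <- substr(seqs, s1, s1 + 2L)
  }
  p_cod <- substr(seqs, s1 - 3L, s1 - 1L)
  e_cod <- ifelse(catalog$cds_len >= 6L, substr(seqs, s1 - 6L, s1 - 4L),
                  "NA_short")
  if ("p_site_codon" %in% schema$feature_names) out$p_site_codon <- p_cod
  if ("e_site_codon" %in% schema$feature_names) out$e_site_codon <- e_cod
  aa_of <- function(cod) {
    aa <- translate_codons(cod)
    aa[cod == "NA_short"] <- "NA_short"
    aa[is.na(aa)] <- "NA_invalid"  # codon containing N; row flagged below
    aa
  }
  if ("p_site_aa" %in% schema$feature_names) out$p_site_aa <- aa_of(p_cod)
  if ("e_site_aa" %in% schema$feature_names) out$e_site_aa <- aa_of(e_cod)
  for (f in intersect(c("utr5_len", "cds_len", "utr3_len"),
                      schema$feature_names)) {
    out[[f]] <- as.numeric(catalog[[f]])
  }

  if (any(TUNNEL_FEATURES %in% schema$feature_names)) {
    tun <- tunnel_aggregates(seqs, catalog$utr5_len, catalog$cds_len)
    for (f in intersect(TUNNEL_FEATURES, schema$feature_names)) {
      out[[f]] <- tun[[f]]
    }
    tun_bad <- tun$has_n
  } else {
    tun_bad <- logical(n)
  }
  for (f in intersect(c("nc_number", "nc_letter"), schema$feature_names)) {
    out[[f]] <- rep(NA, n)
  }

  df <- as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
  # An N inside any requested window invalidates the record. Note "N" is a
  # legitimate amino-acid level (asparagine), so only nucleotide- and
  # codon-valued features are screened, plus the NA_invalid marker that
  # aa_of() assigns to untranslatable codons.
  has_n <- tun_bad
  for (cn in grep("^nt_[mp][0-9]+$", names(df), value = TRUE)) {
    has_n <- has_n | df[[cn]] == "N"
  }
  for (cn in intersect(c("stop_codon", "p_site_codon", "e_site_codon"),
                       names(df))) {
    has_n <- has_n | grepl("N", df[[cn]], fixed = TRUE)
  }
  for (cn in intersect(c("p_site_aa", "e_site_aa"), names(df))) {
    has_n <- has_n | df[[cn]] == "NA_invalid"
  }
  excluded <- data.frame(transcript_id = df$transcript_id[has_n],
                         reason = rep("N in feature window", sum(has_n)),
                         stringsAsFactors = FALSE)
  df <- df[!has_n, , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "schema_name") <- schema$name
  attr(df, "excluded") <- excluded
  df
}

# Aggregate exit-tunnel properties over the last (up to) 30 encoded
# residues of each CDS. Returns a list of numeric vectors plus has_n.
tunnel_aggregates <- function(seqs, utr5_len, cds_len) {
  n <- length(seqs)
  ncod <- cds_len %/% 3L
  take <- pmin(ncod, TUNNEL_WINDOW)
  from <- utr5_len + cds_len - 3L * take + 1L
  to <- utr5_len + cds_len
  tails <- substr(seqs, from, to)
  res <- list(tun_frac_positive = numeric(n), tun_frac_negative = numeric(n),
              tun_net_charge = numeric(n), tun_mean_hydropathy = numeric(n),
              tun_frac_aromatic = numeric(n), tun_frac_proline = numeric(n),
              tun_frac_glycine = numeric(n), tun_frac_polar = numeric(n),
              tun_frac_small = numeric(n),
              tun_cterm_charge = character(n), has_n = logical(n))
  for (i in seq_len(n)) {
    aa <- translate_codons(seq_codons(tails[i]))
    if (anyNA(aa)) {
      res$has_n[i] <- TRUE
      aa <- aa[!is.na(aa)]
      if (!length(aa)) aa <- "G"
    }
    m <- length(aa)
    res$tun_frac_positive[i] <- sum(aa %in% AA_POSITIVE) / m
    res$tun_frac_negative[i] <- sum(aa %in% AA_NEGATIVE) / m
    res$tun_net_charge[i] <- sum(aa %in% c("K", "R")) - sum(aa %in% AA_NEGATIVE)
    res$tun_mean_hydropathy[i] <- mean(KD_HYDROPATHY[aa], na.rm = TRUE)
    res$tun_frac_aromatic[i] <- sum(aa %in% AA_AROMATIC) / m
    res$tun_frac_proline[i] <- sum(aa == "P") / m
    res$tun_frac_glycine[i] <- sum(aa == "G") / m
    res$tun_frac_polar[i] <- sum(aa %in% AA_POLAR) / m
    res$tun_frac_small[i] <- sum(aa %in% AA_SMALL) / m
    last <- aa[m]
    res$tun_cterm_charge[i] <-
      if (last %in% AA_POSITIVE) "positive"
      else if (last %in% AA_NEGATIVE) "negative" else "neutral"
  }
  res
}

#' Attach randomized negative-control features
#'
#' Assigns each transcript a uniform random integer in 1..100
#' (`nc_number`) and a uniform random letter from A/C/G/U (`nc_letter`),
#' independent of all biological features and reproducible given the seed.
#'
#' @param features Feature data frame from [extract_features()].
#' @param seed Integer seed (a dedicated substream is derived from it).
#' @return The feature data frame with the control columns filled.
#' @export
attach_negative_controls <- function(features, seed) {
  n <- nrow(features)
  with_rt_seed(substream_seed(seed, "negative_controls"), {
    features$nc_number <- as.numeric(sample.int(100L, n, replace = TRUE))
    features$nc_letter <- sample(RNA_BASES, n, replace = TRUE)
  })
  features
}

#' Derive reduced, assay, and mock feature-schema variants
#'
#' `reduced` keeps the context features plus every non-tunnel, non-control
#' feature whose importance exceeds the negative-control baseline (the
#' larger of the two control scores), and drops the tunnel features.
#' `assay` additionally drops the region-length features
#' (`utr5_len`, `cds_len`, `utr3_len`), which have no analog in a
#' fixed-backbone reporter construct. `mock1`..`mock3` are seeded random
#' subsets of low-importance features (score at or below the control
#' baseline), each the same size as `reduced`. Variant schemas carry only
#' mRNA features (no negative controls).
#'
#' @param variant One of `"reduced"`, `"assay"`, `"mock1"`, `"mock2"`,
#'   `"mock3"`.
#' @param importance Importance table (columns `feature`, `score`) from
#'   [permutation_importance()]. Required for mock variants; when `NULL`,
#'   `reduced`/`assay` fall back to context features plus 3'-UTR length.
#' @param seed Integer seed for the mock subsets.
#' @param base Base schema, default [default_schema()].
#' @param mock_fallback What to do when fewer baseline-low features exist
#'   than a mock schema needs: `"error"` (default) aborts;
#'   `"bottom_rank"` widens the candidate pool to the lowest-scoring
#'   features by rank (1.3 x the required size), which is always
#'   feasible. The baseline rule is noisy because it is the maximum of
#'   just two null scores, so the strict rule can be unsatisfiable on
#'   weakly structured data.
#' @return A [feature_schema()].
#' @export
derive_variant_schema <- function(variant, importance = NULL, seed = 1L,
                                  base = default_schema(),
                                  mock_fallback = c("error", "bottom_rank")) {
  mock_fallback <- match.arg(mock_fallback)
  variant <- match.arg(variant, c("reduced", "assay", "mock1", "mock2",
                                  "mock3"))
  grp <- base$groups
  context <- names(grp)[grp == "context"]
  tunnel <- names(grp)[grp == "tunnel"]
  nc <- names(grp)[grp == "negative_control"]
  if (!is.null(importance)) {
    if (!all(c("feature", "score") %in% names(importance))) {
      stop("importance table needs columns 'feature' and 'score'")
    }
    baseline <- max(importance$score[importance$feature %in% nc])
    high <- importance$feature[importance$score > baseline]
    low <- importance$feature[importance$score <= baseline]
  } else {
    if (grepl("^mock", variant)) {
      stop("mock variants require an importance table")
    }
    baseline <- NA_real_
    high <- "utr3_len"
    low <- character(0)
  }
  reduced <- intersect(base$feature_names,
                       setdiff(union(context, high), c(tunnel, nc)))
  keep <- switch(
    variant,
    reduced = reduced,
    assay = setdiff(reduced, c("utr5_len", "cds_len", "utr3_len")),
    {
      candidates <- setdiff(intersect(base$feature_names, low), nc)
      if (length(candidates) < length(reduced)) {
        if (mock_fallback == "error") {
          stop("only ", length(candidates), " low-importance features ",
               "available; ", length(reduced), " needed for a mock schema")
        }
        pool_size <- min(length(base$feature_names) - length(nc),
                         ceiling(1.3 * length(reduced)))
        ord <- importance[order(importance$score), , drop = FALSE]
        candidates <- intersect(setdiff(ord$feature, nc),
                                base$feature_names)[seq_len(pool_size)]
      }
      sub_seed <- substream_seed(seed, paste0("variant_", variant))
      with_rt_seed(sub_seed,
                   sort(match(sample(candidates, length(reduced)),
                              base$feature_names)))
      # sampled indices sorted to keep base ordering
    })
  if (grepl("^mock", variant)) keep <- base$feature_names[keep]
  feature_schema(variant, keep, grp[keep])
}

#' Write / read a feature schema as a plain-text document
#'
#' @param schema A [feature_schema()].
#' @param path File path.
#' @return `path` (write) or a [feature_schema()] (read).
#' @export
write_schema <- function(schema, path) {
  lines <- c(paste0("name: ", schema$name),
             paste0(schema$feature_names, "\t", schema$groups))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_schema
#' @export
read_schema <- function(path) {
  lines <- readLines(path)
  name <- sub("^name: ", "", lines[1])
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  feats <- vapply(parts, `[`, character(1), 1L)
  groups <- setNames(vapply(parts, `[`, character(1), 2L), feats)
  feature_schema(name, feats, groups)
}
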