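# Stage orchestration: each subcommand reads/writes plain tabular
# artifacts in a run directory, together with a manifest recording the
# package version, seed, configuration echo, and input checksums. All
# randomness flows from the single `seed` entry via named substreams, and
# no timestamps are written, so a rerun with the same seed reproduces
# byte-identical outputs.

#' Run one pipeline stage
#'
#' Subcommands and their artifacts (all under `config$out_dir`):
#' \describe{
#'   \item{simulate}{`catalog.fa`, `regions.tsv`, `truth.tsv`,
#'     `counts.tsv` from the synthetic generator.}
#'   \item{quantify}{`readthrough.tsv` (RPKMs, log2 RE, detectability,
#'     extreme labels) from `counts.tsv`.}
#'   \item{features}{`features.tsv` and `schema.txt` from the catalog.}
#'   \item{train}{`model.rds` (regression and classification forests) from
#'     features + readthrough.}
#'   \item{importance}{`importance_regression.tsv`,
#'     `importance_classification.tsv` from `model.rds`.}
#'   \item{stats}{`group_medians.tsv`, `chi2_residuals.tsv`,
#'     `correlations.tsv`.}
#'   \item{fold}{`mfe.tsv` (lowest local MFE per 3'-UTR).}
#'   \item{predict-ptc}{`ptc_predictions.tsv` for alleles in
#'     `config$alleles_path` + `config$genes_fasta`.}
#'   \item{dualluc}{`dualluc_results.tsv`, `dualluc_stop_tests.tsv` from a
#'     plate CSV.}
#' }
#'
#' @param subcommand One of `"simulate"`, `"quantify"`, `"features"`,
#'   `"train"`, `"importance"`, `"stats"`, `"fold"`, `"predict-ptc"`,
#'   `"dualluc"`.
#' @param config Named list; recognized entries: `out_dir` (required),
#'   `seed` (default 1), `schema` (default `"full-v1"`), `rpkm_cds_min`
#'   (5), `rpkm_ext_min` (0.5), `extreme_fraction` (0.15),
#'   `outlier_percent` (25), `backend` (`"builtin"`), `sim` (a
#'   [sim_config()] for `simulate`), plus stage input paths
#'   (`counts_path`, `catalog_fasta`, `regions_path`, `features_path`,
#'   `readthrough_path`, `model_path`, `alleles_path`, `genes_fasta`,
#'   `plate_path`) defaulting to the artifacts of earlier stages in
#'   `out_dir`.
#' @return Invisibly, a character vector of the files written.
#' @export
rt_run <- function(subcommand, config) {
  subcommand <- match.arg(subcommand,
                          c("simulate", "quantify", "features", "train",
                            "importance", "stats", "fold", "predict-ptc",
                            "dualluc"))
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  defaults <- list(seed = 1L, schema = "full-v1", rpkm_cds_min = 5,
                   rpkm_ext_min = 0.5, extreme_fraction = 0.15,
                   outlier_percent = 25, backend = "builtin")
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  art <- function(name) file.path(config$out_dir, name)
  path_default <- function(entry, name) {
    if (is.null(config[[entry]])) art(name) else config[[entry]]
  }
  inputs <- character(0)
  written <- switch(
    subcommand,
    simulate = {
      sim <- config$sim
      if (is.null(sim)) sim <- sim_config(seed = config$seed)
      catalog <- simulate_catalog(sim)
      counts <- simulate_counts(catalog, sim)
      write_catalog(catalog, art("catalog.fa"), art("regions.tsv"),
                    meta = c(seed = config$seed))
      write_tsv_meta(catalog[, c("transcript_id", "true_log2_re")],
                     art("truth.tsv"), meta = c(seed = config$seed))
      write_tsv_meta(counts, art("counts.tsv"), meta = c(seed = config$seed))
      c(art("catalog.fa"), art("regions.tsv"), art("truth.tsv"),
        art("counts.tsv"))
    },
    quantify = {
      counts_path <- path_default("counts_path", "counts.tsv")
      inputs <- counts_path
      counts <- read_region_counts(counts_path)
      tbl <- if ("cds_count" %in% names(counts)) {
        compute_readthrough(counts)
      } else {
        counts
      }
      det <- if ("rpkm_cds" %in% names(tbl)) {
        filter_detectable(tbl, config$rpkm_cds_min, config$rpkm_ext_min)
      } else {
        # pre-computed efficiencies: no RPKM filter applicable
        structure(tbl[is.finite(tbl$log2_re), , drop = FALSE],
                  discarded = c(nonfinite = sum(!is.finite(tbl$log2_re))))
      }
      det <- label_extremes(det, config$extreme_fraction)
      tbl$detectable <- tbl$transcript_id %in% det$transcript_id
      tbl$extreme_label <- "none"
      tbl$extreme_label[match(det$transcript_id, tbl$transcript_id)] <-
        det$extreme_label
      disc <- attr(det, "discarded")
      write_tsv_meta(tbl, art("readthrough.tsv"),
                     meta = c(seed = config$seed,
                              setNames(as.character(disc),
                                       paste0("discarded_", names(disc)))))
      art("readthrough.tsv")
    },
    features = {
      fa <- path_default("catalog_fasta", "catalog.fa")
      rg <- path_default("regions_path", "regions.tsv")
      inputs <- c(fa, rg)
      catalog <- read_catalog(fa, rg)
      schema <- pipeline_schema(config$schema)
      feats <- extract_features(catalog, schema)
      feats <- attach_negative_controls(feats, config$seed)
      write_schema(schema, art("schema.txt"))
      write_tsv_meta(feats, art("features.tsv"),
                     meta = c(seed = config$seed, schema = schema$name))
      exclusions <- rbind(attr(catalog, "excluded"),
                          attr(feats, "excluded"))
      write_tsv_meta(exclusions, art("exclusions.tsv"),
                     meta = c(seed = config$seed))
      c(art("schema.txt"), art("features.tsv"), art("exclusions.tsv"))
    },
    train = {
      fp <- path_default("features_path", "features.tsv")
      rp <- path_default("readthrough_path", "readthrough.tsv")
      inputs <- c(fp, rp)
      feats <- read_tsv_meta(fp)
      schema_name <- unname(attr(feats, "meta")["schema"])
      if (!identical(schema_name, config$schema)) {
        stop("schema mismatch: feature table was built with '",
             schema_name, "' but config requests '", config$schema, "'")
      }
      rt <- read_tsv_meta(rp)
      rt <- rt[rt$detectable %in% c(TRUE, "TRUE"), , drop = FALSE]
      m <- match(rt$transcript_id, feats$transcript_id)
      rt <- rt[!is.na(m), , drop = FALSE]
      feats_rt <- feats[m[!is.na(m)], , drop = FALSE]
      schema <- pipeline_schema(config$schema)
      reg <- train_regressor(feats_rt, rt$log2_re,
                             model_spec("regression", seed = config$seed),
                             schema = schema)
      ext <- rt$extreme_label %in% c("high", "low")
      cls <- train_classifier(feats_rt[ext, , drop = FALSE],
                              rt$extreme_label[ext],
                              model_spec("classification",
                                         seed = config$seed),
                              schema = schema)
      saveRDS(list(regression = reg, classification = cls,
                   package_version = as.character(packageVersion("readthroughr"))),
              art("model.rds"))
      art("model.rds")
    },
    importance = {
      mp <- path_default("model_path", "model.rds")
      inputs <- mp
      models <- readRDS(mp)
      for (task in c("regression", "classification")) {
        imp <- permutation_importance(models[[task]])
        write_tsv_meta(imp, art(paste0("importance_", task, ".tsv")),
                       meta = c(seed = config$seed,
                                metric = if (task == "regression")
                                  "pct_inc_mse" else "mean_decrease_accuracy"))
      }
      c(art("importance_regression.tsv"), art("importance_classification.tsv"))
    },
    stats = {
      fp <- path_default("features_path", "features.tsv")
      rp <- path_default("readthrough_path", "readthrough.tsv")
      inputs <- c(fp, rp)
      feats <- read_tsv_meta(fp)
      rt <- read_tsv_meta(rp)
      rt <- rt[rt$detectable %in% c(TRUE, "TRUE"), , drop = FALSE]
      m <- match(rt$transcript_id, feats$transcript_id)
      keep <- !is.na(m)
      rt <- rt[keep, , drop = FALSE]
      fx <- feats[m[keep], , drop = FALSE]
      quad <- paste0(fx$stop_codon, fx$nt_p4)
      gm <- rbind(
        group_median_analysis(rt$log2_re, fx$stop_codon, "stop"),
        group_median_analysis(rt$log2_re, fx$nt_p4, "nt_p4"),
        group_median_analysis(rt$log2_re, quad, "quadruplet"),
        group_median_analysis(rt$log2_re, fx$p_site_codon, "p_site_codon"),
        group_median_analysis(rt$log2_re, fx$nc_letter, "nc_letter"))
      write_tsv_meta(gm, art("group_medians.tsv"),
                     meta = c(seed = config$seed))
      chi <- chi2_stop_nt4(fx$stop_codon, fx$nt_p4)
      res_df <- as.data.frame(as.table(chi$std_residuals),
                              stringsAsFactors = FALSE)
      names(res_df) <- c("stop_codon", "nt4", "std_residual")
      write_tsv_meta(res_df, art("chi2_residuals.tsv"),
                     meta = c(seed = config$seed,
                              chi2 = format(chi$chi2, digits = 10),
                              p = format(chi$p, digits = 10)))
      cor_all <- correlate(fx$utr3_len, rt$log2_re)
      cor_filt <- correlate(fx$utr3_len, rt$log2_re, filter = c(100, 5000))
      cors <- data.frame(
        analysis = c("utr3_len_all", "utr3_len_100_5000"),
        rho = c(cor_all$rho, cor_filt$rho),
        p = c(cor_all$p, cor_filt$p),
        n = c(cor_all$n, cor_filt$n))
      write_tsv_meta(cors, art("correlations.tsv"),
                     meta = c(seed = config$seed))
      c(art("group_medians.tsv"), art("chi2_residuals.tsv"),
        art("correlations.tsv"))
    },
    fold = {
      fa <- path_default("catalog_fasta", "catalog.fa")
      rg <- path_default("regions_path", "regions.tsv")
      inputs <- c(fa, rg)
      catalog <- read_catalog(fa, rg)
      mfe <- fold_utr3(catalog, backend = config$backend)
      write_tsv_meta(mfe, art("mfe.tsv"),
                     meta = c(seed = config$seed, backend = config$backend))
      art("mfe.tsv")
    },
    `predict-ptc` = {
      mp <- path_default("model_path", "model.rds")
      ap <- config$alleles_path
      gf <- config$genes_fasta
      if (is.null(ap) || is.null(gf)) {
        stop("predict-ptc requires config$alleles_path and config$genes_fasta")
      }
      inputs <- c(mp, ap, gf)
      models <- readRDS(mp)
      alleles <- read_alleles(ap, gf)
      schema <- pipeline_schema(config$schema)
      preds <- predict_alleles(models$regression, alleles, "native",
                               schema = schema, seed = config$seed)
      if (!is.null(config$reporter)) {
        preds <- rbind(preds,
                       predict_alleles(models$regression, alleles,
                                       "reporter", spec = config$reporter,
                                       schema = schema,
                                       seed = config$seed))
      }
      attr(preds, "features") <- NULL
      write_tsv_meta(preds, art("ptc_predictions.tsv"),
                     meta = c(seed = config$seed))
      art("ptc_predictions.tsv")
    },
    dualluc = {
      pp <- config$plate_path
      if (is.null(pp)) stop("dualluc requires config$plate_path")
      inputs <- pp
      plate <- utils::read.csv(pp, stringsAsFactors = FALSE)
      res <- g418_response(plate, threshold = config$outlier_percent)
      write_tsv_meta(res, art("dualluc_results.tsv"),
                     meta = c(seed = config$seed,
                              outlier_percent = config$outlier_percent))
      files <- art("dualluc_results.tsv")
      if (!is.null(config$stops)) {
        cmp <- compare_response_by_stop(res, config$stops)
        write_tsv_meta(cmp$tests, art("dualluc_stop_tests.tsv"),
                       meta = c(seed = config$seed))
        files <- c(files, art("dualluc_stop_tests.tsv"))
      }
      files
    })
  manifest <- data.frame(
    key = c("package_version", "subcommand", "seed", "schema",
            if (length(inputs)) paste0("md5_", basename(inputs))),
    value = c(as.character(packageVersion("readthroughr")), subcommand,
              as.character(config$seed), config$schema,
              if (length(inputs)) unname(tools::md5sum(inputs))),
    stringsAsFactors = FALSE)
  write_tsv_meta(manifest,
                 file.path(config$out_dir,
                           paste0("manifest_", gsub("-", "_", subcommand),
                                  ".tsv")))
  invisible(written)
}

# Resolve a schema name used in pipeline configs. Variant schemas need an
# importance table and are derived in code, not by name, so only the full
# schema is addressable here.
pipeline_schema <- function(name) {
  if (name %in% c("full", "full-v1")) return(default_schema())
  stop("unknown schema name '", name,
       "'; derive variant schemas with derive_variant_schema()")
}
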