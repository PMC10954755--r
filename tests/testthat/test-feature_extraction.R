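test_that("the full schema has the documented composition", {
  sch <- default_schema()
  expect_equal(length(sch$feature_names), 77L)
  tab <- table(sch$groups)
  expect_equal(unname(tab[["context"]]), 21L)
  expect_equal(unname(tab[["tunnel"]]), 10L)
  expect_equal(unname(tab[["other"]]), 44L)
  expect_equal(unname(tab[["negative_control"]]), 2L)
  expect_false(anyDuplicated(sch$feature_names) > 0)
})

test_that("features read off a constructed record correctly", {
  r <- build_record("F1", "AUCAUC", "AUGAAG", "UGA", "CUAGAAACC")
  f <- extract_features(mrna_catalog(r))
  expect_equal(f$p_site_codon, "AAG")
  expect_equal(f$p_site_aa, "K")
  expect_equal(f$e_site_codon, "AUG")
  expect_equal(f$e_site_aa, "M")
  expect_equal(f$stop_codon, "UGA")
  expect_equal(f$nt_p4, "C")
  expect_equal(f$nt_m1, "G")
  expect_equal(f$nt_m2, "A")
  expect_equal(f$nt_m3, "A")
  # CDS is 6 nt: nt -7 would precede the start codon
  expect_equal(f$nt_m6, "A")  # first base of AUG
  expect_equal(f$nt_m7, "NA_short")
  # 3'-UTR is 12 nt (incl. stop): +13 runs off the transcript
  expect_equal(f$nt_p12, "C")
  expect_equal(f$nt_p13, "NA_short")
  expect_equal(f$utr5_len, 6)
  expect_equal(f$cds_len, 6)
  expect_equal(f$utr3_len, 12)
})

test_that("the -9..+12 window reconstructed from features matches the sequence", {
  cat_ <- random_catalog(200, seed = 13, min_cds_codons = 4L,
                         max_tail = 60L)
  f <- extract_features(cat_)
  m <- match(f$transcript_id, cat_$transcript_id)
  for (i in seq_len(nrow(f))) {
    r <- cat_[m[i], ]
    s1 <- r$utr5_len + r$cds_len + 1L
    vals <- c(rev(vapply(1:9, function(k) f[[paste0("nt_m", k)]][i],
                         character(1))),
              strsplit(f$stop_codon[i], "")[[1]],
              vapply(4:12, function(k) f[[paste0("nt_p", k)]][i],
                     character(1)))
    pos <- s1 + (-9:11)
    in_bounds <- pos > r$utr5_len & pos <= nchar(r$sequence)
    expect_equal(vals[in_bounds],
                 vapply(pos[in_bounds],
                        function(p) substr(r$sequence, p, p),
                        character(1)))
    expect_true(all(vals[!in_bounds] == "NA_short"))
  }
})

test_that("records with N in a feature window are excluded, untouched elsewhere", {
  r_ok <- build_record("OK", "AUCAUC", "AUGAAGGCUAAAGCGUUU", "UGA",
                       "CUAGAAACCGGG")
  r_n_far <- r_ok
  r_n_far$transcript_id <- "NFAR"
  # N in the 5'-UTR, outside every requested window
  substr(r_n_far$sequence, 1, 1) <- "N"
  r_n_win <- r_ok
  r_n_win$transcript_id <- "NWIN"
  # N at nt +4
  substr(r_n_win$sequence, r_ok$utr5_len + r_ok$cds_len + 4L,
         r_ok$utr5_len + r_ok$cds_len + 4L) <- "N"
  cat_ <- mrna_catalog(rbind(r_ok, r_n_far, r_n_win))
  f <- extract_features(cat_)
  expect_setequal(f$transcript_id, c("OK", "NFAR"))
  expect_equal(attr(f, "excluded")$transcript_id, "NWIN")
})

test_that("negative controls are reproducible, uniform, and independent", {
  cat_ <- simulate_catalog(sim_config(n_transcripts = 10000L, seed = 3))
  f <- extract_features(cat_)
  f1 <- attach_negative_controls(f, seed = 5)
  f2 <- attach_negative_controls(f, seed = 5)
  expect_identical(f1$nc_number, f2$nc_number)
  expect_identical(f1$nc_letter, f2$nc_letter)
  f3 <- attach_negative_controls(f, seed = 6)
  expect_false(identical(f1$nc_letter, f3$nc_letter))

  freq <- table(f1$nc_letter) / nrow(f1)
  expect_true(all(abs(freq - 0.25) < 0.02))
  expect_true(all(f1$nc_number %in% 1:100))

  # independence from the planted readthrough truth across nc seeds
  truth <- cat_$true_log2_re[match(f$transcript_id, cat_$transcript_id)]
  ok <- 0L
  for (s in 1:20) {
    fs <- attach_negative_controls(f, seed = s)
    if (abs(cor(fs$nc_number, truth, method = "spearman")) < 0.05) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok, 19L)
})

test_that("assay-schema features depend only on the context window", {
  cat_ <- random_catalog(50, seed = 21, min_cds_codons = 12L,
                         max_tail = 80L)
  assay <- derive_variant_schema("assay")
  f0 <- extract_features(cat_, assay)
  mutated <- cat_
  # scramble sequence outside the -9..+12 window (and outside the P-/E-site
  # codons): flip the first 5'-UTR base and the last 3'-UTR base
  substr(mutated$sequence, 1, 1) <-
    chartr("ACGU", "CAUG", substr(mutated$sequence, 1, 1))
  last <- nchar(mutated$sequence)
  keep_from <- mutated$utr5_len + mutated$cds_len + 13L
  flip <- last > keep_from
  substr(mutated$sequence[flip], last[flip], last[flip]) <-
    chartr("ACGU", "CAUG", substr(mutated$sequence[flip], last[flip],
                                  last[flip]))
  f1 <- extract_features(mutated, assay)
  expect_equal(f0, f1, ignore_attr = TRUE)
})

test_that("variant schemas follow the reduced/assay/mock rules", {
  sch <- default_schema()
  imp <- data.frame(feature = sch$feature_names,
                    score = 0, stringsAsFactors = FALSE)
  # plant importance: planted features high, controls set the baseline
  imp$score[imp$feature %in% c("stop_codon", "nt_p4", "utr3_len",
                               "p_site_aa")] <- 10
  imp$score[imp$feature == "nc_number"] <- 0.4
  imp$score[imp$feature == "nc_letter"] <- 0.2
  imp$score[imp$feature == "tun_net_charge"] <- 5  # high but tunnel

  red <- derive_variant_schema("reduced", imp)
  expect_false(any(red$groups == "tunnel"))
  expect_false(any(red$groups == "negative_control"))
  expect_true(all(c("stop_codon", "nt_p4", "p_site_codon", "utr3_len")
                  %in% red$feature_names))

  assay <- derive_variant_schema("assay", imp)
  # only utr3_len cleared the importance baseline, so it is the only
  # length feature the assay schema has to drop
  expect_setequal(setdiff(red$feature_names, assay$feature_names),
                  "utr3_len")
  expect_false("utr3_len" %in% assay$feature_names)

  m1 <- derive_variant_schema("mock1", imp, seed = 9)
  m2 <- derive_variant_schema("mock2", imp, seed = 9)
  expect_equal(length(m1$feature_names), length(red$feature_names))
  expect_equal(length(m2$feature_names), length(red$feature_names))
  expect_false(identical(m1$feature_names, m2$feature_names))
  expect_identical(m1$feature_names,
                   derive_variant_schema("mock1", imp, seed = 9)$feature_names)
  baseline <- 0.4
  expect_true(all(imp$score[match(m1$feature_names, imp$feature)] <=
                    baseline))
  # nesting: assay subset of reduced subset of full
  expect_true(all(assay$feature_names %in% red$feature_names))
  expect_true(all(red$feature_names %in% sch$feature_names))

  # not enough low-importance features -> fatal with count
  imp_hi <- imp
  imp_hi$score[!imp_hi$feature %in% c("nc_number", "nc_letter")] <- 10
  expect_error(derive_variant_schema("mock1", imp_hi, seed = 1),
               "low-importance")
  expect_error(derive_variant_schema("mock1", NULL), "importance")

  # rank-based fallback fills the mock from the lowest-scoring features
  imp_rank <- imp
  set.seed(33)
  imp_rank$score <- imp_rank$score + runif(nrow(imp_rank), 0, 0.1)
  imp_rank$score[imp_rank$feature %in% c("nc_number", "nc_letter")] <- -1
  expect_error(derive_variant_schema("mock1", imp_rank, seed = 1),
               "low-importance")
  mfb <- derive_variant_schema("mock1", imp_rank, seed = 1,
                               mock_fallback = "bottom_rank")
  red_rank <- derive_variant_schema("reduced", imp_rank)
  expect_equal(length(mfb$feature_names), length(red_rank$feature_names))
  # members come from the lowest-scoring candidate pool
  non_nc <- imp_rank[!imp_rank$feature %in% c("nc_number", "nc_letter"), ]
  pool <- non_nc$feature[order(non_nc$score)][
    seq_len(min(nrow(non_nc), ceiling(1.3 * length(red_rank$feature_names))))]
  expect_true(all(mfb$feature_names %in% pool))
})

test_that("schemas round-trip through their plain-text format", {
  sch <- default_schema()
  p <- tempfile(fileext = ".txt")
  write_schema(sch, p)
  got <- read_schema(p)
  expect_equal(got$name, sch$name)
  expect_equal(got$feature_names, sch$feature_names)
  expect_equal(got$groups, sch$groups)
})
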