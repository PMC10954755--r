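sense_pool <- function() {
  bases <- c("A", "C", "G", "U")
  setdiff(apply(expand.grid(bases, bases, bases), 1, paste, collapse = ""),
          c("UAA", "UAG", "UGA"))
}

random_allele <- function(seed, n_codons = 60, utr3_len = 90) {
  set.seed(seed)
  sense <- sense_pool()
  cds <- paste(c("AUG", sample(sense, n_codons - 2, TRUE), "UAA"),
               collapse = "")
  utr3 <- paste(sample(c("A", "C", "G", "U"), utr3_len, TRUE),
                collapse = "")
  k <- sample(5:(n_codons - 5), 1)
  ptc_allele(sprintf("AL%03d", seed), cds, utr3, k,
             sample(c("UAA", "UAG", "UGA"), 1))
}

test_that("native records keep the length bookkeeping of the mutation", {
  a <- random_allele(1, n_codons = 50, utr3_len = 80)
  rec <- build_native_record(a)
  k <- a$ptc_codon_index
  expect_equal(rec$cds_len, 3 * (k - 1))
  expect_equal(rec$utr3_len, 3 * (50 - k + 1) + 80)
  expect_equal(nchar(rec$sequence), 150 + 80)

  # stop codon and nt +4 read off as planted
  f <- extract_features(rec)
  expect_equal(f$stop_codon, a$ptc_stop)
  expect_equal(f$nt_p4, substr(a$gene_cds, 3 * k + 1, 3 * k + 1))

  expect_error(build_native_record(
    ptc_allele("X", a$gene_cds, a$utr3_native, 1, "UGA")), "P-site")
})

test_that("the native record window equals the directly mutated sequence", {
  for (s in 1:50) {
    a <- random_allele(s)
    rec <- build_native_record(a)
    mutated <- a$gene_cds
    substr(mutated, 3 * a$ptc_codon_index - 2, 3 * a$ptc_codon_index) <-
      a$ptc_stop
    full <- paste0(mutated, a$utr3_native)
    s1 <- 3 * (a$ptc_codon_index - 1) + 1
    expect_equal(substr(rec$sequence, rec$cds_len - 8, rec$cds_len + 15),
                 substr(full, s1 - 9, s1 + 14))
  }
})

test_that("reporter records are local: identical contexts, identical features", {
  spec <- synth_reporter_spec(seed = 2)
  a1 <- random_allele(3)
  # second allele: same 7-codon context around the PTC, different elsewhere
  a2 <- random_allele(4)
  ctx <- substr(a1$gene_cds, 3 * (a1$ptc_codon_index - 3) - 2,
                3 * (a1$ptc_codon_index + 3))
  cds2 <- a2$gene_cds
  substr(cds2, 3 * (a2$ptc_codon_index - 3) - 2,
         3 * (a2$ptc_codon_index + 3)) <- ctx
  a2 <- ptc_allele(a2$name, cds2, a2$utr3_native, a2$ptc_codon_index,
                   a1$ptc_stop)
  r1 <- build_reporter_record(a1, spec)
  r2 <- build_reporter_record(a2, spec)
  f1 <- extract_features(r1)
  f2 <- extract_features(r2)
  expect_equal(f1[, -1], f2[, -1], ignore_attr = TRUE)
  # 3'-UTR length is a construct constant
  expect_equal(r1$utr3_len, spec$utr3_reporter_len)
  expect_equal(r2$utr3_len, r1$utr3_len)
})

test_that("assay features agree between native and reporter schemes", {
  spec <- synth_reporter_spec(seed = 5)
  assay <- derive_variant_schema("assay")
  for (s in 6:10) {
    a <- random_allele(s, n_codons = 80)
    fn <- extract_features(build_native_record(a), assay)
    fr <- extract_features(build_reporter_record(a, spec), assay)
    shared <- c("stop_codon", paste0("nt_m", 1:9), paste0("nt_p", 4:12),
                "p_site_codon", "p_site_aa")
    expect_equal(fn[, shared], fr[, shared], ignore_attr = TRUE)
  }
})

test_that("reporter features outside the insert are constant across alleles", {
  spec <- synth_reporter_spec(seed = 11)
  sch <- default_schema()
  feats <- lapply(11:14, function(s) {
    extract_features(build_reporter_record(random_allele(s), spec), sch)
  })
  # the E-site codon/amino acid derive from nt -4..-6, which sit inside
  # the 7-codon insert, so they legitimately vary with the allele
  other <- setdiff(names(sch$groups)[sch$groups == "other"],
                   c("e_site_codon", "e_site_aa"))
  for (col in other) {
    vals <- vapply(feats, function(f) as.character(f[[col]]), character(1))
    expect_equal(length(unique(vals)), 1L, info = col)
  }
})

test_that("scheme comparison recovers planted discordant points", {
  set.seed(51)
  a <- setNames(sort(rnorm(13)), sprintf("AL%02d", 1:13))
  b <- a + rnorm(13, 0, 0.01)
  b["AL03"] <- max(a) + 2  # planted discordant points
  b["AL09"] <- min(a) - 2
  expect_equal(compare_prediction_schemes(a, a)$rho, 1)
  expect_equal(compare_prediction_schemes(unname(a), unname(rev(a)))$rho, -1)
  got <- compare_prediction_schemes(a, b, leave_k = 2)
  expect_setequal(got$outliers, c("AL03", "AL09"))
  expect_gt(got$rho_without, got$rho)
  expect_error(compare_prediction_schemes(a[1:3], b[1:3]), "at least 4")
})

test_that("allele specifications round-trip through TSV + FASTA", {
  alleles <- lapply(21:23, random_allele)
  fa <- tempfile(fileext = ".fa")
  tsv <- tempfile(fileext = ".tsv")
  seqs <- unlist(lapply(alleles, function(a) {
    setNames(list(a$gene_cds, a$utr3_native),
             paste0(a$name, c("_cds", "_utr3")))
  }))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), fa)
  write_tsv_meta(data.frame(
    name = vapply(alleles, `[[`, character(1), "name"),
    gene = vapply(alleles, `[[`, character(1), "name"),
    ptc_codon_index = vapply(alleles, `[[`, integer(1), "ptc_codon_index"),
    ptc_stop = vapply(alleles, `[[`, character(1), "ptc_stop")), tsv)
  got <- read_alleles(tsv, fa)
  for (i in seq_along(alleles)) {
    expect_equal(got[[i]]$gene_cds, alleles[[i]]$gene_cds)
    expect_equal(got[[i]]$ptc_codon_index, alleles[[i]]$ptc_codon_index)
  }
})
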