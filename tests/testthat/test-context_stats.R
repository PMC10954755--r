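test_that("a group covering the whole sample has zero median difference", {
  y <- rnorm(50)
  got <- group_median_analysis(y, rep("all", 50), "degenerate")
  expect_equal(got$delta_median, 0)
  expect_equal(got$n, 50L)
  # single test: q equals p
  expect_equal(got$q, got$p)
})

test_that("BH-adjusted q-values are monotone in p and small groups are flagged", {
  set.seed(6)
  y <- c(rnorm(200), rnorm(100, 1), rnorm(3, 5))
  g <- c(rep("a", 200), rep("b", 100), rep("c", 3))
  got <- group_median_analysis(y, g, "toy")
  ord <- order(got$p)
  expect_true(all(diff(got$q[ord]) >= -1e-12))
  expect_true(got$small_group[got$level == "c"])
  expect_false(any(got$small_group[got$level %in% c("a", "b")]))
  expect_error(group_median_analysis(numeric(0), character(0)), "finite")
})

test_that("group-vs-complement Wilcoxon matches exact enumeration for tiny groups", {
  set.seed(11)
  for (m in c(2, 4, 6)) {
    for (n in c(3, 5, 8)) {
      x <- sample(seq_len(200), m + n)  # distinct values: no ties
      g <- rep(c("A", "B"), c(m, n))
      got <- group_median_analysis(x, g, "pair", complement = TRUE)
      p_a <- got$p[got$level == "A"]
      expect_equal(p_a, oracle_wilcoxon_p(x[seq_len(m)], x[-seq_len(m)]),
                   tolerance = 1e-12)
    }
  }
})

test_that("chi-squared independence test matches hand-computed values", {
  # 2x2 sub-case [[30,10],[10,30]]
  stop_v <- rep(c("UAA", "UGA"), each = 40)
  nt4_v <- c(rep(c("A", "C"), c(30, 10)), rep(c("A", "C"), c(10, 30)))
  got <- chi2_stop_nt4(stop_v, nt4_v)
  # closed forms for a 2x2 table with equal margins of 40
  expect_equal(unname(got$expected[1, 1]), 20)
  expect_equal(got$chi2, (30 - 20)^2 / 20 * 4, tolerance = 1e-10)
  # adjusted standardized residual: (O-E)/sqrt(E*(1-.5)*(1-.5))
  expect_equal(unname(got$std_residuals[1, 1]), 10 / sqrt(20 * 0.25),
               tolerance = 1e-10)
  expect_equal(sum(got$observed - got$expected), 0, tolerance = 1e-10)

  expect_error(chi2_stop_nt4(rep("UGA", 10), sample(c("A", "C"), 10, TRUE)),
               "at least 2")
})

test_that("outer-product tables give zero residuals and zero statistic", {
  stop_counts <- c(UAA = 20, UAG = 30, UGA = 50)
  nt4_counts <- c(A = 10, C = 20, G = 30, U = 40)
  stop_v <- character(0)
  nt4_v <- character(0)
  for (s in names(stop_counts)) {
    for (b in names(nt4_counts)) {
      k <- stop_counts[[s]] * nt4_counts[[b]] / 100
      stop_v <- c(stop_v, rep(s, k))
      nt4_v <- c(nt4_v, rep(b, k))
    }
  }
  got <- chi2_stop_nt4(stop_v, nt4_v)
  expect_equal(max(abs(got$std_residuals)), 0, tolerance = 1e-10)
  expect_equal(got$chi2, 0, tolerance = 1e-10)
})

test_that("planted stop/nt4 attraction produces a positive residual", {
  cfg <- sim_config(n_transcripts = 4000, seed = 19)
  cat_ <- simulate_catalog(cfg)
  f <- extract_features(cat_)
  got <- chi2_stop_nt4(f$stop_codon, f$nt_p4)
  expect_gt(got$std_residuals["UGA", "G"], 0)
  expect_gt(got$std_residuals["UAA", "A"], 0)
})

test_that("spearman correlation matches monotone cases and a tie oracle", {
  x <- 1:20
  expect_equal(correlate(x, x^3)$rho, 1)
  expect_equal(correlate(x, -x)$rho, -1)
  set.seed(23)
  xt <- sample(1:5, 60, TRUE)  # heavy ties
  yt <- sample(1:4, 60, TRUE)
  got <- correlate(xt, yt)
  oracle <- cor(rank(xt), rank(yt))  # rank-then-Pearson with midranks
  expect_equal(got$rho, oracle, tolerance = 1e-12)
  # strict filter bounds
  got_f <- correlate(c(100, 150, 200, 250, 300, 5000), c(1, 2, 3, 4, 5, 6),
                     filter = c(100, 5000))
  expect_equal(got_f$n, 4L)  # both boundary values excluded (strict)
  expect_error(correlate(1:3, 1:3), "at least 4")
})

test_that("context frequency tables are consistent with their counts", {
  r <- lapply(c(A = "A", C = "C", G = "G", U = "U"), function(b) {
    build_record(paste0("Q", b), "AUC", "AUGAAA", "UGA",
                 paste0(b, "CCCCC"))
  })
  cat_ <- mrna_catalog(do.call(rbind, r))
  tabs <- context_frequency_table(extract_features(cat_))
  expect_equal(tabs$quadruplet$proportion, rep(0.25, 4))
  for (fam in tabs) {
    expect_equal(sum(fam$proportion), 1)
    expect_equal(fam$proportion * sum(fam$count), fam$count)
  }
})

test_that("simulated catalogs reproduce the configured stop frequencies", {
  cfg <- sim_config(n_transcripts = 5000, seed = 29)
  tabs <- context_frequency_table(simulate_catalog(cfg))
  got <- setNames(tabs$stop$proportion, tabs$stop$level)
  expect_true(all(abs(got[names(cfg$stop_freqs)] - cfg$stop_freqs) < 0.02))
})
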