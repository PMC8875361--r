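test_that("size factors are exactly 1 for identical columns", {
  m <- make_counts(matrix(rep(c(10L, 200L, 3000L), 4), ncol = 4))
  expect_equal(unname(size_factors(m)), rep(1, 4), tolerance = 1e-10)
})

test_that("size factors match the hand-computed median-of-ratios example", {
  # geometric means 141.42 and 70.71; per-sample ratio medians 1/sqrt(2), sqrt(2)
  m <- make_counts(rbind(c(100L, 200L), c(50L, 100L)))
  expect_equal(unname(size_factors(m)), c(0.7071, 1.4142), tolerance = 1e-4)
})

test_that("genes with zeros are excluded from the size-factor reference", {
  m <- make_counts(rbind(c(100L, 200L), c(50L, 100L), c(0L, 77L)))
  sub <- m[1:2, ]
  expect_equal(size_factors(m), size_factors(sub))
  allzero <- make_counts(rbind(c(0L, 5L), c(3L, 0L)))
  expect_error(size_factors(allzero), "zero-free")
})

test_that("size factors agree with the standard median-of-ratios reference", {
  suppressMessages(requireNamespace("DESeq2"))
  set.seed(31)
  # odd gene count: the sample median is a single element, so median of
  # ratios and exp(median of log ratios) coincide exactly
  m <- make_counts(matrix(rnbinom(201 * 6, mu = 150, size = 10), 201))
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("method-of-moments dispersion hits the floor for Poisson-like data", {
  samples <- data.frame(sample_id = paste0("s", 1:3), strain = "CS",
                        condition = "standard", replicate = 1:3)
  # normalized counts (90, 100, 110): variance 100 = mean 100 -> floor
  m <- make_counts(matrix(c(90L, 100L, 110L), 1), samples = samples$sample_id)
  a <- estimate_dispersion(m, samples, sf = setNames(rep(1, 3), colnames(m)))
  expect_equal(unname(a), 1e-8)
})

test_that("dispersion estimates recover the truth at 50 replicates", {
  # interval [0.05, 0.2] fixed from a 2000-gene Monte-Carlo oracle
  # (median MoM estimate 0.098 at true alpha 0.1)
  set.seed(17)
  n <- 1000
  m <- make_counts(matrix(rnbinom(n * 50, mu = 200, size = 10), n))
  samples <- data.frame(sample_id = colnames(m), strain = "CS",
                        condition = "standard", replicate = 1:50)
  a <- estimate_dispersion(m, samples, sf = setNames(rep(1, 50), colnames(m)))
  expect_gt(median(a), 0.05)
  expect_lt(median(a), 0.2)

  short <- samples[1:1, ]
  expect_error(estimate_dispersion(m[, 1, drop = FALSE], short))
})

test_that("identical groups give a zero fold change and p = 1", {
  m <- make_counts(matrix(rep(c(50L, 80L, 110L), 2), 1))
  grp <- factor(rep(c("ref", "test"), each = 3), levels = c("ref", "test"))
  sf <- setNames(rep(1, 6), colnames(m))
  res <- nb_wald_test(m, grp, sf, 0.05)
  expect_equal(res$log2fc, 0, tolerance = 1e-8)
  expect_equal(res$wald, 0, tolerance = 1e-6)
  expect_equal(res$p, 1, tolerance = 1e-6)
})

test_that("the Wald fit recovers a planted four-fold change", {
  # mean estimated log2fc -2.009 (sd 0.30) in the pre-build Monte-Carlo run;
  # asserted within 2 +/- 0.15
  cc <- two_group_counts(500, mu_ref = 400, mu_test = 100, alpha = 0.05,
                         seed = 5)
  grp <- factor(rep(c("ref", "test"), each = 3), levels = c("ref", "test"))
  sf <- setNames(rep(1, 6), colnames(cc))
  res <- nb_wald_test(cc, grp, sf, rep(0.05, 500))
  expect_lt(abs(mean(res$log2fc) + 2), 0.15)
  expect_true(all(res$wald == res$log2fc / res$se))
})

test_that("Wald results agree with an independent GLM fit", {
  cc <- two_group_counts(20, mu_ref = 300, mu_test = 150, alpha = 0.08,
                         seed = 9)
  grp <- factor(rep(c("ref", "test"), each = 3), levels = c("ref", "test"))
  sf <- setNames(runif(6, 0.8, 1.2), colnames(cc))
  res <- nb_wald_test(cc, grp, sf, rep(0.08, 20))
  for (i in seq_len(20)) {
    fit <- stats::glm(cc[i, ] ~ grp + offset(log(sf)),
                      family = MASS::negative.binomial(theta = 1 / 0.08))
    expect_equal(res$log2fc[i], unname(coef(fit)[2]) / log(2),
                 tolerance = 1e-5)
  }
})

test_that("swapping test and reference negates the statistic", {
  cc <- two_group_counts(50, mu_ref = 200, mu_test = 120, alpha = 0.05,
                         seed = 21)
  sf <- setNames(rep(1, 6), colnames(cc))
  fwd <- factor(rep(c("ref", "test"), each = 3), levels = c("ref", "test"))
  # same labels, reversed reference level: test and reference roles swap
  rev <- factor(rep(c("ref", "test"), each = 3), levels = c("test", "ref"))
  a <- nb_wald_test(cc, fwd, sf, rep(0.05, 50))
  b <- nb_wald_test(cc, rev, sf, rep(0.05, 50))
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-8)
  expect_equal(a$wald, -b$wald, tolerance = 1e-6)
  expect_equal(a$p, b$p, tolerance = 1e-8)
})

test_that("scaling one sample scales its size factor and offsets absorb it", {
  sim <- simulate_counts(sim_config(n_genes = 100, seed = 13))
  counts <- sim$counts
  scaled <- counts
  scaled[, 1] <- scaled[, 1] * 3L
  sf1 <- size_factors(counts)
  sf2 <- size_factors(scaled)
  # median-of-ratios renormalizes globally by c^(-1/n); relative to the
  # other samples the scaled sample's factor grows by exactly c
  expect_equal(unname(sf2[1] / sf2[-1]), unname(3 * sf1[1] / sf1[-1]),
               tolerance = 1e-10)
  expect_equal(unname(sf2[-1] / sf1[-1]), rep(3^(-1 / 45), 44),
               tolerance = 1e-10)

  # contrasts that do not contain the rescaled sample (CS_standard_r1 sits
  # in every *_standard table) are exactly invariant
  disp <- rep(0.05, 100)
  c1 <- run_all_contrasts(counts, sim$samples, dispersions = disp)
  c2 <- run_all_contrasts(scaled, sim$samples, dispersions = disp)
  expect_identical(colnames(counts)[1], "CS_standard_r1")
  untouched <- names(c1)[!grepl("standard", names(c1))]
  expect_length(untouched, 8L)
  for (nm in untouched) {
    expect_equal(c1[[nm]]$log2fc, c2[[nm]]$log2fc, tolerance = 1e-10)
  }

  # offset correctness: rescaling every size factor by a constant leaves
  # every log2fc exactly unchanged
  c3 <- run_all_contrasts(counts, sim$samples, sf = 2 * sf1,
                          dispersions = disp)
  c4 <- run_all_contrasts(counts, sim$samples, sf = sf1, dispersions = disp)
  for (nm in names(c3)) {
    expect_equal(c3[[nm]]$log2fc, c4[[nm]]$log2fc, tolerance = 1e-10)
  }
})

test_that("zero-count genes are flagged rather than tested", {
  m <- make_counts(rbind(c(0L, 0L, 0L, 0L, 0L, 0L),
                         c(0L, 0L, 0L, 40L, 60L, 50L),
                         c(35L, 45L, 55L, 0L, 0L, 0L),
                         c(10L, 20L, 30L, 15L, 25L, 20L),
                         c(0L, 0L, 0L, 1800L, 2200L, 2000L)))
  grp <- factor(rep(c("ref", "test"), each = 3), levels = c("ref", "test"))
  sf <- setNames(rep(1, 6), colnames(m))
  res <- nb_wald_test(m, grp, sf, rep(0.05, 5))
  expect_equal(res$flag, c("untestable", "zero_group", "zero_group", "",
                           "zero_group"))
  expect_equal(res$log2fc[1], 0)
  expect_equal(res$p[1], 1)
  expect_true(is.na(res$fdr[1]))
  expect_gt(res$log2fc[2], 1)       # reference empty -> strongly up
  expect_lt(res$log2fc[3], -1)      # test empty -> strongly down
  expect_true(all(abs(res$log2fc) <= 10))
  expect_equal(res$log2fc[5], 10)   # large counts vs empty hit the cap
  expect_true(all(res$wald[-1] == res$log2fc[-1] / res$se[-1]))
  expect_false(any(is.na(res$fdr[2:5])))
})

test_that("large-mean Poisson-limit p-values match a z-test on log counts", {
  # delta-method z-test with known Poisson variance; max relative error
  # 0.04 in the pre-build oracle run, asserted < 0.10
  set.seed(7)
  n <- 200
  y1 <- matrix(rpois(n * 3, 1e4), n)
  y2 <- matrix(rpois(n * 3, 1e4), n)
  cc <- make_counts(cbind(y1, y2))
  grp <- factor(rep(c("ref", "test"), each = 3), levels = c("ref", "test"))
  res <- nb_wald_test(cc, grp, setNames(rep(1, 6), colnames(cc)),
                      rep(1e-8, n))
  z <- (rowMeans(log(y2)) - rowMeans(log(y1))) /
    sqrt(1 / (3 * rowMeans(y1)) + 1 / (3 * rowMeans(y2)))
  pz <- 2 * pnorm(-abs(z))
  expect_lt(max(abs(res$p - pz) / pz), 0.10)
})

test_that("BH adjustment reproduces worked examples and rejects bad input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.05, 0.05)), c(0.05, 0.05))
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.1, NA)))
})

test_that("BH agrees with stats::p.adjust on random vectors", {
  set.seed(4)
  for (k in 1:50) {
    p <- runif(sample(1:150, 1))
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
})

test_that("the full contrast set has the design's shape", {
  sim <- simulate_counts(sim_config(n_genes = 30, seed = 19))
  cons <- run_all_contrasts(sim$counts, sim$samples)
  expect_length(cons, 14L)  # 4 mutants x 3 conditions + 2 CS stress tables
  expect_true(all(c("dsigB_vs_CS_standard", "dsigCDE_vs_CS_highlight",
                    "CS_heat_vs_standard", "CS_highlight_vs_standard")
                  %in% names(cons)))
  for (tab in cons) {
    expect_identical(tab$gene_id, rownames(sim$counts))
    ok <- !is.na(tab$fdr)
    expect_true(all(tab$p >= 0 & tab$p <= 1))
    expect_true(all(tab$fdr[ok] >= tab$p[ok] - 1e-12))
    expect_true(all(tab$fdr[ok] <= 1))
  }

  no_cs <- sim$samples[!(sim$samples$strain == "CS" &
                           sim$samples$condition == "heat"), ]
  expect_error(run_all_contrasts(sim$counts[, no_cs$sample_id], no_cs),
               "heat")
})
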