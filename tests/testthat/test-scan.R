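# A tiny fully informative genoprob object built by hand: one chromosome,
# markers at 0 and 10, no error, everyone observed at both markers.
informative_probs <- function(het) {
  n <- length(het)
  map <- data.frame(chrom = "1", marker = c("m1", "m2"), pos = c(0, 10))
  g <- matrix(rep(as.integer(het), 2), n, 2,
              dimnames = list(sprintf("i%02d", seq_len(n)),
                              c("m1", "m2")))
  compute_genoprob(map, g, error_rate = 0, grid_step = 10)
}

test_that("scan recovers a planted QTL and leaves null chromosomes low", {
  cr <- small_cross(seed = 11, effect = 50)
  probs <- compute_genoprob(cr$sim$map, cr$sim$geno, grid_step = 2)
  sc <- scan_glmm(probs, cr$pheno, quiet = TRUE)
  expect_s3_class(sc, "scanresult")
  expect_true(all(is.finite(sc$lod)) && all(sc$lod >= 0))
  pk <- scan_peaks(sc)
  expect_equal(pk$chrom[1], "2")
  expect_lt(abs(pk$pos[1] - 20), 10)
})

test_that("swapping the two female types leaves every LOD unchanged", {
  cr <- small_cross(seed = 12, n = 50, n_chr = 1)
  probs <- compute_genoprob(cr$sim$map, cr$sim$geno, grid_step = 5)
  sc1 <- scan_glmm(probs, cr$pheno, quiet = TRUE)
  flipped <- cr$pheno
  names(flipped)[2:3] <- c("minutes_cyd", "minutes_mel")
  sc2 <- scan_glmm(probs, flipped, quiet = TRUE)
  expect_equal(sc1$lod, sc2$lod, tolerance = 1e-5)
})

test_that("zero-variance scan equals the closed-form binomial LRT", {
  # four fully informative males: het 9/10 and 8/10, hom 1/10 and 2/10
  het <- c(1, 1, 0, 0)
  probs <- informative_probs(het)
  ph <- data.frame(id = probs$ids, minutes_mel = c(9, 8, 1, 2),
                   minutes_cyd = c(1, 2, 9, 8))
  sc <- scan_glmm(probs, ph, sigma_zero = TRUE, quiet = TRUE)
  oracle <- binom_lrt_lod(ph$minutes_mel, ph$minutes_mel + ph$minutes_cyd, het)
  expect_equal(unique(round(sc$lod, 8)), round(oracle, 8))
  # larger random case
  set.seed(3)
  het2 <- rep(0:1, each = 15)
  probs2 <- informative_probs(het2)
  tot <- 5 + rpois(30, 8)
  mel <- rbinom(30, tot, plogis(-0.5 + het2))
  ph2 <- data.frame(id = probs2$ids, minutes_mel = mel, minutes_cyd = tot - mel)
  sc2 <- scan_glmm(probs2, ph2, sigma_zero = TRUE, quiet = TRUE)
  expect_equal(max(sc2$lod), binom_lrt_lod(mel, tot, het2), tolerance = 1e-6)
})

test_that("nonparametric scan reduces to the rank-sum statistic and handles ties", {
  set.seed(4)
  het <- rep(0:1, c(12, 14))
  probs <- informative_probs(het)
  tot <- rep(10, 26)
  mel <- rbinom(26, tot, plogis(-0.4 + 0.9 * het))
  ph <- data.frame(id = probs$ids, minutes_mel = mel, minutes_cyd = tot - mel)
  sc <- scan_nonparametric(probs, ph, quiet = TRUE)
  kw <- kruskal.test(mel / tot, factor(het))$statistic
  expect_equal(max(sc$lod), unname(kw) / (2 * log(10)), tolerance = 1e-8)
  # constant phenotype gives a flat zero profile
  ph0 <- data.frame(id = probs$ids, minutes_mel = 5, minutes_cyd = 5)
  expect_true(all(scan_nonparametric(probs, ph0, quiet = TRUE)$lod == 0))
})

test_that("GLMM and nonparametric peaks co-localize on a strong QTL", {
  cr <- small_cross(seed = 13, effect = 50)
  probs <- compute_genoprob(cr$sim$map, cr$sim$geno, grid_step = 5)
  g_pk <- scan_peaks(scan_glmm(probs, cr$pheno, quiet = TRUE))
  np_pk <- scan_peaks(scan_nonparametric(probs, cr$pheno, quiet = TRUE))
  expect_equal(g_pk$chrom[1], np_pk$chrom[1])
})

test_that("zero-courtship males are excluded with a message", {
  cr <- small_cross(seed = 14, n = 40, n_chr = 1)
  ph <- cr$pheno
  ph$minutes_mel[1:3] <- 0
  ph$minutes_cyd[1:3] <- 0
  probs <- compute_genoprob(cr$sim$map, cr$sim$geno, grid_step = 10)
  expect_message(sc <- scan_glmm(probs, ph), "excluded")
  expect_equal(attr(sc, "n_used"), 37)
})

test_that("subset scan conditions on the genotype call at a locus", {
  cr <- small_cross(seed = 15, n = 70, n_chr = 2)
  probs <- compute_genoprob(cr$sim$map, cr$sim$geno, grid_step = 10)
  full <- scan_glmm(probs, cr$pheno, quiet = TRUE)
  # conditioning that matches everyone reproduces the full scan
  calls <- genotype_calls(probs, "1", 0)
  if (mean(calls) > 0.5) {
    sub_all <- scan_subset(probs, cr$pheno, "1", 0, "het", quiet = TRUE)
    expect_lt(length(attr(sub_all, "subset_ids")), 71)
  }
  sub_het <- scan_subset(probs, cr$pheno, "2", 20, "het", quiet = TRUE)
  sub_hom <- scan_subset(probs, cr$pheno, "2", 20, "hom", quiet = TRUE)
  expect_equal(length(attr(sub_het, "subset_ids")) +
                 length(attr(sub_hom, "subset_ids")), 70)
  expect_equal(attr(full, "n_used"), 70)
})

test_that("subsetting by a condition every individual meets equals the full scan", {
  cr <- small_cross(seed = 16, n = 30, n_chr = 1)
  probs <- compute_genoprob(cr$sim$map, cr$sim$geno, grid_step = 10)
  # force all calls het at marker 1 by overwriting the genotype column
  g <- cr$sim$geno
  g[, 1] <- 1L
  probs2 <- compute_genoprob(cr$sim$map, g, grid_step = 10)
  full <- scan_glmm(probs2, cr$pheno, quiet = TRUE)
  sub <- scan_subset(probs2, cr$pheno, "1", 0, "het", quiet = TRUE)
  expect_equal(sub$lod, full$lod, tolerance = 1e-6)
  expect_error(scan_subset(probs2, cr$pheno, "1", 0, "hom"),
               "no individuals")
})

test_that("permutation thresholds are monotone, seeded, and grid-consistent", {
  cr <- small_cross(seed = 17, n = 50, n_chr = 2, effect = 0)
  probs <- compute_genoprob(cr$sim$map, cr$sim$geno, grid_step = 10)
  pm <- permutation_threshold(probs, cr$pheno, n_permutations = 30, seed = 5)
  expect_length(pm$max_lods, 30)
  expect_true(all(pm$max_lods >= 0))
  expect_gte(lod_threshold(pm, 0.01), lod_threshold(pm, 0.05))
  expect_gte(lod_threshold(pm, 0.05), lod_threshold(pm, 0.50))
  # alpha -> 1 recovers the minimum of the max-LOD distribution
  expect_equal(lod_threshold(pm, 1), min(pm$max_lods))
  expect_error(lod_threshold(pm, 0), "alpha")
  # same seed, same shuffles
  pm2 <- permutation_threshold(probs, cr$pheno, n_permutations = 30, seed = 5)
  expect_identical(pm$max_lods, pm2$max_lods)
  # a one-chromosome genome can never exceed the full-genome max
  sub <- probs
  keep <- probs$grid$chrom == "1"
  sub$grid <- probs$grid[keep, ]
  sub$prob <- probs$prob[, keep, drop = FALSE]
  pm1 <- permutation_threshold(sub, cr$pheno, n_permutations = 30, seed = 5)
  expect_true(all(pm1$max_lods <= pm$max_lods + 1e-8))
  expect_lte(lod_threshold(pm1, 0.05), lod_threshold(pm, 0.05) + 1e-8)
  # empirical genome-wide P value
  expect_equal(lod_pvalue(pm, min(pm$max_lods)), 1)
  expect_lte(lod_pvalue(pm, max(pm$max_lods) + 1), 0)
})
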