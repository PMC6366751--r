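test_that("penalized LOD identity holds exactly", {
  expect_equal(plod(14.90, 3, 2.99), 5.93)
  expect_equal(plod(0, 0, 2.99), 0)     # empty model
  expect_equal(plod(10, 2, 0), 10)      # no penalty
  expect_error(plod(5, 1, -1), "non-negative")
})

test_that("support intervals track the peak and shrink with the drop", {
  sc <- structure(data.frame(chrom = "5", pos = 0:10,
                             lod = c(1, 2, 4, 6, 5.2, 5, 4.4, 3, 2, 1, 0.5)),
                  class = c("scanresult", "data.frame"))
  iv <- support_interval(sc, "5", drop = 1.5)
  expect_equal(iv, c(3, 5), ignore_attr = TRUE)  # lod >= 6 - 1.5 = 4.5
  expect_equal(attr(iv, "peak"), 3)
  # width is non-increasing in the drop parameter
  widths <- vapply(c(3, 2, 1.5, 1, 0.5), function(d) {
    diff(as.numeric(support_interval(sc, "5", drop = d)))
  }, numeric(1))
  expect_true(all(diff(widths) <= 0))
  # single-point spike: zero-width interval at the peak
  spike <- sc; spike$lod <- c(rep(0, 5), 10, rep(0, 5))
  expect_equal(support_interval(spike, "5"), c(5, 5), ignore_attr = TRUE)
  # flat profile returns the whole chromosome with a warning
  flat <- sc; flat$lod <- rep(2, 11)
  expect_warning(iv_flat <- support_interval(flat, "5"), "flat")
  expect_equal(iv_flat, c(0, 10), ignore_attr = TRUE)
  # LOD ties at the peak break toward the lowest cM
  tied <- sc; tied$lod <- c(0, 0, 6, 0, 0, 6, 0, 0, 0, 0, 0)
  expect_equal(attr(support_interval(tied, "5", drop = 1), "peak"), 2)
})

test_that("effect sizes scale the het-hom contrast by the parental gap", {
  ph <- data.frame(id = sprintf("i%02d", 1:20),
                   minutes_mel = c(rep(2, 10), rep(18, 10)),
                   minutes_cyd = c(rep(18, 10), rep(2, 10)))
  calls <- setNames(rep(c(0L, 1L), each = 10), ph$id)
  es <- effect_size(ph, calls = calls, parental_means = c(0.1, 0.9))
  expect_equal(es$percent_of_parental_difference, 100)  # full parental gap
  # identical class means give 0%
  ph0 <- ph; ph0$minutes_mel <- 10; ph0$minutes_cyd <- 10
  expect_equal(effect_size(ph0, calls = calls)$percent_of_parental_difference, 0)
  # invariant to rescaling everyone's minutes by a common factor
  ph4 <- ph
  ph4$minutes_mel <- ph$minutes_mel * 4
  ph4$minutes_cyd <- ph$minutes_cyd * 4
  es4 <- effect_size(ph4, calls = calls, parental_means = c(0.1, 0.9))
  expect_equal(es4$percent_of_parental_difference,
               es$percent_of_parental_difference)
  # CI bounds ordered around the class mean
  expect_true(all(es$class_means$lower <= es$class_means$weighted_mean &
                  es$class_means$weighted_mean <= es$class_means$upper))
  expect_error(effect_size(ph, calls = calls, parental_means = c(0.5, 0.5)),
               "equal")
  expect_error(effect_size(ph, calls = setNames(rep(1L, 20), ph$id)),
               "both genotype classes")
})

test_that("weighted and unweighted class means differ when information varies", {
  ph <- data.frame(id = c("a", "b", "c", "d"),
                   minutes_mel = c(1, 40, 0, 10),
                   minutes_cyd = c(1, 10, 10, 10))
  calls <- setNames(c(1L, 1L, 0L, 0L), ph$id)
  w <- effect_size(ph, calls = calls, weighted = TRUE)
  u <- effect_size(ph, calls = calls, weighted = FALSE)
  expect_equal(w$class_means$weighted_mean[2], 41 / 52)
  expect_equal(u$class_means$unweighted_mean[2], mean(c(0.5, 0.8)))
  expect_false(isTRUE(all.equal(w$percent_of_parental_difference,
                                u$percent_of_parental_difference)))
})

test_that("multi-QTL model drops absent interactions and reports drop tests", {
  cfg <- sim_config(
    n_individuals = 150,
    chromosomes = data.frame(name = c("1", "2"), length_cM = c(40, 40)),
    marker_spacing = 10, genotyping_error_rate = 0, missing_rate = 0,
    qtl_specs = data.frame(chrom = c("1", "2"), pos = c(10, 30),
                           effect = c(35, 35)),
    overdispersion_sd = 0.4, minutes_per_trial = 3, seed = 23)
  sim <- simulate_backcross(cfg)
  ph <- simulate_preference_phenotypes(sim, cfg)
  probs <- compute_genoprob(sim$map, sim$geno, grid_step = 10)
  loci <- data.frame(chrom = c("1", "2"), pos = c(10, 30))
  fit <- fit_multiqtl(probs, ph, loci, threshold = 2.99, quiet = TRUE)
  expect_s3_class(fit, "qtl_model")
  # additive truth: the pairwise interaction should be eliminated
  expect_equal(nrow(fit$interactions_retained), 0)
  # pLOD identity to machine precision
  expect_equal(fit$plod, fit$lod - 2.99 * 2)
  # both planted QTLs are supported by the drop-one tests
  expect_equal(nrow(fit$drop_table), 2)
  expect_true(all(fit$drop_table$p < 0.05))
  expect_true(all(fit$drop_table$two_dlnl > 0))
  # dropping a QTL worsens the penalized score of the model
  expect_true(all(fit$drop_table$delta_plod < 0))
  expect_error(fit_multiqtl(probs, ph, rbind(loci, loci[1, ]), 2.99),
               "distinct")
})

test_that("group comparison flags real differences and not copies", {
  cr <- small_cross(seed = 24, n = 40, n_chr = 1)
  same <- compare_groups(cr$pheno, cr$pheno)
  expect_lt(same$two_dlnl, 1e-3)
  expect_equal(same$df, 1)
  expect_gt(same$p, 0.9)
  # planted logit gap of 2 between groups of 30
  set.seed(25)
  make_group <- function(base, tag) {
    tot <- 4 + rpois(30, 8)
    mel <- rbinom(30, tot, plogis(base + rnorm(30, 0, 0.5)))
    data.frame(id = sprintf("%s%02d", tag, 1:30), minutes_mel = mel,
               minutes_cyd = tot - mel)
  }
  hits <- vapply(1:20, function(i) {
    compare_groups(make_group(-1, "a"), make_group(1, "b"))$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
  empty <- data.frame(id = "x", minutes_mel = 0, minutes_cyd = 0)
  expect_error(compare_groups(cr$pheno, empty), "no courtship")
})

test_that("per-cue F tests match the textbook one-way ANOVA on a hand-built table", {
  # eight males, one locus, balanced genotype groups
  ph <- data.frame(id = sprintf("m%d", 1:8),
                   minutes_mel = c(1, 2, 2, 3, 6, 7, 7, 8),
                   minutes_cyd = c(5, 5, 6, 6, 2, 2, 1, 1),
                   n_trials = rep(4, 8))
  calls <- matrix(rep(0:1, each = 4), ncol = 1,
                  dimnames = list(NULL, "q1"))
  res <- per_cue_effects(calls, ph, n_tests = 2)
  y <- sqrt(ph$minutes_mel / ph$n_trials)
  g <- factor(calls[, 1])
  ssb <- sum(tapply(y, g, length) * (tapply(y, g, mean) - mean(y))^2)
  ssw <- sum((y - ave(y, g))^2)
  f_oracle <- (ssb / 1) / (ssw / 6)
  got <- res$tests[res$tests$species == "mel" & res$tests$locus == "q1", ]
  expect_equal(got$F, f_oracle, tolerance = 1e-10)
  expect_equal(got$df2, 6)
  expect_equal(got$p_bonferroni, min(1, got$p * 2))
  # Levene output has the right shape
  expect_equal(nrow(res$levene), 2)
  expect_true(all(res$levene$p >= 0 & res$levene$p <= 1))
})

test_that("constant per-cue response yields F = 0 and P = 1", {
  ph <- data.frame(id = sprintf("m%d", 1:8), minutes_mel = 4, minutes_cyd = 4,
                   n_trials = 2)
  calls <- matrix(rep(0:1, 4), ncol = 1, dimnames = list(NULL, "q1"))
  res <- per_cue_effects(calls, ph, n_tests = 6)
  expect_true(all(res$tests$F == 0))
  expect_true(all(res$tests$p == 1))
})

test_that("zero-trial males are excluded from per-cue models with a warning", {
  ph <- data.frame(id = sprintf("m%d", 1:9),
                   minutes_mel = c(1, 2, 2, 3, 6, 7, 7, 8, 5),
                   minutes_cyd = c(5, 5, 6, 6, 2, 2, 1, 1, 3),
                   n_trials = c(rep(4, 8), 0))
  calls <- matrix(c(rep(0:1, each = 4), 1L), ncol = 1,
                  dimnames = list(NULL, "q1"))
  expect_warning(res <- per_cue_effects(calls, ph), "zero trials")
  expect_equal(res$tests$df2[1], 6)
})
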