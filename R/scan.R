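# Align a phenotype table with a genoprob object: common individuals,
# zero-courtship males excluded (they carry no information about the
# courtship proportion).
align_scan_data <- function(probs, pheno, quiet = FALSE) {
  need <- c("id", "minutes_mel", "minutes_cyd")
  if (!all(need %in% names(pheno))) {
    stop("pheno must have columns ", paste(need, collapse = ", "))
  }
  pheno <- pheno[pheno$id %in% probs$ids, , drop = FALSE]
  zero <- pheno$minutes_mel + pheno$minutes_cyd == 0
  if (any(zero) && !quiet) {
    message(sum(zero), " individual(s) with no courtship excluded from scan")
  }
  pheno <- pheno[!zero, , drop = FALSE]
  if (nrow(pheno) == 0) stop("no usable individuals shared by pheno and probs")
  ridx <- match(pheno$id, probs$ids)
  list(y = pheno$minutes_mel,
       n = pheno$minutes_mel + pheno$minutes_cyd,
       ids = pheno$id, ridx = ridx)
}

new_scanresult <- function(grid, lod, n_used, extra = list()) {
  out <- data.frame(chrom = grid$chrom, pos = grid$pos, lod = lod,
                    stringsAsFactors = FALSE)
  attr(out, "n_used") <- n_used
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("scanresult", "data.frame")
  out
}

#' Binomial mixed-model genome scan for a courtship-proportion QTL
#'
#' At every grid position, fits a binomial GLMM for the number of courtship
#' minutes toward *H. melpomene* out of the male's total, with logit link,
#' the P(het) genotype probability as the covariate (regression on genotype
#' probabilities, in the spirit of Haley-Knott regression), and an
#' individual-level normal random intercept absorbing overdispersion. The
#' LOD score is \eqn{(\ell_{full} - \ell_{null}) / \ln 10}, where the null
#' model drops the genotype covariate and is fitted once.
#'
#' @param probs a [compute_genoprob()] result.
#' @param pheno data frame with columns `id`, `minutes_mel`, `minutes_cyd`
#'   (and optionally `n_trials`). Males with zero total courtship are
#'   excluded.
#' @param n_nodes Gauss-Hermite nodes for the marginal likelihood.
#' @param sigma_zero pin the random-intercept variance to zero, reducing the
#'   scan to a plain binomial-GLM (Haley-Knott-style) regression on genotype
#'   probabilities; mainly for comparison and testing.
#' @param quiet suppress the exclusion message.
#' @return a `scanresult` data frame (`chrom`, `pos`, `lod`) with attributes
#'   `n_used`, `loglik_null`, and `not_converged` (grid indices whose full
#'   fit did not converge; their LOD is from the best fit achieved).
#' @export
scan_glmm <- function(probs, pheno, n_nodes = 21, sigma_zero = FALSE,
                      quiet = FALSE) {
  dat <- align_scan_data(probs, pheno, quiet = quiet)
  fitter <- if (sigma_zero) {
    function(y, n, X = NULL, start = NULL) fit_binom_fixed(y, n, X)
  } else {
    function(y, n, X = NULL, start = NULL) {
      fit_binom_olre(y, n, X, start = start, n_nodes = n_nodes)
    }
  }
  null_fit <- fitter(dat$y, dat$n)
  start <- if (sigma_zero) NULL else c(null_fit$par[1], 0, null_fit$par[2])
  G <- nrow(probs$grid)
  lod <- numeric(G)
  bad <- integer(0)
  X <- matrix(1, length(dat$y), 2,
              dimnames = list(NULL, c("(Intercept)", "p_het")))
  warm <- start
  prev_chrom <- ""
  for (g in seq_len(G)) {
    x <- probs$prob[dat$ridx, g]
    if (stats::sd(x) < 1e-10) { lod[g] <- 0; next }
    X[, 2] <- x
    # warm-start from the neighbouring position on the same chromosome
    if (probs$grid$chrom[g] != prev_chrom) warm <- start
    prev_chrom <- probs$grid$chrom[g]
    fit <- fitter(dat$y, dat$n, X, start = warm)
    if (!fit$converged) bad <- c(bad, g)
    if (!sigma_zero) warm <- fit$par
    lod[g] <- max(0, (fit$loglik - null_fit$loglik) / log(10))
  }
  new_scanresult(probs$grid, lod, length(dat$y),
                 list(loglik_null = null_fit$loglik, not_converged = bad,
                      model = "glmm"))
}

#' Nonparametric (rank-based) genome scan
#'
#' A Kruskal-Wallis-type interval-mapping scan extended to genotype
#' probabilities: each male's courtship proportion is midranked, and at each
#' position the squared standardized linear rank statistic
#' \deqn{H = (n-1)\,\frac{\left[\sum_i (p_i - \bar p)(R_i - \bar R)\right]^2}
#'   {\sum_i (p_i - \bar p)^2 \sum_i (R_i - \bar R)^2}}
#' is computed with \eqn{p_i} the P(het) covariate. With fully informative
#' genotypes this is the two-group Kruskal-Wallis (equivalently Wilcoxon
#' rank-sum) statistic with midrank tie correction. Reported on the LOD
#' scale as \eqn{H / (2\ln 10)}.
#'
#' @inheritParams scan_glmm
#' @return a `scanresult` data frame.
#' @export
scan_nonparametric <- function(probs, pheno, quiet = FALSE) {
  dat <- align_scan_data(probs, pheno, quiet = quiet)
  prop <- dat$y / dat$n
  R <- rank(prop)  # midranks for ties
  Rc <- R - mean(R)
  ssR <- sum(Rc^2)
  n <- length(R)
  G <- nrow(probs$grid)
  lod <- numeric(G)
  if (ssR > 0) for (g in seq_len(G)) {
    x <- probs$prob[dat$ridx, g]
    xc <- x - mean(x)
    ssx <- sum(xc^2)
    if (ssx < 1e-12) next
    H <- (n - 1) * sum(xc * Rc)^2 / (ssx * ssR)
    lod[g] <- H / (2 * log(10))
  }
  new_scanresult(probs$grid, lod, n, list(model = "np"))
}

#' Genome scan restricted to individuals with a given genotype at a locus
#'
#' Re-runs [scan_glmm()] on the subset of males whose maximum-posterior
#' genotype call at the conditioning locus matches `genotype`. Used to probe
#' interactions between QTLs (e.g. scanning het and hom carriers at a major
#' locus separately).
#'
#' @inheritParams scan_glmm
#' @param chrom,pos conditioning locus.
#' @param genotype `"hom"` or `"het"` (or 0/1).
#' @return a `scanresult` data frame; attribute `subset_ids` lists the males
#'   used.
#' @export
scan_subset <- function(probs, pheno, chrom, pos, genotype,
                        n_nodes = 21, quiet = FALSE) {
  if (is.character(genotype)) {
    genotype <- match(match.arg(genotype, c("hom", "het")), c("hom", "het")) - 1L
  }
  calls <- genotype_calls(probs, chrom, pos)
  keep <- probs$ids[!is.na(calls) & calls == genotype]
  if (!length(keep)) stop("no individuals with the requested genotype")
  sub <- probs
  ki <- match(keep, probs$ids)
  sub$prob <- probs$prob[ki, , drop = FALSE]
  sub$ids <- keep
  out <- scan_glmm(sub, pheno[pheno$id %in% keep, , drop = FALSE],
                   n_nodes = n_nodes, quiet = quiet)
  attr(out, "subset_ids") <- keep
  out
}

#' Genome-wide significance threshold by phenotype permutation
#'
#' Repeatedly shuffles whole phenotype rows (`minutes_mel`, `minutes_cyd`,
#' `n_trials` kept together, so the per-male trial structure and the
#' random-intercept grouping are preserved) across individuals, re-runs the
#' genome scan, and records the genome-wide maximum LOD. The significance
#' threshold at level `alpha` is the `1 - alpha` empirical quantile of the
#' max-LOD distribution. The permutation orders are drawn up front from the
#' seed, so the same seed gives the same shuffles regardless of the grid.
#'
#' @inheritParams scan_glmm
#' @param n_permutations number of permutations (>= 1).
#' @param seed integer seed for the permutation orders.
#' @param model `"glmm"` (default) or `"np"`.
#' @return object of class `permresult`: list with `max_lods`, `n_permutations`,
#'   `seed`, `model`.
#' @export
permutation_threshold <- function(probs, pheno, n_permutations = 1000,
                                  seed = 1L, model = c("glmm", "np"),
                                  n_nodes = 21) {
  model <- match.arg(model)
  if (n_permutations < 1) stop("need at least one permutation")
  dat <- align_scan_data(probs, pheno, quiet = TRUE)
  pheno_used <- data.frame(id = dat$ids, minutes_mel = dat$y,
                           minutes_cyd = dat$n - dat$y,
                           stringsAsFactors = FALSE)
  n <- nrow(pheno_used)
  set.seed(seed)
  orders <- replicate(n_permutations, sample.int(n), simplify = FALSE)
  max_lods <- vapply(orders, function(ord) {
    ph <- pheno_used
    ph$id <- pheno_used$id[ord]
    sc <- if (model == "glmm") {
      scan_glmm(probs, ph, n_nodes = n_nodes, quiet = TRUE)
    } else {
      scan_nonparametric(probs, ph, quiet = TRUE)
    }
    max(sc$lod)
  }, numeric(1))
  structure(list(max_lods = max_lods, n_permutations = n_permutations,
                 seed = seed, model = model),
            class = "permresult")
}

#' Read a LOD threshold off a permutation result
#'
#' The `1 - alpha` empirical quantile of the permutation max-LOD
#' distribution; monotone non-increasing in `alpha`.
#'
#' @param perm a [permutation_threshold()] result.
#' @param alpha genome-wide significance level in (0, 1].
#' @return LOD threshold (scalar, vectorized over `alpha`).
#' @export
lod_threshold <- function(perm, alpha = 0.05) {
  stopifnot(inherits(perm, "permresult"))
  if (any(alpha <= 0 | alpha > 1)) stop("alpha must be in (0, 1]")
  unname(stats::quantile(perm$max_lods, 1 - alpha, type = 7))
}

#' Empirical genome-wide P value for an observed LOD
#'
#' Fraction of permutation max-LODs at or above the observed LOD.
#'
#' @inheritParams lod_threshold
#' @param lod observed LOD score.
#' @export
lod_pvalue <- function(perm, lod) {
  stopifnot(inherits(perm, "permresult"))
  mean(perm$max_lods >= lod)
}

#' Peak positions of a genome scan
#'
#' Per-chromosome maximum LOD; ties broken toward the lowest cM.
#'
#' @param scan a `scanresult`.
#' @return data frame `chrom`, `pos`, `lod`, one row per chromosome, sorted
#'   by decreasing LOD.
#' @export
scan_peaks <- function(scan) {
  parts <- split(seq_len(nrow(scan)),
                 factor(scan$chrom, levels = unique(scan$chrom)))
  out <- do.call(rbind, lapply(parts, function(idx) {
    best <- idx[which(scan$lod[idx] == max(scan$lod[idx]))]
    best <- best[which.min(scan$pos[best])]
    data.frame(chrom = scan$chrom[best], pos = scan$pos[best],
               lod = scan$lod[best], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(-out$lod), ]
}
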