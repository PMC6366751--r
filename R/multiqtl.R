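#' Penalized LOD score of a multi-QTL model
#'
#' \deqn{pLOD_a(\gamma) = LOD(\gamma) - T\,|\gamma|}
#' where \eqn{|\gamma|} is the number of QTLs in model \eqn{\gamma} and `T`
#' is the genome-wide permutation threshold acting as a per-QTL penalty. The
#' empty model scores 0.
#'
#' @param lod model LOD score versus the null (no-QTL) model.
#' @param n_qtl number of QTLs in the model.
#' @param threshold penalty `T` (the permutation LOD threshold).
#' @examples
#' plod(14.90, 3, 2.99)  # 5.93
#' @export
plod <- function(lod, n_qtl, threshold) {
  if (any(threshold < 0)) stop("threshold must be non-negative")
  lod - threshold * n_qtl
}

# Design matrix of P(het) covariates at the requested loci, plus the
# requested pairwise interaction columns.
multiqtl_design <- function(probs, ridx, loci, interactions) {
  q <- nrow(loci)
  main <- matrix(numeric(0), nrow = length(ridx), ncol = 0)
  for (k in seq_len(q)) {
    main <- cbind(main,
                  probs$prob[ridx, grid_index(probs, loci$chrom[k], loci$pos[k])])
  }
  if (q > 0) colnames(main) <- paste0("q", seq_len(q))
  X <- cbind("(Intercept)" = 1, main)
  if (nrow(interactions)) {
    for (i in seq_len(nrow(interactions))) {
      a <- interactions$a[i]; b <- interactions$b[i]
      X <- cbind(X, main[, a] * main[, b])
      colnames(X)[ncol(X)] <- paste0("q", a, ":q", b)
    }
  }
  X
}

#' Fit and simplify a multi-QTL binomial mixed model
#'
#' Fits the saturated binomial GLMM for relative courtship time with the
#' P(het) genotype probabilities at the given loci as explanatory variables,
#' all pairwise interactions, and the individual-level random intercept
#' (always retained). The model is simplified stepwise by likelihood-ratio
#' tests: the interactions are tested jointly first, then singly, removing
#' nonsignificant terms (at `alpha_drop`); main effects are retained. For
#' the retained model the function reports its LOD versus the no-QTL null,
#' its penalized LOD `pLODa = LOD - T |gamma|`, and, for each QTL in turn,
#' the drop-one statistics: `2dlnL`, its P value, and the change in pLODa
#' against the model eliminating that QTL.
#'
#' @inheritParams scan_glmm
#' @param loci data frame with columns `chrom`, `pos` (distinct loci).
#' @param threshold permutation penalty `T` used in the penalized LOD.
#' @param alpha_drop significance level for dropping interaction terms.
#' @return object of class `qtl_model`: list with `loci`, `coef`, `sigma`,
#'   `loglik`, `lod`, `plod`, `interactions_retained`,
#'   `interaction_tests`, and `drop_table` (per-QTL `lod`, `delta_plod`,
#'   `two_dlnl`, `p`).
#' @export
fit_multiqtl <- function(probs, pheno, loci, threshold, alpha_drop = 0.05,
                         n_nodes = 21, quiet = FALSE) {
  loci$chrom <- as.character(loci$chrom)
  key <- paste(loci$chrom, loci$pos)
  if (anyDuplicated(key)) stop("loci must be distinct positions")
  q <- nrow(loci)
  dat <- align_scan_data(probs, pheno, quiet = quiet)
  fit_with <- function(interactions) {
    X <- multiqtl_design(probs, dat$ridx, loci, interactions)
    fit_binom_olre(dat$y, dat$n, X, n_nodes = n_nodes)
  }
  pairs <- if (q >= 2) {
    idx <- utils::combn(q, 2)
    data.frame(a = idx[1, ], b = idx[2, ])
  } else data.frame(a = integer(0), b = integer(0))
  no_int <- pairs[0, ]

  fit_add <- fit_with(no_int)
  interaction_tests <- NULL
  retained <- no_int
  if (nrow(pairs)) {
    fit_sat <- fit_with(pairs)
    joint <- lrt_fits(fit_sat, fit_add, df = nrow(pairs))
    interaction_tests <- data.frame(term = "all pairwise",
                                    two_dlnl = joint$stat, df = joint$df,
                                    p = joint$p)
    if (joint$p <= alpha_drop) {
      # drop interactions singly, least significant first
      retained <- pairs
      repeat {
        if (!nrow(retained)) break
        cur <- fit_with(retained)
        single <- vapply(seq_len(nrow(retained)), function(i) {
          red <- fit_with(retained[-i, , drop = FALSE])
          lrt_fits(cur, red, 1)$p
        }, numeric(1))
        worst <- which.max(single)
        if (single[worst] > alpha_drop) {
          retained <- retained[-worst, , drop = FALSE]
        } else break
      }
    }
  }
  fit_final <- fit_with(retained)
  null_fit <- fit_binom_olre(dat$y, dat$n, n_nodes = n_nodes)
  lod_final <- max(0, (fit_final$loglik - null_fit$loglik) / log(10))
  plod_final <- plod(lod_final, q, threshold)

  drop_table <- do.call(rbind, lapply(seq_len(q), function(k) {
    keep_int <- retained[retained$a != k & retained$b != k, , drop = FALSE]
    # re-index interactions after removing locus k
    remap <- function(j) j - (j > k)
    keep_int <- data.frame(a = remap(keep_int$a), b = remap(keep_int$b))
    X <- multiqtl_design(probs, dat$ridx, loci[-k, , drop = FALSE], keep_int)
    fit_red <- fit_binom_olre(dat$y, dat$n, X, n_nodes = n_nodes)
    df <- 1L + sum(retained$a == k | retained$b == k)
    lr <- lrt_fits(fit_final, fit_red, df)
    lod_red <- max(0, (fit_red$loglik - null_fit$loglik) / log(10))
    data.frame(chrom = loci$chrom[k], pos = loci$pos[k],
               lod_reduced = lod_red,
               delta_plod = plod(lod_red, q - 1, threshold) - plod_final,
               two_dlnl = lr$stat, df = lr$df, p = lr$p,
               stringsAsFactors = FALSE)
  }))

  structure(list(loci = loci, coef = fit_final$coef, sigma = fit_final$sigma,
                 loglik = fit_final$loglik, loglik_null = null_fit$loglik,
                 lod = lod_final, plod = plod_final, threshold = threshold,
                 n_used = length(dat$y),
                 interactions_retained = retained,
                 interaction_tests = interaction_tests,
                 drop_table = drop_table),
            class = "qtl_model")
}

#' @export
print.qtl_model <- function(x, ...) {
  cat("Multi-QTL binomial mixed model (", nrow(x$loci), " QTLs, n = ",
      x$n_used, ")\n", sep = "")
  cat("  LOD =", format(x$lod, digits = 4),
      " pLODa =", format(x$plod, digits = 4),
      " (T =", x$threshold, ")\n")
  if (nrow(x$interactions_retained)) {
    cat("  retained interactions:",
        paste0("q", x$interactions_retained$a, ":q",
               x$interactions_retained$b, collapse = ", "), "\n")
  } else cat("  all pairwise interactions eliminated\n")
  cat("  drop-one tests:\n")
  print(x$drop_table, row.names = FALSE)
  invisible(x)
}

#' LOD support interval around a chromosome's scan peak
#'
#' The smallest contiguous interval containing the per-chromosome LOD peak
#' over which the LOD stays within `drop` units of the maximum (default 1.5,
#' the conventional approximate confidence region for QTL location). Ties at
#' the peak are broken toward the lowest cM.
#'
#' @param scan a `scanresult`.
#' @param chrom chromosome name.
#' @param drop LOD drop defining the interval.
#' @return numeric `c(low, high)` in cM, with attributes `peak` and
#'   `peak_lod`. A flat profile returns the whole chromosome with a warning.
#' @export
support_interval <- function(scan, chrom, drop = 1.5) {
  idx <- which(scan$chrom == as.character(chrom))
  if (!length(idx)) stop("chromosome not in scan: ", chrom)
  lod <- scan$lod[idx]
  pos <- scan$pos[idx]
  o <- order(pos)
  lod <- lod[o]; pos <- pos[o]
  if (max(lod) - min(lod) < 1e-12) {
    warning("flat LOD profile; returning the whole chromosome")
    out <- c(min(pos), max(pos))
    attr(out, "peak") <- pos[1]; attr(out, "peak_lod") <- lod[1]
    return(out)
  }
  pk <- which(lod == max(lod))[1]
  keep <- lod >= max(lod) - drop
  lo <- pk
  while (lo > 1 && keep[lo - 1]) lo <- lo - 1
  hi <- pk
  while (hi < length(keep) && keep[hi + 1]) hi <- hi + 1
  out <- c(pos[lo], pos[hi])
  attr(out, "peak") <- pos[pk]
  attr(out, "peak_lod") <- lod[pk]
  out
}

#' QTL effect size as a percentage of the parental difference
#'
#' Classifies males as hom or het at a locus (maximum-posterior call, with
#' calls of P(het) in `[0.45, 0.55]` excluded as ambiguous, unless explicit
#' calls are supplied, e.g. inferred from a linked dominant color-pattern
#' marker), computes the mean courtship proportion of each class, and scales
#' the het-hom contrast by the parental-species gap:
#' \deqn{\%\;=\;100\,\frac{\bar p_{het} - \bar p_{hom}}
#'   {\bar p_{mel} - \bar p_{cyd}}}
#' Class means weight males by their total courtship minutes (pooled
#' proportion), reflecting the unequal information per male; unweighted
#' per-male means are also reported. 95% CIs are a normal approximation on
#' the log-odds scale of the pooled class proportion.
#'
#' @param pheno phenotype data frame (`id`, `minutes_mel`, `minutes_cyd`).
#' @param calls named 0/1 vector of genotype calls; if `NULL`, derived from
#'   `probs` at `chrom`/`pos`.
#' @param probs,chrom,pos locus specification used when `calls` is `NULL`.
#' @param parental_means `c(cydno, melpomene)` mean courtship proportions.
#' @param weighted use minutes-weighted class means for the percentage
#'   (default) or plain per-male means.
#' @return object of class `effect_estimate`: list with `class_means` (per
#'   genotype: n, weighted and unweighted mean, 95% CI),
#'   `percent_of_parental_difference`, `parental_means`, `locus`.
#' @export
effect_size <- function(pheno, calls = NULL, probs = NULL, chrom = NULL,
                        pos = NULL, parental_means = c(0.05, 0.95),
                        weighted = TRUE) {
  gap <- parental_means[2] - parental_means[1]
  if (gap == 0) stop("parental means are equal; effect scale undefined")
  if (is.null(calls)) {
    if (is.null(probs)) stop("supply calls or probs + chrom/pos")
    calls <- genotype_calls(probs, chrom, pos, drop_ambiguous = TRUE)
  }
  df <- pheno[match(names(calls), pheno$id), , drop = FALSE]
  tot <- df$minutes_mel + df$minutes_cyd
  ok <- !is.na(calls) & !is.na(tot) & tot > 0
  df <- df[ok, , drop = FALSE]; g <- calls[ok]; tot <- tot[ok]
  if (length(unique(g)) < 2) stop("both genotype classes must be represented")
  cls <- lapply(c(hom = 0, het = 1), function(k) {
    y <- sum(df$minutes_mel[g == k]); n <- sum(tot[g == k])
    pw <- y / n
    se <- sqrt(1 / max(y, 0.5) + 1 / max(n - y, 0.5))
    ci <- stats::plogis(stats::qlogis(pw) + c(-1, 1) * 1.96 * se)
    data.frame(n_males = sum(g == k), weighted_mean = pw,
               unweighted_mean = mean(df$minutes_mel[g == k] / tot[g == k]),
               lower = ci[1], upper = ci[2])
  })
  cm <- do.call(rbind, cls)
  cm <- cbind(genotype = c("hom", "het"), cm)
  mean_col <- if (weighted) "weighted_mean" else "unweighted_mean"
  pct <- 100 * (cm[[mean_col]][2] - cm[[mean_col]][1]) / gap
  structure(list(class_means = cm,
                 percent_of_parental_difference = pct,
                 parental_means = parental_means,
                 locus = if (!is.null(chrom)) list(chrom = chrom, pos = pos),
                 weighted = weighted),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat("QTL effect estimate\n")
  print(x$class_means, row.names = FALSE)
  cat(sprintf("  %% of parental difference: %.1f\n",
              x$percent_of_parental_difference))
  invisible(x)
}

#' Compare mean courtship preference of two groups of males
#'
#' Likelihood-ratio test from a binomial mixed model (individual-level
#' random intercept) with a group factor versus an intercept-only model.
#'
#' @param pheno_a,pheno_b phenotype data frames for the two groups.
#' @param n_nodes quadrature nodes.
#' @return list with `two_dlnl`, `df` (1), `p`.
#' @export
compare_groups <- function(pheno_a, pheno_b, n_nodes = 21) {
  check <- function(ph, lab) {
    if (nrow(ph) == 0 || sum(ph$minutes_mel + ph$minutes_cyd) == 0) {
      stop("group ", lab, " has no courtship data")
    }
  }
  check(pheno_a, "A"); check(pheno_b, "B")
  ph <- rbind(pheno_a[c("id", "minutes_mel", "minutes_cyd")],
              pheno_b[c("id", "minutes_mel", "minutes_cyd")])
  tot <- ph$minutes_mel + ph$minutes_cyd
  grp <- rep(c(0, 1), c(nrow(pheno_a), nrow(pheno_b)))
  keep <- tot > 0
  y <- ph$minutes_mel[keep]; n <- tot[keep]; grp <- grp[keep]
  X <- cbind("(Intercept)" = 1, group = grp)
  full <- fit_binom_olre(y, n, X, n_nodes = n_nodes)
  null <- fit_binom_olre(y, n, n_nodes = n_nodes)
  lr <- lrt_fits(full, null, 1)
  list(two_dlnl = lr$stat, df = lr$df, p = lr$p)
}

#' Per-cue post hoc QTL effects on courtship toward each female type
#'
#' Models the square-root-transformed courtship minutes per trial toward
#' each female type separately as a linear function of the genotypes at the
#' mapped QTLs: marginal (drop-one) F tests per locus, Bonferroni-corrected
#' for the `n_tests` tests (default 6 = 3 loci x 2 female types), plus
#' Levene homogeneity-of-variance checks of the residuals across genotype
#' groups (number of heterozygous loci per male).
#'
#' @param calls matrix or data frame of 0/1 genotype calls, one column per
#'   locus, rows matching `pheno$id` order or named.
#' @param pheno phenotype data frame with `minutes_mel`, `minutes_cyd`,
#'   `n_trials`; males with zero trials are excluded with a warning.
#' @param n_tests Bonferroni multiplier.
#' @return list with `tests` (locus x species F table with raw and adjusted
#'   P) and `levene` (per species F, df, P).
#' @export
per_cue_effects <- function(calls, pheno, n_tests = 6) {
  calls <- as.matrix(calls)
  if (is.null(colnames(calls))) colnames(calls) <- paste0("q", seq_len(ncol(calls)))
  if (nrow(calls) != nrow(pheno)) stop("calls and pheno must align by row")
  bad <- is.na(pheno$n_trials) | pheno$n_trials == 0
  if (any(bad)) {
    warning(sum(bad), " male(s) with zero trials excluded")
    pheno <- pheno[!bad, , drop = FALSE]
    calls <- calls[!bad, , drop = FALSE]
  }
  species <- c(cyd = "minutes_cyd", mel = "minutes_mel")
  tests <- list(); levene <- list()
  grp <- factor(rowSums(calls))
  for (sp in names(species)) {
    y <- sqrt(pheno[[species[sp]]] / pheno$n_trials)
    dat <- data.frame(y = y, calls)
    fit <- stats::lm(y ~ ., data = dat)
    if (stats::var(y) < 1e-12) {
      tests[[sp]] <- data.frame(locus = colnames(calls), species = sp,
                                F = 0, df1 = 1,
                                df2 = fit$df.residual, p = 1,
                                p_bonferroni = 1, stringsAsFactors = FALSE)
    } else {
      d1 <- stats::drop1(fit, test = "F")
      rows <- match(colnames(calls), rownames(d1))
      tests[[sp]] <- data.frame(locus = colnames(calls), species = sp,
                                F = d1$`F value`[rows], df1 = d1$Df[rows],
                                df2 = fit$df.residual,
                                p = d1$`Pr(>F)`[rows],
                                p_bonferroni = pmin(1, d1$`Pr(>F)`[rows] * n_tests),
                                stringsAsFactors = FALSE)
    }
    lev <- car::leveneTest(stats::residuals(fit), grp, center = stats::median)
    levene[[sp]] <- data.frame(species = sp, F = lev$`F value`[1],
                               df1 = lev$Df[1], df2 = lev$Df[2],
                               p = lev$`Pr(>F)`[1])
  }
  list(tests = do.call(rbind, c(tests, make.row.names = FALSE)),
       levene = do.call(rbind, c(levene, make.row.names = FALSE)))
}
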