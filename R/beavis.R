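#' Simulate significance-conditional inflation of QTL effects (Beavis effect)
#'
#' For each "true" effect size on a grid (percent of the parental
#' difference), simulates replicate courtship phenotype sets on a fixed
#' genotype column at the focal locus, computes the locus LOD score from the
#' binomial mixed model, flags replicates reaching the genome-wide
#' significance threshold, and records the estimated effect of every
#' replicate using the same minutes-weighted estimator as [effect_size()].
#' Comparing estimates among significant runs to the full distribution
#' quantifies the winner's-curse inflation of reported QTL effects at the
#' study's sample size. Significance is assessed at the focal locus against
#' the supplied genome-wide threshold rather than by re-scanning the genome
#' in every replicate.
#'
#' @param het 0/1 vector of het indicators at the focal locus (real calls or
#'   a simulated column); must contain both classes.
#' @param effects grid of true effect sizes, percent of the parental
#'   difference (default 5-40% in steps of 5).
#' @param n_reps replicates per effect size.
#' @param threshold genome-wide LOD significance threshold.
#' @param parental_means,overdispersion_sd,trial_rate,minutes_per_trial
#'   phenotype-generator parameters, as in [sim_config()].
#' @param n_nodes quadrature nodes for the per-replicate model fits.
#' @param seed integer seed; per-replicate seeds are drawn from it.
#' @return object of class `beavis_grid`: list with `records` (data frame
#'   `true_effect`, `est_effect`, `lod`, `significant`), `threshold`,
#'   `n_reps`, `seed`.
#' @export
run_beavis <- function(het, effects = seq(5, 40, by = 5), n_reps = 1000,
                       threshold = 2.99, parental_means = c(0.05, 0.95),
                       overdispersion_sd = 0.8, trial_rate = 4.3,
                       minutes_per_trial = 1.65, n_nodes = 15, seed = 1L) {
  het <- as.integer(het)
  if (length(unique(het)) < 2) stop("focal genotype column is monomorphic")
  if (any(effects < 0 | effects > 100)) stop("effects are percentages in [0, 100]")
  if (n_reps < 1) stop("n_reps must be >= 1")
  n <- length(het)
  ids <- sprintf("I%04d", seq_len(n))
  pm <- parental_means
  gap <- pm[2] - pm[1]
  set.seed(seed)
  total_runs <- length(effects) * n_reps
  rep_seeds <- sample.int(.Machine$integer.max, total_runs)
  gh <- gh_rule(n_nodes)
  X <- cbind(1, het)

  run <- 0L
  rec <- vector("list", total_runs)
  for (eff in effects) {
    shift <- eff / 100 * gap
    base <- mean(pm) - shift / 2
    mu <- vapply(pmin(pmax(c(base, base + shift), 1e-4), 1 - 1e-4),
                 logit_normal_location, numeric(1), sd = overdispersion_sd)
    for (r in seq_len(n_reps)) {
      run <- run + 1L
      set.seed(rep_seeds[run])
      u <- stats::rnorm(n, 0, overdispersion_sd)
      p <- stats::plogis(mu[het + 1] + u)
      n_trials <- 1L + stats::rpois(n, trial_rate)
      tot <- stats::rpois(n, minutes_per_trial * n_trials)
      mel <- stats::rbinom(n, tot, p)
      ok <- tot > 0
      null_fit <- fit_binom_olre(mel[ok], tot[ok], n_nodes = n_nodes)
      full_fit <- fit_binom_olre(mel[ok], tot[ok], X[ok, , drop = FALSE],
                                 start = c(null_fit$par[1], 0, null_fit$par[2]),
                                 n_nodes = n_nodes)
      lod <- max(0, (full_fit$loglik - null_fit$loglik) / log(10))
      # minutes-weighted class means, as in effect_size()
      p_hom <- sum(mel[ok & het == 0]) / sum(tot[ok & het == 0])
      p_het <- sum(mel[ok & het == 1]) / sum(tot[ok & het == 1])
      rec[[run]] <- c(eff, 100 * (p_het - p_hom) / gap, lod)
    }
  }
  rec <- do.call(rbind, rec)
  records <- data.frame(true_effect = rec[, 1], est_effect = rec[, 2],
                        lod = rec[, 3], significant = rec[, 3] >= threshold)
  structure(list(records = records, threshold = threshold, n_reps = n_reps,
                 effects = effects, seed = seed),
            class = "beavis_grid")
}

#' Summarize a Beavis grid per true effect size
#'
#' @param grid a [run_beavis()] result.
#' @return data frame per true effect: number and proportion of significant
#'   runs, unconditional and significance-conditional mean estimated
#'   effects, and the median and 5% quantile of significant estimates.
#' @export
beavis_summary <- function(grid) {
  stopifnot(inherits(grid, "beavis_grid"))
  parts <- split(grid$records, grid$records$true_effect)
  out <- do.call(rbind, lapply(parts, function(d) {
    sig <- d$est_effect[d$significant]
    data.frame(true_effect = d$true_effect[1], n_runs = nrow(d),
               n_significant = length(sig),
               power = length(sig) / nrow(d),
               mean_all = mean(d$est_effect),
               mean_significant = if (length(sig)) mean(sig) else NA_real_,
               median_significant = if (length(sig)) stats::median(sig) else NA_real_,
               q05_significant = if (length(sig)) {
                 unname(stats::quantile(sig, 0.05))
               } else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Proportion of significant simulations below an observed effect
#'
#' For each true effect on the grid, the fraction of significant replicates
#' whose estimated effect is smaller than the empirically measured effect.
#' Reading off where this curve crosses 0.5 (median rule) or 0.95
#' (conservative rule) gives lower bounds on the plausible true effect.
#'
#' @param grid a [run_beavis()] result.
#' @param observed_effect empirically measured effect (percent of parental
#'   difference).
#' @return data frame `true_effect`, `n_significant`, `prop_below`
#'   (`NA` where a cell has no significant runs).
#' @export
prob_significant_below <- function(grid, observed_effect) {
  stopifnot(inherits(grid, "beavis_grid"))
  parts <- split(grid$records, grid$records$true_effect)
  out <- do.call(rbind, lapply(parts, function(d) {
    sig <- d$est_effect[d$significant]
    data.frame(true_effect = d$true_effect[1], n_significant = length(sig),
               prop_below = if (length(sig)) {
                 mean(sig < observed_effect)
               } else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
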