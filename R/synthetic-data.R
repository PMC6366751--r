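#' Configuration for the backcross study simulator
#'
#' Bundles the parameters of the synthetic backcross design: a male backcross
#' (F1 x parental) pedigree over multiple chromosomes, RAD-like marker noise,
#' and binomial courtship-minute phenotypes with planted QTLs. Defaults
#' emulate a *Heliconius*-style design: 139 males, 21 chromosomes of 50 cM,
#' markers every 5 cM, a median of 5 choice trials per male, and courtship
#' activity calibrated so the median proportion of trial time spent courting
#' is about 0.11.
#'
#' @param n_individuals number of backcross males.
#' @param chromosomes data frame with columns `name` and `length_cM`.
#' @param marker_spacing marker spacing in cM.
#' @param genotyping_error_rate probability a scored marker genotype is
#'   flipped (hom <-> het, symmetric).
#' @param missing_rate probability a marker genotype is missing, independent
#'   per marker.
#' @param qtl_specs data frame with columns `chrom`, `pos` (cM) and `effect`
#'   (percent of the parental difference in mean courtship proportion moved
#'   by a het-vs-hom allele substitution); `NULL` for no QTLs.
#' @param parental_means length-2 vector `c(cydno, melpomene)` of mean
#'   courtship proportions in the two parental species; must be increasing.
#' @param overdispersion_sd standard deviation of the individual-level random
#'   intercept on the logit scale.
#' @param trial_rate rate of the shifted-Poisson trial-count distribution:
#'   `n_trials = 1 + Poisson(trial_rate)` (default gives median 5 trials).
#' @param minutes_per_trial expected total courtship minutes per trial; total
#'   minutes per male are `Poisson(minutes_per_trial * n_trials)`. The
#'   distribution of per-male courtship totals is not constrained by the
#'   study design, so this is an explicit knob.
#' @param seed integer seed; fixing it makes all generator output
#'   bit-identical across runs.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals = 139,
                       chromosomes = data.frame(
                         name = as.character(1:21),
                         length_cM = rep(50, 21)),
                       marker_spacing = 5,
                       genotyping_error_rate = 0.001,
                       missing_rate = 0.05,
                       qtl_specs = NULL,
                       parental_means = c(0.05, 0.95),
                       overdispersion_sd = 0.8,
                       trial_rate = 4.3,
                       minutes_per_trial = 1.65,
                       seed = 1L) {
  if (n_individuals < 1) stop("need at least one individual")
  if (nrow(chromosomes) < 1) stop("need at least one chromosome")
  if (any(chromosomes$length_cM < 0)) stop("chromosome lengths must be >= 0")
  for (r in c(genotyping_error_rate, missing_rate)) {
    if (r < 0 || r > 1) stop("rates must be in [0, 1]")
  }
  if (length(parental_means) != 2 || any(parental_means < 0) ||
      any(parental_means > 1) || parental_means[2] <= parental_means[1]) {
    stop("parental_means must be increasing proportions in [0, 1]")
  }
  if (overdispersion_sd < 0) stop("overdispersion_sd must be >= 0")
  if (!is.null(qtl_specs)) {
    if (!all(c("chrom", "pos", "effect") %in% names(qtl_specs))) {
      stop("qtl_specs needs columns chrom, pos, effect")
    }
    if (any(qtl_specs$effect < 0 | qtl_specs$effect > 100)) {
      stop("QTL effects are percentages in [0, 100]")
    }
    len <- chromosomes$length_cM[match(as.character(qtl_specs$chrom),
                                       chromosomes$name)]
    if (any(is.na(len)) || any(qtl_specs$pos < 0 | qtl_specs$pos > len)) {
      stop("QTL positions must lie on a configured chromosome")
    }
  }
  structure(list(n_individuals = n_individuals, chromosomes = chromosomes,
                 marker_spacing = marker_spacing,
                 genotyping_error_rate = genotyping_error_rate,
                 missing_rate = missing_rate, qtl_specs = qtl_specs,
                 parental_means = parental_means,
                 overdispersion_sd = overdispersion_sd,
                 trial_rate = trial_rate,
                 minutes_per_trial = minutes_per_trial,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Marker map implied by a config: markers every `marker_spacing` cM plus the
# chromosome end. A zero-length chromosome gets a single marker at 0.
config_map <- function(config) {
  maps <- lapply(seq_len(nrow(config$chromosomes)), function(i) {
    nm <- config$chromosomes$name[i]
    len <- config$chromosomes$length_cM[i]
    pos <- unique(c(seq(0, len, by = config$marker_spacing), len))
    data.frame(chrom = nm, marker = sprintf("c%s_m%02d", nm, seq_along(pos)),
               pos = pos)
  })
  do.call(rbind, maps)
}

#' Simulate a backcross pedigree with noisy marker genotypes
#'
#' True genotypes of each male form a two-state Markov chain (hom CYD:CYD vs
#' het CYD:MEL) along each chromosome: the first marker is het with
#' probability 1/2 and the state switches across a gap of `d` cM with the
#' Haldane recombination fraction \eqn{r(d) = (1 - e^{-2d/100})/2}
#' (crossovers without interference). Observed genotypes flip truth with the
#' genotyping error rate and are masked at the missing rate.
#'
#' @param config a [sim_config()].
#' @param map optional marker map (data frame `chrom`, `marker`, `pos`)
#'   overriding the spacing-derived map.
#' @param seed overrides `config$seed` when given.
#' @return list of class `bc_sim` with `map`, `truth` (individuals x markers
#'   0/1 matrix of true het indicators), `geno` (observed matrix, `NA` =
#'   missing) and `ids`.
#' @export
simulate_backcross <- function(config, map = NULL, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(if (is.null(seed)) config$seed else seed)
  if (is.null(map)) map <- config_map(config)
  n <- config$n_individuals
  ids <- sprintf("BC%03d", seq_len(n))
  chroms <- split(map, factor(map$chrom, levels = unique(map$chrom)))
  truth <- matrix(NA_integer_, n, nrow(map), dimnames = list(ids, map$marker))
  col0 <- 0L
  for (ch in chroms) {
    m <- nrow(ch)
    states <- matrix(0L, n, m)
    states[, 1] <- stats::rbinom(n, 1, 0.5)
    if (m > 1) {
      r <- recomb_fraction(diff(ch$pos))
      for (j in 2:m) {
        flip <- stats::rbinom(n, 1, r[j - 1])
        states[, j] <- bitwXor(states[, j - 1], flip)
      }
    }
    truth[, col0 + seq_len(m)] <- states
    col0 <- col0 + m
  }
  geno <- truth
  if (config$genotyping_error_rate > 0) {
    err <- stats::rbinom(length(geno), 1, config$genotyping_error_rate)
    geno <- matrix(bitwXor(as.integer(geno), err), nrow = n)
  }
  if (config$missing_rate > 0) {
    geno[matrix(stats::runif(length(geno)) < config$missing_rate,
                nrow = n)] <- NA_integer_
  }
  dimnames(geno) <- dimnames(truth)
  structure(list(map = map, truth = truth, geno = geno, ids = ids),
            class = "bc_sim")
}

# Solve for the logit-scale location mu such that the logit-normal mean
# E[plogis(mu + sd * Z)] equals the target proportion m. Keeps planted QTL
# effects unbiased on the proportion scale even under overdispersion.
logit_normal_location <- function(m, sd, n_nodes = 41) {
  if (sd == 0) return(stats::qlogis(m))
  gh <- gh_rule(n_nodes)
  w <- gh$w / sqrt(pi)
  f <- function(mu) sum(w * stats::plogis(mu + sqrt(2) * sd * gh$x)) - m
  stats::uniroot(f, interval = stats::qlogis(m) + c(-1, 1) * (6 * sd + 5),
                 tol = 1e-10)$root
}

#' Simulate courtship-preference phenotypes with planted QTLs
#'
#' For each male, the number of choice trials is drawn as
#' `1 + Poisson(trial_rate)` and the total courtship minutes as
#' `Poisson(minutes_per_trial * n_trials)`. Minutes toward *melpomene* are
#' binomial with an individual-specific proportion: on the logit scale
#' \deqn{\mathrm{logit}(p_i) = \mu(g_i) + u_i, \qquad u_i \sim N(0, \sigma^2)}
#' where the location \eqn{\mu(g)} is solved so that the *mean* proportion of
#' each genotype class equals its target: the all-homozygous baseline sits at
#' the parental midpoint minus half the summed QTL shifts, and each planted
#' QTL adds `effect/100` of the parental gap when heterozygous. With a single
#' QTL of 100% effect the two class means therefore reproduce the parental
#' means exactly.
#'
#' @param sim a `bc_sim` from [simulate_backcross()], or a 0/1 matrix of true
#'   het indicators with marker column names (then `map` must be given).
#' @param config the [sim_config()] holding QTL specs and phenotype
#'   parameters.
#' @param map marker map; taken from `sim` when it is a `bc_sim`.
#' @param seed overrides `config$seed + 1` when given.
#' @return data frame with columns `id`, `minutes_mel`, `minutes_cyd`,
#'   `n_trials`. Males whose total courtship is zero are retained (they are
#'   excluded downstream by the scans).
#' @export
simulate_preference_phenotypes <- function(sim, config, map = NULL,
                                           seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(sim, "bc_sim")) {
    truth <- sim$truth
    map <- sim$map
  } else {
    truth <- sim
    if (is.null(map)) stop("supply a map when passing a raw truth matrix")
  }
  set.seed(if (is.null(seed)) config$seed + 1L else seed)
  n <- nrow(truth)
  pm <- config$parental_means
  gap <- pm[2] - pm[1]
  qs <- config$qtl_specs
  if (is.null(qs) || nrow(qs) == 0) {
    het <- matrix(0L, n, 0)
    shifts <- numeric(0)
  } else {
    qcols <- vapply(seq_len(nrow(qs)), function(k) {
      on_chr <- map$chrom == as.character(qs$chrom[k])
      if (!any(on_chr)) stop("QTL chromosome not in map: ", qs$chrom[k])
      idx <- which(on_chr)
      idx[which.min(abs(map$pos[idx] - qs$pos[k]))]
    }, integer(1))
    het <- truth[, qcols, drop = FALSE]
    shifts <- qs$effect / 100 * gap
  }
  base <- mean(pm) - 0.5 * sum(shifts)
  target <- pmin(pmax(base + drop(het %*% shifts), 1e-4), 1 - 1e-4)
  # class-wise logit locations (few distinct targets, solve each once)
  ut <- unique(target)
  mu_map <- vapply(ut, logit_normal_location, numeric(1),
                   sd = config$overdispersion_sd)
  mu <- mu_map[match(target, ut)]
  u <- stats::rnorm(n, 0, config$overdispersion_sd)
  p <- stats::plogis(mu + u)
  n_trials <- 1L + stats::rpois(n, config$trial_rate)
  total <- stats::rpois(n, config$minutes_per_trial * n_trials)
  mel <- stats::rbinom(n, total, p)
  data.frame(id = rownames(truth), minutes_mel = mel,
             minutes_cyd = total - mel, n_trials = n_trials,
             stringsAsFactors = FALSE)
}

#' Simulate four-population derived-allele frequencies with introgression
#'
#' Generates per-site derived-allele frequencies for (P1, P2, P3, outgroup)
#' in which P1 and P2 share a low-frequency background (Uniform(0, 0.2)), P3
#' carries a high-frequency derived allele (Uniform(0.5, 1)), and a fraction
#' of P2's sites are fully introgressed from P3 (`p2 := p3`). The outgroup is
#' fixed ancestral. Because the f_d denominator contribution has the same
#' distribution at introgressed and non-introgressed sites, the expected
#' windowed f_d equals the introgression fraction.
#'
#' @param n_sites number of sites (> 0), placed every 1 kb on one chromosome.
#' @param introgression_fraction fraction of P2 sites introgressed from P3.
#' @param seed integer seed.
#' @return data frame with `chrom`, `pos`, `p1`, `p2`, `p3`, `p4` suitable
#'   for [windowed_fd()].
#' @export
simulate_four_population_frequencies <- function(n_sites,
                                                 introgression_fraction,
                                                 seed = 1L) {
  if (n_sites <= 0) stop("n_sites must be positive")
  if (introgression_fraction < 0 || introgression_fraction > 1) {
    stop("introgression_fraction must be in [0, 1]")
  }
  set.seed(seed)
  pa <- stats::runif(n_sites, 0, 0.2)
  pb <- stats::runif(n_sites, 0.5, 1)
  intro <- stats::runif(n_sites) < introgression_fraction
  data.frame(chrom = "chr1", pos = seq_len(n_sites) * 1000,
             p1 = pa, p2 = ifelse(intro, pb, pa), p3 = pb, p4 = 0)
}
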