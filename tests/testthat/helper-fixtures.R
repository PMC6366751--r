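# Shared fixtures and independent oracles used across test files.

# Small backcross with one planted QTL; cheap enough to rebuild per file.
small_cross <- function(seed = 11, n = 80, effect = 40, n_chr = 3,
                        chr_len = 40, overdispersion_sd = 0.5) {
  cfg <- sim_config(
    n_individuals = n,
    chromosomes = data.frame(name = as.character(seq_len(n_chr)),
                             length_cM = rep(chr_len, n_chr)),
    marker_spacing = 10,
    genotyping_error_rate = 0, missing_rate = 0,
    qtl_specs = data.frame(chrom = as.character(min(2, n_chr)), pos = 20,
                           effect = effect),
    overdispersion_sd = overdispersion_sd,
    seed = seed)
  sim <- simulate_backcross(cfg)
  ph <- simulate_preference_phenotypes(sim, cfg)
  list(cfg = cfg, sim = sim, pheno = ph)
}

# Brute-force two-state HMM posterior by exhaustive path enumeration over
# ALL grid positions (markers emit, grid-only points do not). Independent of
# the forward-backward implementation; tractable for <= 12 grid points.
enum_posterior <- function(gpos, marker_at, obs, error_rate) {
  G <- length(gpos)
  stopifnot(G <= 12)
  r <- prefqtl::recomb_fraction(diff(gpos))
  paths <- as.matrix(expand.grid(rep(list(0:1), G)))
  logp <- apply(paths, 1, function(s) {
    lp <- log(0.5)
    if (G > 1) for (g in 2:G) {
      lp <- lp + log(ifelse(s[g] != s[g - 1], r[g - 1], 1 - r[g - 1]))
    }
    for (g in seq_len(G)) {
      if (!is.na(marker_at[g]) && !is.na(obs[marker_at[g]])) {
        agree <- obs[marker_at[g]] == s[g]
        lp <- lp + log(ifelse(agree, 1 - error_rate, error_rate))
      }
    }
    lp
  })
  w <- exp(logp - max(logp))
  w <- w / sum(w)
  colSums(paths * w)
}

# Closed-form binomial log-likelihood-ratio for a two-group design with a
# 0/1 covariate: group MLEs are pooled proportions.
binom_lrt_lod <- function(y, n, g) {
  ll_at <- function(idx, p) sum(dbinom(y[idx], n[idx], p, log = TRUE))
  p0 <- sum(y) / sum(n)
  p_hom <- sum(y[g == 0]) / sum(n[g == 0])
  p_het <- sum(y[g == 1]) / sum(n[g == 1])
  (ll_at(g == 0, p_hom) + ll_at(g == 1, p_het) - ll_at(TRUE, p0)) / log(10)
}
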