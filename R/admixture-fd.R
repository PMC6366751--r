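#' Per-site ABBA/BABA components for the f_d admixture estimator
#'
#' Given derived-allele frequencies in four populations
#' (P1 = allopatric "control" population, P2 = sympatric population tested for
#' introgression, P3 = candidate donor/recipient, P4 = outgroup used to
#' polarize), returns the four per-site summands:
#' \deqn{ABBA = (1-p_1)\,p_2\,p_3\,(1-p_4), \qquad
#'       BABA = p_1\,(1-p_2)\,p_3\,(1-p_4)}
#' and the "dynamic donor" versions in which both \eqn{p_2} and \eqn{p_3} are
#' replaced by \eqn{p_D = \max(p_2, p_3)} — the denominator of f_d, which
#' corresponds to complete local introgression from the more-derived
#' population.
#'
#' @param p1,p2,p3,p4 derived-allele frequencies in `[0, 1]` (vectors).
#' @return data frame with columns `abba`, `baba`, `abba_d`, `baba_d`.
#' @examples
#' site_components(0, 0.5, 1, 0)  # abba 0.5, baba 0, abba_d 1, baba_d 0
#' @export
site_components <- function(p1, p2, p3, p4) {
  ps <- cbind(p1, p2, p3, p4)
  if (any(ps < 0 | ps > 1)) stop("frequencies must be in [0, 1]")
  pd <- pmax(p2, p3)
  data.frame(abba   = (1 - p1) * p2 * p3 * (1 - p4),
             baba   = p1 * (1 - p2) * p3 * (1 - p4),
             abba_d = (1 - p1) * pd * pd * (1 - p4),
             baba_d = p1 * (1 - pd) * pd * (1 - p4))
}

#' Windowed f_d admixture estimation
#'
#' Computes Patterson's D and the f_d admixture-proportion estimator in
#' sliding windows of physical coordinates. Per window,
#' \deqn{D = \frac{\sum(ABBA - BABA)}{\sum(ABBA + BABA)}, \qquad
#'       f_d = \frac{\sum(ABBA - BABA)}{\sum(ABBA_D - BABA_D)}}
#' with sums over contained sites. f_d approximates the proportional
#' effective migration rate: 0 means no localized allele movement between P2
#' and P3, 1 means complete local introgression. Windows are half-open
#' `[start, end)` on 0-based physical coordinates. Windows with fewer than
#' `min_sites` usable sites, or with a non-positive f_d denominator, are
#' emitted with `fd = NA`. Negative f_d values are reported, not clipped.
#'
#' @param freqs data frame with columns `chrom`, `pos` (bp, strictly
#'   increasing within chromosome), `p1`, `p2`, `p3`, `p4`.
#' @param width window width in bp (default 100 kb).
#' @param step window step in bp (default 20 kb; `step = width` gives
#'   non-overlapping windows).
#' @param min_sites minimum informative sites per window (default 1).
#' @return data frame with `chrom`, `start`, `end`, `n_sites`, `d`, `fd`.
#' @export
windowed_fd <- function(freqs, width = 1e5, step = 2e4, min_sites = 1) {
  need <- c("chrom", "pos", "p1", "p2", "p3", "p4")
  if (!all(need %in% names(freqs))) {
    stop("freqs must have columns ", paste(need, collapse = ", "))
  }
  if (width <= 0 || step <= 0 || step > width) {
    stop("need width > 0 and 0 < step <= width")
  }
  out <- lapply(split(freqs, freqs$chrom), function(ch) {
    if (is.unsorted(ch$pos, strictly = TRUE)) {
      stop("positions must be strictly increasing within chromosome ",
           ch$chrom[1])
    }
    comp <- site_components(ch$p1, ch$p2, ch$p3, ch$p4)
    starts <- seq(0, max(ch$pos), by = step)
    res <- lapply(starts, function(s) {
      idx <- ch$pos >= s & ch$pos < s + width
      ns <- sum(idx)
      num <- sum(comp$abba[idx] - comp$baba[idx])
      tot <- sum(comp$abba[idx] + comp$baba[idx])
      den <- sum(comp$abba_d[idx] - comp$baba_d[idx])
      data.frame(chrom = ch$chrom[1], start = s, end = s + width,
                 n_sites = ns,
                 d  = if (ns >= min_sites && tot > 0) num / tot else NA_real_,
                 fd = if (ns >= min_sites && den > 0) num / den else NA_real_)
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
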