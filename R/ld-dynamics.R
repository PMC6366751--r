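#' Convert a genetic map distance to a recombination fraction
#'
#' Haldane's map function (default) assumes crossovers occur as a Poisson
#' process with no interference: \eqn{r = (1 - e^{-2d})/2} for \eqn{d} in
#' Morgans. Kosambi's function, which allows positive interference, is
#' available for sensitivity analysis: \eqn{r = \tanh(2d)/2}.
#'
#' @param d_cM genetic distance in centiMorgans (non-negative).
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#' @return recombination fraction(s) in `[0, 0.5)`.
#' @examples
#' recomb_fraction(10)      # ~0.0906
#' recomb_fraction(0)       # 0
#' @export
recomb_fraction <- function(d_cM, map_function = c("haldane", "kosambi")) {
  map_function <- match.arg(map_function)
  if (any(d_cM < 0)) stop("map distance must be non-negative")
  d <- d_cM / 100  # Morgans
  switch(map_function,
         haldane = 0.5 * (1 - exp(-2 * d)),
         kosambi = 0.5 * tanh(2 * d))
}

#' Linkage-disequilibrium decay under random mating
#'
#' Under random mating, LD (\eqn{D}) between two loci with recombination
#' fraction \eqn{r} decays by the factor \eqn{(1 - r)} each generation, so the
#' fraction retained after \eqn{t} generations is \eqn{(1 - r)^t}. Unlinked
#' loci (\eqn{r = 0.5}) therefore lose 50% of their LD per generation.
#'
#' @param d_cM genetic distance in cM; ignored when `r` is supplied.
#' @param r recombination fraction; overrides `d_cM` when given. Use
#'   `r = 0.5` for unlinked loci.
#' @param t generations (non-negative; may be a vector).
#' @param map_function map function used to convert `d_cM`.
#' @return list with `r`, `percent_loss_per_generation` (one-generation
#'   percent decline, rounded to one decimal), and `trajectory`, a data frame
#'   of `t` and `retained_fraction` \eqn{(1-r)^t}.
#' @examples
#' ld_decline(d_cM = 1.2)$percent_loss_per_generation  # 1.2
#' ld_decline(r = 0.5)$percent_loss_per_generation     # 50
#' @export
ld_decline <- function(d_cM = NULL, r = NULL, t = 0:20,
                       map_function = c("haldane", "kosambi")) {
  if (is.null(r)) {
    if (is.null(d_cM)) stop("supply d_cM or r")
    r <- recomb_fraction(d_cM, map_function)
  }
  if (r < 0 || r > 0.5) stop("recombination fraction must be in [0, 0.5]")
  if (any(t < 0)) stop("generations must be non-negative")
  list(r = r,
       percent_loss_per_generation = round(100 * r, 1),
       trajectory = data.frame(t = t, retained_fraction = (1 - r)^t))
}

#' Expected number of recombination events between two loci
#'
#' `n_meioses * r(d)`: the expected count of recombinant gametes between two
#' loci a given map distance apart, across a set of independent meioses.
#'
#' @inheritParams recomb_fraction
#' @param n_meioses number of meioses (individuals scored).
#' @return expected recombinant count.
#' @examples
#' expected_recombinants(1.2, 35)   # ~0.42
#' @export
expected_recombinants <- function(d_cM, n_meioses,
                                  map_function = c("haldane", "kosambi")) {
  if (any(n_meioses < 0)) stop("n_meioses must be non-negative")
  n_meioses * recomb_fraction(d_cM, map_function)
}
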