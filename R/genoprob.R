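#' Backcross genotype probabilities by a two-state hidden Markov model
#'
#' Computes, for every individual, the posterior probability of the
#' heterozygous (CYD:MEL) genotype at every marker and every whole-cM grid
#' position, conditional on the observed multipoint marker data. The hidden
#' chain has two states (hom, het) with prior 1/2 each at the chromosome
#' start; the transition probability across a gap of `d` cM is the Haldane
#' recombination fraction \eqn{r(d)}; the emission model scores an observed
#' genotype as correct with probability `1 - error_rate` and flipped with
#' probability `error_rate`, while missing genotypes (and pure grid
#' positions) are uninformative. Posteriors come from the scaled
#' forward-backward algorithm.
#'
#' @param map data frame with columns `chrom`, `marker`, `pos` (cM,
#'   non-decreasing within chromosome).
#' @param geno individuals x markers matrix with entries 0 (hom CYD:CYD),
#'   1 (het CYD:MEL) or `NA` (missing); column names must match
#'   `map$marker`, row names are individual ids.
#' @param error_rate assumed genotyping error probability in `[0, 0.5)`.
#' @param grid_step spacing of the evaluation grid in cM; the grid is the
#'   union of marker positions and multiples of `grid_step` (default: every
#'   cM). Use a large value to evaluate at markers only.
#' @return object of class `genoprob`: list with `grid` (data frame `chrom`,
#'   `pos`, `marker`), `prob` (individuals x grid-positions matrix of
#'   P(het)), `ids`, `map`, `error_rate`.
#' @examples
#' map <- data.frame(chrom = "1", marker = c("m1", "m2"), pos = c(0, 10))
#' g <- matrix(c(0L, 1L), 1, 2, dimnames = list("a", c("m1", "m2")))
#' gp <- compute_genoprob(map, g, error_rate = 0)
#' # P(het) rises from 0 at m1 to 1 at m2
#' @export
compute_genoprob <- function(map, geno, error_rate = 0.001, grid_step = 1) {
  if (error_rate < 0 || error_rate >= 0.5) stop("error_rate must be in [0, 0.5)")
  if (grid_step <= 0) stop("grid_step must be positive")
  geno <- as.matrix(geno)
  if (is.null(colnames(geno)) || !all(colnames(geno) %in% map$marker)) {
    stop("all genotype columns must be named and present in the map")
  }
  if (!all(map$marker %in% colnames(geno))) {
    stop("map markers missing from the genotype matrix")
  }
  geno <- geno[, map$marker, drop = FALSE]
  n <- nrow(geno)
  ids <- rownames(geno)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  chroms <- split(seq_len(nrow(map)),
                  factor(map$chrom, levels = unique(map$chrom)))
  grid_list <- list()
  prob_list <- list()
  for (ci in seq_along(chroms)) {
    idx <- chroms[[ci]]
    mpos <- map$pos[idx]
    if (is.unsorted(mpos)) stop("marker positions must be non-decreasing")
    gpos <- sort(unique(c(mpos, seq(0, max(mpos), by = grid_step))))
    G <- length(gpos)
    # marker index at each grid point (0 = none)
    mk <- match(round(gpos, 9), round(mpos, 9))
    # emission likelihoods per individual x grid point x state
    e0 <- matrix(1, n, G)
    e1 <- matrix(1, n, G)
    for (g in which(!is.na(mk))) {
      obs <- geno[, idx[mk[g]]]
      seen <- !is.na(obs)
      e0[seen, g] <- ifelse(obs[seen] == 0, 1 - error_rate, error_rate)
      e1[seen, g] <- ifelse(obs[seen] == 1, 1 - error_rate, error_rate)
    }
    r <- recomb_fraction(diff(gpos))
    # scaled forward
    f0 <- matrix(0, n, G); f1 <- matrix(0, n, G)
    a0 <- 0.5 * e0[, 1]; a1 <- 0.5 * e1[, 1]
    s <- a0 + a1
    f0[, 1] <- a0 / s; f1[, 1] <- a1 / s
    if (G > 1) for (g in 2:G) {
      rr <- r[g - 1]
      a0 <- (f0[, g - 1] * (1 - rr) + f1[, g - 1] * rr) * e0[, g]
      a1 <- (f0[, g - 1] * rr + f1[, g - 1] * (1 - rr)) * e1[, g]
      s <- a0 + a1
      f0[, g] <- a0 / s; f1[, g] <- a1 / s
    }
    # scaled backward
    b0 <- rep(1, n); b1 <- rep(1, n)
    post <- matrix(0, n, G)
    post[, G] <- f1[, G] / (f0[, G] + f1[, G])
    if (G > 1) for (g in (G - 1):1) {
      rr <- r[g]
      nb0 <- (1 - rr) * e0[, g + 1] * b0 + rr * e1[, g + 1] * b1
      nb1 <- rr * e0[, g + 1] * b0 + (1 - rr) * e1[, g + 1] * b1
      s <- nb0 + nb1
      b0 <- nb0 / s; b1 <- nb1 / s
      num <- f1[, g] * b1
      post[, g] <- num / (f0[, g] * b0 + num)
    }
    grid_list[[ci]] <- data.frame(
      chrom = map$chrom[idx[1]], pos = gpos,
      marker = ifelse(is.na(mk), NA_character_, map$marker[idx][mk]),
      stringsAsFactors = FALSE)
    prob_list[[ci]] <- post
  }
  grid <- do.call(rbind, grid_list)
  rownames(grid) <- NULL
  prob <- do.call(cbind, prob_list)
  dimnames(prob) <- list(ids, paste0(grid$chrom, "@", grid$pos))
  structure(list(grid = grid, prob = prob, ids = ids, map = map,
                 error_rate = error_rate),
            class = "genoprob")
}

#' @export
print.genoprob <- function(x, ...) {
  cat("Backcross genotype probabilities\n")
  cat("  individuals:", length(x$ids), "\n")
  cat("  chromosomes:", length(unique(x$grid$chrom)),
      " grid positions:", nrow(x$grid), "\n")
  invisible(x)
}

# Index of the grid position closest to chrom@pos (exact chromosome match).
grid_index <- function(probs, chrom, pos) {
  idx <- which(probs$grid$chrom == as.character(chrom))
  if (!length(idx)) stop("chromosome not in grid: ", chrom)
  idx[which.min(abs(probs$grid$pos[idx] - pos))]
}

#' Maximum-posterior genotype calls at a locus
#'
#' Calls each individual hom (0) or het (1) at the grid position nearest
#' `chrom@pos` by thresholding P(het) at 1/2. Calls with P(het) inside
#' `ambiguous` (default `[0.45, 0.55]`) can optionally be returned as `NA`.
#'
#' @param probs a [compute_genoprob()] result.
#' @param chrom,pos locus.
#' @param drop_ambiguous if `TRUE`, ambiguous calls become `NA`.
#' @param ambiguous P(het) interval treated as ambiguous.
#' @return named integer vector of 0/1 calls (with `NA` when dropped).
#' @export
genotype_calls <- function(probs, chrom, pos, drop_ambiguous = FALSE,
                           ambiguous = c(0.45, 0.55)) {
  p <- probs$prob[, grid_index(probs, chrom, pos)]
  calls <- as.integer(p > 0.5)
  if (drop_ambiguous) calls[p >= ambiguous[1] & p <= ambiguous[2]] <- NA_integer_
  stats::setNames(calls, probs$ids)
}
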