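#' Read a cross file (rotated R/qtl-style CSV)
#'
#' Reads the combined genotype + map + phenotype CSV dialect in which the
#' first columns are phenotypes (`id`, `minutes_mel`, `minutes_cyd`,
#' `n_trials`, ...) and the remaining columns are markers; the first data
#' row carries the chromosome of each marker (blank for phenotype columns)
#' and the second carries its cM position, followed by one row per
#' individual. Genotype codes are configurable and default to `CC`
#' (homozygous CYD:CYD) and `CM` (heterozygous CYD:MEL); `-`, `NA` and empty
#' cells are missing. Unknown codes are rejected with their row and column.
#'
#' @param file path to the CSV.
#' @param genotype_codes named character vector `c(hom = ..., het = ...)`.
#' @param na_strings genotype strings treated as missing.
#' @return object of class `cross_data`: list with `map` (`chrom`, `marker`,
#'   `pos`), `geno` (individuals x markers 0/1/NA matrix), `pheno` (data
#'   frame). Individuals whose genotypes are entirely missing are dropped
#'   from `geno` with a warning and listed in the `ungenotyped` attribute.
#' @export
read_cross <- function(file, genotype_codes = c(hom = "CC", het = "CM"),
                       na_strings = c("-", "NA", "")) {
  raw <- utils::read.csv(file, header = TRUE, colClasses = "character",
                         check.names = FALSE)
  if (nrow(raw) < 3) stop("cross file needs chromosome, position and data rows")
  chrom_row <- as.character(raw[1, ])
  pos_row <- as.character(raw[2, ])
  is_marker <- !is.na(chrom_row) & chrom_row != ""
  if (!any(is_marker)) stop("no marker columns found (empty chromosome row)")
  if (!"id" %in% names(raw)[!is_marker]) stop("phenotype columns must include 'id'")
  map <- data.frame(chrom = chrom_row[is_marker],
                    marker = names(raw)[is_marker],
                    pos = as.numeric(pos_row[is_marker]),
                    stringsAsFactors = FALSE)
  if (anyNA(map$pos)) stop("non-numeric marker positions in the position row")
  dat <- raw[-(1:2), , drop = FALSE]
  pheno <- dat[, !is_marker, drop = FALSE]
  for (nm in setdiff(names(pheno), "id")) {
    pheno[[nm]] <- as.numeric(pheno[[nm]])
  }
  rownames(pheno) <- NULL
  gchar <- as.matrix(dat[, is_marker, drop = FALSE])
  geno <- matrix(NA_integer_, nrow(gchar), ncol(gchar),
                 dimnames = list(pheno$id, map$marker))
  geno[gchar == genotype_codes[["hom"]]] <- 0L
  geno[gchar == genotype_codes[["het"]]] <- 1L
  known <- gchar %in% c(genotype_codes, na_strings) | is.na(gchar)
  if (!all(known)) {
    bad <- which(!known, arr.ind = TRUE)[1, ]
    stop("unknown genotype code '", gchar[bad[1], bad[2]], "' at row ",
         bad[1] + 2, ", column '", map$marker[bad[2]], "'")
  }
  ungeno <- pheno$id[rowSums(!is.na(geno)) == 0]
  if (length(ungeno)) {
    warning(length(ungeno), " individual(s) with phenotype but no genotypes ",
            "dropped from the genotype matrix: ",
            paste(utils::head(ungeno, 5), collapse = ", "))
    geno <- geno[!(pheno$id %in% ungeno), , drop = FALSE]
  }
  structure(list(map = map, geno = geno, pheno = pheno),
            class = "cross_data", ungenotyped = ungeno)
}

#' Write a cross file (rotated R/qtl-style CSV)
#'
#' Inverse of [read_cross()].
#'
#' @param map,geno,pheno cross components, as produced by
#'   [simulate_backcross()] and [simulate_preference_phenotypes()].
#' @param file output path.
#' @inheritParams read_cross
#' @export
write_cross <- function(map, geno, pheno, file,
                        genotype_codes = c(hom = "CC", het = "CM")) {
  if (!all(pheno$id == rownames(geno))) {
    pheno <- pheno[match(rownames(geno), pheno$id), , drop = FALSE]
  }
  gchar <- matrix(genotype_codes[["hom"]], nrow(geno), ncol(geno))
  gchar[geno == 1L] <- genotype_codes[["het"]]
  gchar[is.na(geno)] <- "-"
  body <- cbind(as.data.frame(lapply(pheno, as.character),
                              stringsAsFactors = FALSE),
                as.data.frame(gchar, stringsAsFactors = FALSE))
  names(body) <- c(names(pheno), map$marker)
  hdr1 <- c(rep("", ncol(pheno)), map$chrom)
  hdr2 <- c(rep("", ncol(pheno)), as.character(map$pos))
  out <- rbind(stats::setNames(as.data.frame(as.list(hdr1)), names(body)),
               stats::setNames(as.data.frame(as.list(hdr2)), names(body)),
               body)
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Read a four-population allele-frequency table
#'
#' CSV with columns `chrom`, `pos`, `p1`, `p2`, `p3`, `p4`, validated for
#' [windowed_fd()].
#'
#' @param file path to the CSV.
#' @export
read_frequencies <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "p1", "p2", "p3", "p4")
  if (!all(need %in% names(df))) {
    stop("frequency file must have columns ", paste(need, collapse = ", "))
  }
  ps <- as.matrix(df[, c("p1", "p2", "p3", "p4")])
  if (any(is.na(ps)) || any(ps < 0 | ps > 1)) {
    stop("frequencies must be in [0, 1] with no missing values")
  }
  df
}

#' Run the full preference-QTL pipeline
#'
#' Chains the analysis stages on a cross: genotype probabilities, binomial
#' mixed-model genome scan, permutation threshold, significant peaks with
#' 1.5-LOD support intervals, a joint multi-QTL model of the significant
#' peaks, and their effect sizes. Optionally writes per-stage CSVs and a
#' JSON summary with the configuration and seed.
#'
#' @param map,geno,pheno cross components (see [read_cross()]).
#' @param error_rate,grid_step passed to [compute_genoprob()].
#' @param n_permutations,alpha,seed permutation settings.
#' @param parental_means parental courtship proportions for effect scaling.
#' @param n_nodes quadrature nodes for all mixed-model fits.
#' @param out_dir if non-`NULL`, directory for the output files.
#' @return list of class `pipeline_report`: `scan`, `perm`, `threshold`,
#'   `peaks` (significant peaks with support intervals), `model`
#'   (multi-QTL fit or `NULL`), `effects`, `n_used`, `config`.
#' @export
run_pipeline <- function(map, geno, pheno, error_rate = 0.001, grid_step = 1,
                         n_permutations = 100, alpha = 0.05, seed = 1L,
                         parental_means = c(0.05, 0.95), n_nodes = 21,
                         out_dir = NULL) {
  if (nrow(pheno) == 0) stop("empty phenotype table")
  probs <- compute_genoprob(map, geno, error_rate = error_rate,
                            grid_step = grid_step)
  scan <- scan_glmm(probs, pheno, n_nodes = n_nodes, quiet = TRUE)
  perm <- permutation_threshold(probs, pheno, n_permutations = n_permutations,
                                seed = seed, n_nodes = n_nodes)
  thr <- lod_threshold(perm, alpha)
  pk <- scan_peaks(scan)
  sig <- pk[pk$lod >= thr, , drop = FALSE]
  peaks <- NULL
  model <- NULL
  effects <- list()
  if (nrow(sig)) {
    ivs <- do.call(rbind, lapply(seq_len(nrow(sig)), function(i) {
      as.numeric(support_interval(scan, sig$chrom[i]))
    }))
    peaks <- cbind(sig, data.frame(ci_lo = ivs[, 1], ci_hi = ivs[, 2]))
    model <- fit_multiqtl(probs, pheno, sig[c("chrom", "pos")], threshold = thr,
                          n_nodes = n_nodes, quiet = TRUE)
    effects <- lapply(seq_len(nrow(sig)), function(i) {
      effect_size(pheno, probs = probs, chrom = sig$chrom[i], pos = sig$pos[i],
                  parental_means = parental_means)
    })
  }
  report <- structure(
    list(scan = scan, perm = perm, threshold = thr, peaks = peaks,
         model = model, effects = effects, n_used = attr(scan, "n_used"),
         config = list(error_rate = error_rate, grid_step = grid_step,
                       n_permutations = n_permutations, alpha = alpha,
                       seed = seed, parental_means = parental_means)),
    class = "pipeline_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(as.data.frame(scan), file.path(out_dir, "genome_scan_lod.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(max_lod = perm$max_lods),
                     file.path(out_dir, "permutation_max_lod.csv"),
                     row.names = FALSE)
    if (!is.null(peaks)) {
      utils::write.csv(peaks, file.path(out_dir, "peaks.csv"), row.names = FALSE)
    }
    summ <- list(
      n_used = report$n_used, threshold = thr, config = report$config,
      peaks = peaks,
      effects = vapply(effects, function(e) e$percent_of_parental_difference,
                       numeric(1)))
    jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Preference-QTL pipeline report\n")
  cat("  individuals used:", x$n_used, "\n")
  cat(sprintf("  genome-wide LOD threshold (alpha = %.2f, %d permutations): %.2f\n",
              x$config$alpha, x$config$n_permutations, x$threshold))
  if (is.null(x$peaks)) {
    cat("  no significant QTLs\n")
  } else {
    cat("  significant QTLs:\n")
    print(x$peaks, row.names = FALSE)
    if (length(x$effects)) {
      cat("  effect sizes (% of parental difference):",
          paste(sprintf("%.1f", vapply(x$effects, function(e)
            e$percent_of_parental_difference, numeric(1))), collapse = ", "),
          "\n")
    }
  }
  invisible(x)
}
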