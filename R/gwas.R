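#' Genome-wide association scan for sex
#'
#' Runs the dominant-model exact test at every marker of a (QC-filtered)
#' genotype matrix, contrasting males against females, and calls
#' genome-wide significance at the Bonferroni threshold
#' `alpha / n_markers` (inclusive: `p <= threshold`).
#'
#' The dominant coding is with respect to the minor allele computed in the
#' full cohort at each marker; ties at MAF 0.5 go to the alphabetically
#' first allele letter.  Missing genotypes are excluded per marker
#' (complete-case per test).  A marker where one sex has no non-missing
#' call is flagged (`note = "no_data_one_sex"`, `p_value = NA`) rather than
#' aborting the scan.
#'
#' @param gm A [genotype_matrix()], normally after [filter_markers()] and
#'   [filter_samples()].
#' @param alpha Family-wise error rate for the Bonferroni threshold.
#' @return Object of class `sex_gwas`: list with
#'   * `results`: tibble (`marker`, `chrom`, `pos`, `a`, `b`, `c`, `d`,
#'     `p_value`, `significant`, `note`) - `a`/`b` male
#'     carriers/non-carriers, `c`/`d` female;
#'   * `threshold`: the Bonferroni threshold used;
#'   * `n_tests`: number of markers tested;
#'   * `manhattan`: plot-ready tibble (`chrom`, `pos`, `marker`,
#'     `neglog10p`).
#' @export
run_sex_gwas <- function(gm, alpha = 0.05) {
  stopifnot(inherits(gm, "genotype_matrix"))
  sex <- gm$samples$sex
  if (!any(sex == "male") || !any(sex == "female"))
    stop("cohort must contain both sexes")
  cm <- gm$calls[sex == "male", , drop = FALSE]
  cf <- gm$calls[sex == "female", , drop = FALSE]
  cnt <- function(m, v) unname(colSums(m == v, na.rm = TRUE))
  m0 <- cnt(cm, 0L); m1 <- cnt(cm, 1L); m2 <- cnt(cm, 2L)
  f0 <- cnt(cf, 0L); f1 <- cnt(cf, 1L); f2 <- cnt(cf, 2L)

  alt <- m1 + f1 + 2 * (m2 + f2)
  ref <- m1 + f1 + 2 * (m0 + f0)
  # minor allele per marker; MAF-0.5 ties resolved to the alphabetically
  # first allele letter
  minor_is_alt <- alt < ref | (alt == ref & gm$markers$alt < gm$markers$ref)
  a <- ifelse(minor_is_alt, m1 + m2, m0 + m1)
  b <- (m0 + m1 + m2) - a
  cc <- ifelse(minor_is_alt, f1 + f2, f0 + f1)
  d <- (f0 + f1 + f2) - cc

  k <- ncol(gm$calls)
  p <- rep(NA_real_, k)
  ok <- (a + b) > 0 & (cc + d) > 0
  if (any(ok)) p[ok] <- fisher_exact_2x2(a[ok], b[ok], cc[ok], d[ok])
  threshold <- bonferroni_threshold(alpha, k)
  significant <- !is.na(p) & p <= threshold

  results <- tibble(marker = gm$markers$id, chrom = gm$markers$chrom,
                    pos = gm$markers$pos, a = a, b = b, c = cc, d = d,
                    p_value = p, significant = significant,
                    note = ifelse(ok, NA_character_, "no_data_one_sex"))
  manhattan <- tibble(chrom = gm$markers$chrom, pos = gm$markers$pos,
                      marker = gm$markers$id, neglog10p = -log10(p))
  structure(list(results = results, threshold = threshold, n_tests = k,
                 manhattan = manhattan),
            class = "sex_gwas")
}

#' @export
print.sex_gwas <- function(x, ...) {
  cat(sprintf("<sex_gwas> %d markers tested, Bonferroni threshold %.3g\n",
              x$n_tests, x$threshold))
  cat(sprintf("  genome-wide significant: %d\n", sum(x$results$significant)))
  invisible(x)
}

#' Manhattan plot of a sex GWAS
#'
#' @param gwas A `sex_gwas` object from [run_sex_gwas()].
#' @return A ggplot object (requires the ggplot2 package); the horizontal
#'   line marks the Bonferroni threshold.
#' @export
plot_manhattan <- function(gwas) {
  stopifnot(inherits(gwas, "sex_gwas"))
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_manhattan() requires the ggplot2 package")
  df <- gwas$manhattan[!is.na(gwas$manhattan$neglog10p), ]
  df$chrom <- factor(df$chrom, levels = unique(df$chrom))
  ggplot2::ggplot(df, ggplot2::aes(x = pos, y = neglog10p, colour = chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = -log10(gwas$threshold)) +
    ggplot2::facet_grid(cols = ggplot2::vars(chrom), scales = "free_x",
                        space = "free_x", switch = "x") +
    ggplot2::labs(x = "chromosome", y = expression(-log[10](italic(P)))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.spacing.x = ggplot2::unit(0.1, "lines"))
}
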