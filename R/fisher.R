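#' Two-sided Fisher's exact test for 2x2 tables
#'
#' Exact two-sided P-value for a 2x2 contingency table, computed by
#' enumerating every table with the observed margins and summing the
#' hypergeometric point probabilities that do not exceed that of the
#' observed table (ties included).  No continuity or mid-P adjustment is
#' applied.  Point probabilities are evaluated in log space so that cohort
#' sizes of 50 and beyond do not overflow.
#'
#' Vectorised over tables; duplicated tables are computed once, which makes
#' genome-scale scans (where only a few hundred distinct tables occur)
#' cheap.
#'
#' @param a,b,c,d Cell counts: `a`/`b` carriers/non-carriers in the first
#'   group, `c`/`d` in the second.  Vectors are recycled position-wise (all
#'   must share one length).
#' @return Numeric vector of P-values in `(0, 1]`.  A table whose carrier
#'   margin is zero (or full) has no information and returns exactly 1.
#' @seealso [dominant_fisher()] for the genotype-level dominant-model
#'   wrapper.
#' @examples
#' fisher_exact_2x2(25, 0, 0, 25)   # perfect separation, ~1.58e-14
#' fisher_exact_2x2(5, 5, 5, 5)     # no association, 1
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  k <- length(a)
  if (length(b) != k || length(c) != k || length(d) != k)
    stop("a, b, c, d must have equal length")
  if (any(c(a, b, c, d) < 0, na.rm = TRUE)) stop("counts must be non-negative")
  key <- paste(a, b, c, d)
  first <- which(!duplicated(key))
  pu <- vapply(first, function(i) .fisher_one(a[i], b[i], c[i], d[i]),
               numeric(1))
  unname(pu[match(key, key[first])])
}

# Single-table enumeration in log space.  Ties with the observed point
# probability are included using a small relative tolerance (the
# conventional two-sided rule).
.fisher_one <- function(a, b, c, d) {
  if (anyNA(c(a, b, c, d))) return(NA_real_)
  r1 <- a + b
  r2 <- c + d
  if (r1 == 0 || r2 == 0)
    stop("both groups need at least one observation")
  kk <- a + c
  n <- r1 + r2
  if (kk == 0 || kk == n) return(1)
  x <- max(0, kk - r2):min(r1, kk)
  lp <- lchoose(r1, x) + lchoose(r2, kk - x) - lchoose(n, kk)
  lobs <- lp[x == a]
  min(1, sum(exp(lp[lp <= lobs + 1e-7])))
}

#' Dominant-model Fisher's exact test for a sex contrast
#'
#' Codes each individual as a carrier (heterozygous or homozygous for the
#' minor allele) or non-carrier, builds the 2x2 sex-by-carrier table from
#' non-missing calls, and returns the two-sided exact P-value from
#' [fisher_exact_2x2()].
#'
#' The minor allele is determined from the pooled male + female calls.  If
#' the two alleles are exactly balanced (minor allele frequency 0.5) the
#' tie is resolved to the alphabetically first allele letter when `alleles`
#' is supplied, otherwise to the alternate allele.
#'
#' @param male,female Genotype calls for each sex: integer codes `0/1/2/NA`
#'   or labels `"hom_ref"/"het"/"hom_alt"` (`"missing"`/`NA` allowed).
#' @param alleles Optional named character vector `c(ref = , alt = )` of
#'   allele letters, used only to break a minor-allele tie.
#' @return Object of class `assoc_result`: list with contingency counts
#'   `a` (male carriers), `b` (male non-carriers), `c` (female carriers),
#'   `d` (female non-carriers), `p_value`, and `carrier_allele`
#'   (`"ref"`/`"alt"`).
#' @examples
#' # 25 males all heterozygous, 25 females homozygous reference:
#' dominant_fisher(rep("het", 25), rep("hom_ref", 25))$p_value
#' @export
dominant_fisher <- function(male, female, alleles = NULL) {
  male <- .as_geno(male)
  female <- .as_geno(female)
  male <- male[!is.na(male)]
  female <- female[!is.na(female)]
  if (length(male) == 0 || length(female) == 0)
    stop("each sex needs at least one non-missing genotype call")
  pooled <- c(male, female)
  alt_count <- sum(pooled)
  ref_count <- 2L * length(pooled) - alt_count
  minor <- if (alt_count < ref_count) "alt"
    else if (alt_count > ref_count) "ref"
    else if (!is.null(alleles)) {
      stopifnot(all(c("ref", "alt") %in% names(alleles)))
      if (alleles[["ref"]] < alleles[["alt"]]) "ref" else "alt"
    } else "alt"
  carrier_codes <- if (minor == "alt") c(1L, 2L) else c(0L, 1L)
  a <- sum(male %in% carrier_codes)
  b <- length(male) - a
  cc <- sum(female %in% carrier_codes)
  d <- length(female) - cc
  structure(list(a = a, b = b, c = cc, d = d,
                 p_value = .fisher_one(a, b, cc, d),
                 carrier_allele = minor),
            class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("<assoc_result> carriers (dominant, minor = %s allele)\n",
              x$carrier_allele))
  cat(sprintf("  males   %d / %d\n  females %d / %d\n", x$a, x$a + x$b,
              x$c, x$c + x$d))
  cat(sprintf("  two-sided exact P = %.4g\n", x$p_value))
  invisible(x)
}

#' Bonferroni genome-wide significance threshold
#'
#' @param alpha Family-wise error rate (default 0.05).
#' @param n_tests Number of tests (markers); must be >= 1.
#' @return `alpha / n_tests`.
#' @examples
#' bonferroni_threshold(0.05, 123247)
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_tests) {
  if (length(n_tests) != 1 || is.na(n_tests) || n_tests < 1)
    stop("n_tests must be a single count >= 1")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  alpha / n_tests
}
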