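#' Configuration for the array genotype simulator
#'
#' Defaults emulate the study design the pipeline targets: a balanced
#' 25-male / 25-female cohort with a handful of planted shadow-Y markers on
#' an otherwise null (Hardy-Weinberg, sex-independent) array background.
#'
#' @param n_males,n_females Sample counts per sex.
#' @param n_null_markers Markers drawn under Hardy-Weinberg at a MAF
#'   uniform in `maf_range`, independent of sex.
#' @param n_shadow_markers Planted shadow-Y markers: every male
#'   heterozygous, every female the same homozygote (before missingness).
#' @param n_xlinked_markers True X-linked markers: males hemizygous (one
#'   allele, emitted as a homozygous call, mirroring array reporting),
#'   females Hardy-Weinberg.
#' @param n_excluded_markers Markers with the excluded-pattern: females
#'   monomorphic, males a mix of heterozygous and alternate-homozygous
#'   calls.
#' @param maf_range Pair of minor-allele frequencies in `(0, 0.5]` from
#'   which null/X-linked MAFs are drawn uniformly.
#' @param missing_rate Probability that any single call is set missing.
#' @param excluded_male_het_prop Probability a male is heterozygous (vs
#'   alternate-homozygous) at an excluded-pattern marker (default 0.5).
#' @param seed Integer seed; all draws flow from it, global RNG state is
#'   untouched.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_males = 25, n_females = 25,
                       n_null_markers = 5000, n_shadow_markers = 10,
                       n_xlinked_markers = 0, n_excluded_markers = 0,
                       maf_range = c(0.05, 0.5), missing_rate = 0,
                       excluded_male_het_prop = 0.5, seed = 1) {
  cfg <- list(n_males = n_males, n_females = n_females,
              n_null_markers = n_null_markers,
              n_shadow_markers = n_shadow_markers,
              n_xlinked_markers = n_xlinked_markers,
              n_excluded_markers = n_excluded_markers,
              maf_range = maf_range, missing_rate = missing_rate,
              excluded_male_het_prop = excluded_male_het_prop,
              seed = as.integer(seed))
  counts <- unlist(cfg[c("n_males", "n_females", "n_null_markers",
                         "n_shadow_markers", "n_xlinked_markers",
                         "n_excluded_markers")])
  if (any(counts < 0)) stop("counts must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must be frequencies in (0, 0.5] with lower <= upper")
  structure(cfg, class = "sim_config")
}

#' Simulate array genotypes with planted sex-linked patterns
#'
#' Generates a [genotype_matrix()] containing four marker classes with
#' ground-truth labels:
#'
#' * `NULL` - Hardy-Weinberg at a random MAF, identical distribution in
#'   both sexes;
#' * `SHADOW_Y` - every male heterozygous, every female the same
#'   homozygote (the cryptic Y-paralog pattern);
#' * `X_LINKED` - males hemizygous (emitted homozygous), females
#'   Hardy-Weinberg;
#' * `EXCLUDED_TYPE` - females monomorphic, males a het/hom-alternate
#'   mixture (the pattern that disqualifies a marker from the shadow-Y
#'   class).
#'
#' Missingness is applied uniformly at `missing_rate` after pattern
#' generation.  Marker order is shuffled so classes are interleaved.
#'
#' @param cfg A [sim_config()].
#' @return List with `genotypes` (a [genotype_matrix()]) and `truth`
#'   (tibble `marker_id`, `class`).
#' @examples
#' sim <- simulate_genotypes(sim_config(n_null_markers = 100, seed = 42))
#' table(sim$truth$class)
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  needs_both <- cfg$n_shadow_markers > 0 || cfg$n_excluded_markers > 0
  if (needs_both && (cfg$n_males == 0 || cfg$n_females == 0))
    stop("shadow-Y / excluded patterns are undefined without both sexes")
  n_s <- cfg$n_males + cfg$n_females
  if (n_s == 0) stop("no samples requested")

  withr::with_seed(cfg$seed, {
    classes <- rep(c("NULL", "SHADOW_Y", "X_LINKED", "EXCLUDED_TYPE"),
                   times = c(cfg$n_null_markers, cfg$n_shadow_markers,
                             cfg$n_xlinked_markers, cfg$n_excluded_markers))
    k <- length(classes)
    male <- rep(c(TRUE, FALSE), c(cfg$n_males, cfg$n_females))
    calls <- matrix(NA_integer_, n_s, k)

    gen_block <- function(class) which(classes == class)

    i <- gen_block("NULL")
    if (length(i)) {
      p <- runif(length(i), cfg$maf_range[1], cfg$maf_range[2])
      calls[, i] <- matrix(rbinom(n_s * length(i), 2L, rep(p, each = n_s)),
                           n_s, length(i))
    }
    i <- gen_block("SHADOW_Y")
    if (length(i)) {
      fem_hom <- sample(c(0L, 2L), length(i), replace = TRUE)
      calls[male, i] <- 1L
      calls[!male, i] <- rep(fem_hom, each = sum(!male))
    }
    i <- gen_block("X_LINKED")
    if (length(i)) {
      p <- runif(length(i), cfg$maf_range[1], cfg$maf_range[2])
      calls[!male, i] <- matrix(
        rbinom(sum(!male) * length(i), 2L, rep(p, each = sum(!male))),
        sum(!male), length(i))
      # hemizygous male alleles collapsed to homozygous calls
      calls[male, i] <- matrix(
        2L * rbinom(sum(male) * length(i), 1L, rep(p, each = sum(male))),
        sum(male), length(i))
    }
    i <- gen_block("EXCLUDED_TYPE")
    if (length(i)) {
      fem_hom <- sample(c(0L, 2L), length(i), replace = TRUE)
      calls[!male, i] <- rep(fem_hom, each = sum(!male))
      alt_hom <- rep(2L - fem_hom, each = sum(male))  # the other homozygote
      is_het <- rbinom(sum(male) * length(i), 1L,
                       cfg$excluded_male_het_prop) == 1L
      calls[male, i] <- ifelse(is_het, 1L, alt_hom)
    }

    ord <- sample.int(k)
    classes <- classes[ord]
    calls <- calls[, ord, drop = FALSE]

    if (cfg$missing_rate > 0) {
      calls[runif(length(calls)) < cfg$missing_rate] <- NA_integer_
    }

    pair <- t(vapply(seq_len(k),
                     function(j) sample(c("A", "C", "G", "T"), 2),
                     character(2)))
    markers <- tibble(
      id = sprintf("M%06d", seq_len(k)),
      chrom = as.character(sample(1:38, k, replace = TRUE)),
      pos = sample.int(120000000L, k, replace = TRUE),
      ref = pair[, 1], alt = pair[, 2])
    samples <- tibble(
      id = c(sprintf("male%03d", seq_len(cfg$n_males)),
             sprintf("female%03d", seq_len(cfg$n_females))),
      sex = rep(c("male", "female"), c(cfg$n_males, cfg$n_females)))

    list(genotypes = genotype_matrix(calls, markers, samples),
         truth = tibble(marker_id = markers$id, class = classes))
  })
}
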