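# Array QC and the dominant-model sex scan.

test_that("marker QC applies call-rate and MAF thresholds with retained boundaries", {
  n <- 40
  sex <- rep(c("male", "female"), each = n / 2)
  mk <- list(
    low_cr = c(rep(NA, 3), rep(1L, n - 3)),          # 37/40 = 0.925
    low_maf = c(rep(1L, 2), rep(0L, n - 2)),         # MAF 2/80 = 0.025
    cr_boundary = c(rep(NA, 2), rep(1L, n - 2)),     # exactly 0.95
    maf_boundary = c(rep(1L, 4), rep(0L, n - 4)))    # exactly 0.05
  good <- replicate(6, rbinom(n, 2, 0.3), simplify = FALSE)
  gm <- make_gm(c(mk, good), sex)
  out <- filter_markers(gm)
  expect_identical(ncol(out$genotypes$calls), 8L)    # 10 - low_cr - low_maf
  removed <- out$report$removed
  expect_setequal(removed$id, c("m01", "m02"))
  expect_match(removed$reason[removed$id == "m01"], "call rate")
  expect_match(removed$reason[removed$id == "m02"], "MAF")
  # vacuous thresholds retain everything with any data
  expect_identical(nrow(filter_markers(gm, min_call_rate = 0,
                                       min_maf = 0)$report$removed), 0L)
  # an all-missing marker is removed with reason "no data", not an error
  gm_nd <- make_gm(list(rep(NA_integer_, n), rbinom(n, 2, 0.3)), sex)
  out_nd <- filter_markers(gm_nd, min_call_rate = 0, min_maf = 0)
  expect_identical(out_nd$report$removed$id, "m01")
  expect_match(out_nd$report$removed$reason, "no data")
  # monomorphic full-call marker removed under the MAF rule
  mono <- make_gm(list(rep(0L, n), rbinom(n, 2, 0.4)), sex)
  expect_identical(filter_markers(mono)$report$removed$id, "m01")
})

test_that("sample QC is strict at the call-rate boundary and keeps a 25+25 cohort", {
  k <- 100
  n <- 72
  sex <- c(rep("male", 25), rep("female", 25),
           rep(c("male", "female"), length.out = 22))
  calls <- matrix(rbinom(n * k, 2, 0.3), n, k)
  calls[51:72, 1:4] <- NA                        # call rate 0.96 <= 0.97
  gm <- genotype_matrix(calls,
                        tibble::tibble(id = sprintf("m%03d", 1:k),
                                       chrom = "1", pos = 1:k * 100L,
                                       ref = "A", alt = "C"),
                        tibble::tibble(id = sprintf("s%02d", 1:n), sex = sex))
  out <- filter_samples(gm)
  expect_identical(nrow(out$genotypes$calls), 50L)
  expect_identical(unname(table(out$genotypes$samples$sex)["male"]), 25L)
  expect_identical(nrow(out$report$removed), 22L)
  # a sample at exactly 96% fails the strict > 0.97 rule
  expect_true(all(out$report$stats$call_rate[!out$report$stats$retained]
                  == 0.96))
  # permissive threshold keeps everyone with at least one call
  expect_identical(nrow(filter_samples(gm, 0)$genotypes$calls), 72L)
  # unusable cohort errors
  allna <- genotype_matrix(matrix(NA_integer_, 2, 2),
                           tibble::tibble(id = c("a", "b"), chrom = "1",
                                          pos = c(1L, 2L), ref = "A",
                                          alt = "C"),
                           tibble::tibble(id = c("x", "y"),
                                          sex = c("male", "female")))
  expect_error(filter_samples(allna), "unusable")
})

test_that("exact test matches enumeration oracle and fisher.test on all small-margin tables", {
  for (r1 in 1:12) for (r2 in 1:12) {
    a <- rep(0:r1, each = r2 + 1)
    cc <- rep(0:r2, times = r1 + 1)
    p <- fisher_exact_2x2(a, r1 - a, cc, r2 - cc)
    for (i in seq_along(a)) {
      expect_equal(p[i], oracle_fisher(a[i], r1 - a[i], cc[i], r2 - cc[i]),
                   tolerance = 1e-12)
    }
  }
  # independent implementation cross-check on a spread of tables
  for (tb in list(c(3, 2, 1, 4), c(25, 0, 0, 25), c(10, 15, 12, 13),
                  c(0, 8, 3, 5), c(7, 7, 7, 7))) {
    expect_equal(fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4]),
                 stats::fisher.test(matrix(tb, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-9)
  }
})

test_that("exact test is symmetric in groups, bounded, and 1 at zero margins", {
  withr::with_seed(5, {
    for (i in 1:50) {
      a <- sample(0:12, 1); b <- sample(0:12, 1)
      cc <- sample(0:12, 1); d <- sample(0:12, 1)
      if (a + b == 0 || cc + d == 0) next
      p <- fisher_exact_2x2(a, b, cc, d)
      expect_gt(p, 0)
      expect_lte(p, 1)
      expect_equal(p, fisher_exact_2x2(cc, d, a, b), tolerance = 1e-12)
    }
  })
  expect_identical(fisher_exact_2x2(0, 10, 0, 12), 1)   # zero carrier margin
  expect_identical(fisher_exact_2x2(5, 0, 7, 0), 1)     # all carriers
  expect_equal(fisher_exact_2x2(5, 5, 5, 5), 1)         # identical counts
})

test_that("dominant coding uses the cohort minor allele and errors sensibly", {
  # alt is minor: carriers are het + hom_alt
  r <- dominant_fisher(c(1, 2, 0, 0), c(0, 0, 0, 0))
  expect_identical(c(r$a, r$b, r$c, r$d), c(2L, 2L, 0L, 4L))
  expect_identical(r$carrier_allele, "alt")
  # ref is minor when alt dominates the pool
  r2 <- dominant_fisher(c(2, 2, 1, 2), c(2, 2, 2, 2))
  expect_identical(r2$carrier_allele, "ref")
  expect_identical(c(r2$a, r2$c), c(1L, 0L))
  # MAF exactly 0.5: tie broken to the alphabetically first allele letter
  r3 <- dominant_fisher(c(0, 2), c(0, 2), alleles = c(ref = "G", alt = "A"))
  expect_identical(r3$carrier_allele, "alt")
  expect_error(dominant_fisher(c(NA, NA), c(0, 1)), "non-missing")
  expect_error(bonferroni_threshold(0.05, 0), "n_tests")
  expect_equal(bonferroni_threshold(0.05, 123247), 0.05 / 123247)
  expect_equal(bonferroni_threshold(0.01, 100), 1e-4)
})

test_that("sex scan finds planted shadow markers exactly, at the perfect-separation P", {
  sim <- simulate_genotypes(sim_config(n_males = 25, n_females = 25,
                                       n_null_markers = 2000,
                                       n_shadow_markers = 10,
                                       missing_rate = 0, seed = 13))
  g <- run_sex_gwas(sim$genotypes)
  planted <- sim$truth$marker_id[sim$truth$class == "SHADOW_Y"]
  hits <- g$results$marker[g$results$significant]
  expect_setequal(hits, planted)
  expect_equal(g$results$p_value[g$results$marker %in% planted],
               rep(2 / choose(50, 25), 10), tolerance = 1e-12)
  expect_equal(g$threshold, 0.05 / 2010)
  # manhattan table is plot-ready and complete
  expect_identical(nrow(g$manhattan), 2010L)
  expect_false(anyNA(g$manhattan$neglog10p))
})

test_that("null-only arrays yield no genome-wide hits and a conservative P distribution", {
  sim <- simulate_genotypes(sim_config(n_null_markers = 1500,
                                       n_shadow_markers = 0, seed = 17))
  g <- run_sex_gwas(sim$genotypes)
  expect_identical(sum(g$results$significant), 0L)
  expect_gt(median(g$results$p_value), 0.4)
})

test_that("raising the test count never increases the number of significant markers", {
  sim <- simulate_genotypes(sim_config(n_null_markers = 500,
                                       n_shadow_markers = 5, seed = 19))
  g <- run_sex_gwas(sim$genotypes)
  p <- g$results$p_value
  n_sig <- vapply(c(10, 1e3, 1e5, 1e7),
                  function(m) sum(p <= bonferroni_threshold(0.05, m)),
                  numeric(1))
  expect_true(all(diff(n_sig) <= 0))
})

test_that("a marker missing in one sex is flagged, not fatal; label swap leaves P unchanged", {
  sex <- rep(c("male", "female"), each = 4)
  gm <- make_gm(list(c(1L, 1L, 0L, 1L, NA, NA, NA, NA),
                     c(0L, 1L, 1L, 2L, 0L, 0L, 1L, 0L)), sex)
  g <- run_sex_gwas(gm)
  expect_identical(g$results$note[1], "no_data_one_sex")
  expect_true(is.na(g$results$p_value[1]))
  expect_false(g$results$significant[1])
  # sex-label swap symmetry of the two-sided P
  swapped <- genotype_matrix(gm$calls, gm$markers,
                             tibble::tibble(id = gm$samples$id,
                                            sex = ifelse(gm$samples$sex == "male",
                                                         "female", "male")))
  expect_equal(run_sex_gwas(swapped)$results$p_value[2],
               g$results$p_value[2], tolerance = 1e-12)
})
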