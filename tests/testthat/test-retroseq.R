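# Pairwise alignment, identity, shared polymorphisms and ORF truncation.

test_that("trivial and hand-scored alignments come out exactly", {
  a <- align_global("ACGT", "ACGT")
  expect_equal(a$score, 4)
  expect_equal(a$identity, 100)
  expect_identical(nrow(a$diverged_sites), 0L)

  b <- align_global("ACGTACGT", "ACGAACGT")
  expect_equal(b$score, 6)                      # 7 matches - 1 mismatch
  expect_equal(b$identity, 87.5)
  expect_identical(b$diverged_sites$pos, 4L)
  expect_identical(b$diverged_sites$parent_base, "T")
  expect_identical(b$diverged_sites$copy_base, "A")

  expect_error(align_global("ACGT", "ACXT"), "non-DNA.*X")
  expect_error(align_global("", "ACGT"), "non-empty")
})

test_that("dynamic programming equals the exhaustive alignment oracle on short pairs", {
  withr::with_seed(61, {
    for (i in 1:14) {
      la <- sample(1:6, 1)
      lb <- sample(1:6, 1)
      a <- paste(sample(c("A", "C", "G", "T"), la, TRUE), collapse = "")
      b <- paste(sample(c("A", "C", "G", "T"), lb, TRUE), collapse = "")
      expect_equal(align_global(a, b)$score, oracle_align_score(a, b),
                   info = paste(a, b))
    }
    # a couple of longer pairs at the edge of enumerability
    for (i in 1:2) {
      a <- paste(sample(c("A", "C", "G", "T"), 7, TRUE), collapse = "")
      b <- paste(sample(c("A", "C", "G", "T"), 7, TRUE), collapse = "")
      expect_equal(align_global(a, b)$score, oracle_align_score(a, b))
    }
  })
})

test_that("alignment scores agree with an independent affine-gap implementation", {
  skip_if_not_installed("Biostrings")
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -1,
                                                     baseOnly = TRUE)
  withr::with_seed(67, {
    for (i in 1:5) {
      a <- paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = "")
      bc <- strsplit(a, "")[[1]]
      # mutate + delete a chunk to force gaps
      bc[sample(120, 8)] <- sample(c("A", "C", "G", "T"), 8, TRUE)
      bc <- bc[-(50:54)]
      b <- paste(bc, collapse = "")
      ref <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                           substitutionMatrix = submat,
                                           gapOpening = 5, gapExtension = 1)
      expect_equal(align_global(a, b)$score, Biostrings::score(ref))
    }
  })
})

test_that("percent identity honors gap-column modes and symmetry", {
  aln <- align_global("AAACCCGGGTTT", "AAACCCTTT")   # 3-bp deletion
  expect_equal(percent_identity(aln, "exclude_gaps"), 100)
  expect_equal(percent_identity(aln, "include_gaps"), round(100 * 9 / 12, 1))
  s <- random_dna(80, seed = 71)
  expect_equal(percent_identity(align_global(s, s)), 100)
  t <- random_dna(80, seed = 72)
  expect_equal(percent_identity(align_global(s, t)),
               percent_identity(align_global(t, s)))
})

test_that("simulated divergence is recovered in the 98% and 89% identity regimes", {
  tr <- "(a,b);"
  for (rate in c(0.02, 0.11)) {
    sim <- simulate_retrocopy_sequences(
      seq_sim_config(parent_length = 1500, divergence_rate = rate,
                     tree = tr, gain_branch = "a", seed = 73))
    ident <- percent_identity(align_global(sim$parent, sim$copies[["a"]]))
    se <- 100 * sqrt(rate * (1 - rate) / 1500)
    expect_lt(abs(ident - 100 * (1 - rate)), 3 * se)
  }
})

test_that("shared polymorphism counts follow the set-intersection oracle and the >2 rule", {
  parent <- random_dna(300, seed = 79)
  flip <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]
  other <- function(b) c(A = "G", C = "T", G = "A", T = "C")[[b]]
  at <- function(p) substr(parent, p, p)
  mk_copy <- function(shared_pos, own_pos) {
    s <- parent
    for (p in shared_pos) s <- sub_base(s, p, flip(at(p)))
    for (p in own_pos) s <- sub_base(s, p, other(at(p)))
    s
  }
  shared4 <- c(10, 50, 100, 150)
  refc <- mk_copy(shared4, c(200, 250))
  # exactly 2 shared -> no ancestral call (boundary of the ">2" rule)
  q2 <- mk_copy(shared4[1:2], c(30, 220))
  r2 <- shared_polymorphisms(parent, refc, q2)
  expect_identical(r2$n_shared, 2L)
  expect_false(r2$ancestral_call)
  expect_identical(r2$n_reference_only, 4L)   # 2 unshared flips + 2 own
  expect_identical(r2$n_query_only, 2L)
  # 3 shared -> ancestral call
  q3 <- mk_copy(shared4[1:3], 260)
  expect_identical(shared_polymorphisms(parent, refc, q3)$n_shared, 3L)
  expect_true(shared_polymorphisms(parent, refc, q3)$ancestral_call)
  # same position, different substituted base does not count as shared
  qdiff <- mk_copy(shared4[1:2], numeric(0))
  qdiff <- sub_base(qdiff, 100, other(at(100)))   # pos 100 shared? no: base differs
  rd <- shared_polymorphisms(parent, refc, qdiff)
  expect_identical(rd$n_shared, 2L)
  # symmetry of n_shared under swapping reference and query
  expect_identical(shared_polymorphisms(parent, q3, refc)$n_shared, 3L)
  # unalignable copy errors
  expect_error(shared_polymorphisms(parent, refc,
                                    paste(rep("A", 300), collapse = "")),
               "wrong parent")
})

test_that("copies sharing a simulated gain share its diverged sites", {
  tr <- "(urocyon,(vulpes,(lycaon,(latrans,familiaris))));"
  sim <- simulate_retrocopy_sequences(
    seq_sim_config(parent_length = 800, divergence_rate = 0.02,
                   branch_rate = 0.005, tree = tr,
                   gain_branch = "familiaris+latrans+lycaon", seed = 83))
  rep_ <- shared_polymorphisms(sim$parent, sim$copies[["familiaris"]],
                               sim$copies[["lycaon"]])
  # gain branch carries ~16 substitutions; descendants inherit them
  expect_true(rep_$ancestral_call)
  expect_gt(rep_$n_shared, 3)
})

test_that("ORF truncation detects an engineered frameshift and premature stop", {
  codons <- c("ATG", rep("CAC", 298), "TAA")
  codons[110] <- "CCT"
  codons[111] <- "AAC"
  parent <- paste(codons, collapse = "")
  expect_identical(nchar(parent), 900L)

  # identical copy: no truncation, no frameshift
  p0 <- predict_orf_truncation(parent, parent)
  expect_identical(p0$copy_protein_length, 299L)
  expect_equal(p0$truncation_fraction, 0)
  expect_length(p0$frameshift_positions, 0)

  # single-base insertion after codon 100 shifts the frame; first shifted
  # stop is engineered at codon 111 -> 110 translated codons
  copy <- paste0(substr(parent, 1, 300), "G", substr(parent, 301, 900))
  # independent check of the engineered stop via direct translation
  aa <- seqinr::translate(seqinr::s2c(substr(copy, 1, 3 * (nchar(copy) %/% 3))))
  expect_identical(which(aa == "*")[1], 111L)

  p1 <- predict_orf_truncation(parent, copy)
  expect_identical(p1$copy_protein_length, 110L)
  expect_equal(p1$truncation_fraction, 1 - 110 / 299, tolerance = 1e-9)
  expect_identical(nrow_fs <- length(p1$frameshift_positions), 1L)
  expect_true(p1$frameshift_positions >= 295 &&
                p1$frameshift_positions <= 305)

  expect_error(predict_orf_truncation(substr(parent, 1, 899), parent),
               "divisible by 3")
  expect_error(predict_orf_truncation(sub("^ATG", "CTG", parent), parent),
               "start ATG")
})
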