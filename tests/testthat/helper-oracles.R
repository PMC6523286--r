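# Independent oracles used across the suite.  Each re-derives the expected
# quantity by a different route than the implementation (direct choose()
# arithmetic, exhaustive path enumeration, exhaustive gain/loss assignment)
# so agreement is evidence, not tautology.

# Two-sided Fisher P by direct hypergeometric enumeration with choose().
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c; n <- r1 + r2
  if (k == 0 || k == n) return(1)
  xs <- max(0, k - r2):min(r1, k)
  probs <- choose(r1, xs) * choose(r2, k - xs) / choose(n, k)
  obs <- probs[xs == a]
  min(1, sum(probs[probs <= obs * (1 + 1e-7)]))
}

# Optimal global affine-gap alignment score by exhaustive enumeration of
# every alignment path (feasible for short sequences only).
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               gap_open = -5, gap_extend = -1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  best <- -Inf
  rec <- function(i, j, score, last) {
    if (i > na && j > nb) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= na && j <= nb)
      rec(i + 1, j + 1,
          score + if (ca[i] == cb[j]) match else mismatch, "d")
    if (i <= na)
      rec(i + 1, j, score + gap_extend + if (identical(last, "u")) 0 else gap_open, "u")
    if (j <= nb)
      rec(i, j + 1, score + gap_extend + if (identical(last, "l")) 0 else gap_open, "l")
    invisible()
  }
  rec(1, 1, 0, "")
  best
}

# --- Dollo oracle: exhaustive gain x loss-subset enumeration -------------
# Represent tip sets as bit masks; precompute, for one tree, every
# (single-gain, loss-subset) configuration's resulting present-tip mask and
# event count, plus the no-gain configuration.
oracle_dollo_table <- function(tree) {
  phy <- if (inherits(tree, "phylo")) tree else ape::read.tree(text = tree)
  n <- ape::Ntip(phy)
  root <- n + 1L
  nn <- n + phy$Nnode
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  desc <- integer(nn)                      # bitmask of descendant tips
  fill <- function(v) {
    if (v <= n) {
      desc[v] <<- bitwShiftL(1L, v - 1L)
    } else {
      m <- 0L
      for (ch in kids[[as.character(v)]]) {
        fill(ch)
        m <- bitwOr(m, desc[ch])
      }
      desc[v] <<- m
    }
    invisible()
  }
  fill(root)
  below <- function(g) {                   # nodes strictly below g
    out <- integer(0)
    walk <- function(v) {
      if (v > n) for (ch in kids[[as.character(v)]]) {
        out <<- c(out, ch)
        walk(ch)
      }
    }
    walk(g)
    out
  }
  present <- 0L
  events <- 0L
  for (g in seq_len(nn)) {
    bl <- below(g)
    nb <- length(bl)
    for (s in 0:(2^nb - 1)) {
      lost <- 0L
      cnt <- 0L
      for (p in seq_len(nb)) {
        if (bitwAnd(s, bitwShiftL(1L, p - 1L)) != 0L) {
          lost <- bitwOr(lost, desc[bl[p]])
          cnt <- cnt + 1L
        }
      }
      present <- c(present, bitwAnd(desc[g], bitwNot(lost)))
      events <- c(events, 1L + cnt)
    }
  }
  list(present = present, events = events, ntip = n,
       tips = phy$tip.label)
}

# Minimum events for a present/absent/unknown profile, given the table.
oracle_dollo_min <- function(tab, profile) {
  pm <- 0L
  am <- 0L
  for (i in seq_along(tab$tips)) {
    st <- profile[[tab$tips[i]]]
    if (st == "present") pm <- bitwOr(pm, bitwShiftL(1L, i - 1L))
    if (st == "absent") am <- bitwOr(am, bitwShiftL(1L, i - 1L))
  }
  ok <- bitwAnd(pm, tab$present) == pm & bitwAnd(am, tab$present) == 0L
  min(tab$events[ok])
}

# --- genotype fixtures ---------------------------------------------------
make_gm <- function(calls_by_marker, sex) {
  calls <- do.call(cbind, lapply(calls_by_marker, as.integer))
  k <- ncol(calls)
  genotype_matrix(
    calls,
    markers = tibble::tibble(id = sprintf("m%02d", seq_len(k)),
                             chrom = rep("1", k),
                             pos = seq_len(k) * 10000L,
                             ref = rep("A", k), alt = rep("C", k)),
    samples = tibble::tibble(id = sprintf("s%03d", seq_along(sex)),
                             sex = sex))
}

# substitute one base at `pos` of a sequence with a stated different base
sub_base <- function(seq, pos, base) {
  stopifnot(substr(seq, pos, pos) != base)
  paste0(substr(seq, 1, pos - 1), base, substr(seq, pos + 1, nchar(seq)))
}

random_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = ""))
}
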