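#' Global pairwise alignment with affine gap penalties
#'
#' Optimal global (end-to-end) alignment of two DNA sequences under an
#' affine gap scheme (a gap of length *k* costs
#' `gap_open + k * gap_extend`), computed by dynamic programming with
#' deterministic tie-breaking: diagonal is preferred over up (gap in
#' `seq_b`) over left (gap in `seq_a`).
#'
#' @param seq_a Parent (reference) DNA sequence; coordinates of diverged
#'   sites and indels are reported 1-based on this ungapped sequence.
#' @param seq_b Copy (query) DNA sequence.
#' @param match,mismatch,gap_open,gap_extend Scoring scheme (defaults
#'   +1 / -1 / -5 / -1).
#' @return Object of class `retro_alignment`: list with `score`,
#'   `aligned_a`/`aligned_b` (gapped rows), `identity` (percent over
#'   non-gap columns), `diverged_sites` (tibble `pos`, `parent_base`,
#'   `copy_base` for substitution columns), and `indels` (tibble `pos`,
#'   `length`, `type` with type `"ins"` = extra copy bases, `"del"` =
#'   missing copy bases; `pos` is the parent coordinate at/after which the
#'   event occurs).
#' @examples
#' aln <- align_global("ACGTACGT", "ACGAACGT")
#' aln$identity
#' aln$diverged_sites
#' @export
align_global <- function(seq_a, seq_b, match = 1, mismatch = -1,
                         gap_open = -5, gap_extend = -1) {
  seq_a <- toupper(seq_a)
  seq_b <- toupper(seq_b)
  for (s in list(seq_a, seq_b)) {
    if (!nzchar(s)) stop("sequences must be non-empty")
    bad <- setdiff(unique(strsplit(s, "")[[1]]), c("A", "C", "G", "T"))
    if (length(bad))
      stop("non-DNA characters in input: ", paste(bad, collapse = ", "))
  }
  res <- align_affine_cpp(seq_a, seq_b, match, mismatch, gap_open, gap_extend)
  ca <- strsplit(res$aligned_a, "")[[1]]
  cb <- strsplit(res$aligned_b, "")[[1]]
  parent_pos <- cumsum(ca != "-")

  both <- ca != "-" & cb != "-"
  matched <- both & ca == cb
  diverged <- both & ca != cb
  identity <- 100 * sum(matched) / sum(both)

  diverged_sites <- tibble(pos = parent_pos[diverged],
                           parent_base = ca[diverged],
                           copy_base = cb[diverged])

  gap_runs <- function(isgap, type) {
    r <- rle(isgap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    k <- r$values
    s <- starts[k]
    tibble(pos = as.integer(ifelse(s > 1, parent_pos[pmax(s - 1L, 1L)], 0L)),
           length = as.integer(r$lengths[k]),
           type = rep(type, sum(k)))
  }
  indels <- rbind(gap_runs(ca == "-", "ins"), gap_runs(cb == "-", "del"))
  indels <- indels[order(indels$pos), , drop = FALSE]

  structure(list(score = res$score, aligned_a = res$aligned_a,
                 aligned_b = res$aligned_b, identity = identity,
                 diverged_sites = diverged_sites, indels = indels),
            class = "retro_alignment")
}

#' @export
print.retro_alignment <- function(x, ...) {
  cat(sprintf("<retro_alignment> score %.0f, identity %.1f%%\n",
              x$score, x$identity))
  cat(sprintf("  diverged sites: %d; indels: %d\n",
              nrow(x$diverged_sites), nrow(x$indels)))
  invisible(x)
}

#' Percent identity of an alignment
#'
#' Matched columns over counted columns, times 100, reported to one
#' decimal.  In `"exclude_gaps"` mode (the usual "percent identity"
#' convention) only columns with a base in both rows are counted; in
#' `"include_gaps"` mode every alignment column counts, which some
#' similarity tools report instead.
#'
#' @param aln A `retro_alignment` from [align_global()].
#' @param mode `"exclude_gaps"` (default) or `"include_gaps"`.
#' @return Percentage in `[0, 100]`, rounded to 1 decimal.
#' @export
percent_identity <- function(aln, mode = c("exclude_gaps", "include_gaps")) {
  stopifnot(inherits(aln, "retro_alignment"))
  mode <- match.arg(mode)
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  matched <- sum(ca != "-" & cb != "-" & ca == cb)
  counted <- if (mode == "exclude_gaps") sum(ca != "-" & cb != "-")
             else length(ca)
  if (counted == 0) stop("no counted columns in this mode")
  round(100 * matched / counted, 1)
}
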