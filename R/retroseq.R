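#' Shared diverged sites between two retrocopies of one parent gene
#'
#' Aligns each retrocopy to the common parent, extracts the diverged-site
#' sets (single-base substitutions, in 1-based parent coordinates), and
#' counts sites shared by the two copies (same parent position *and* same
#' substituted base).  Under the ancestry rule, more than 2 shared
#' polymorphisms (i.e. `n_shared >= 3`) indicate that an ancestral version
#' of the retrocopy predates the two lineages; two or fewer do not.
#' Indels are compared separately and never count toward the rule.
#'
#' @param parent Parent DNA sequence.
#' @param reference_copy Retrocopy used as the reference (e.g. the
#'   domestic-dog Y copy).
#' @param query_copy Retrocopy from the species under test.
#' @return Object of class `shared_poly_report`: list with `n_shared`,
#'   `n_reference_only`, `n_query_only`, `n_shared_indels`,
#'   `ancestral_call` (`n_shared >= 3`), and `shared_sites` (tibble `pos`,
#'   `base`).
#' @export
shared_polymorphisms <- function(parent, reference_copy, query_copy) {
  aln_r <- align_global(parent, reference_copy)
  aln_q <- align_global(parent, query_copy)
  for (aln in list(aln_r, aln_q)) {
    if (aln$identity < 50)
      stop("copy aligns at <50% identity; wrong parent sequence?")
  }
  key <- function(d) paste(d$pos, d$copy_base)
  kr <- key(aln_r$diverged_sites)
  kq <- key(aln_q$diverged_sites)
  shared <- intersect(kr, kq)
  ikey <- function(a) paste(a$indels$pos, a$indels$length, a$indels$type)
  structure(list(
    n_shared = length(shared),
    n_reference_only = length(setdiff(kr, kq)),
    n_query_only = length(setdiff(kq, kr)),
    n_shared_indels = length(intersect(ikey(aln_r), ikey(aln_q))),
    ancestral_call = length(shared) >= 3,
    shared_sites = aln_r$diverged_sites[kr %in% shared, , drop = FALSE]),
    class = "shared_poly_report")
}

#' @export
print.shared_poly_report <- function(x, ...) {
  cat(sprintf("<shared_poly_report> shared %d | ref-only %d | query-only %d\n",
              x$n_shared, x$n_reference_only, x$n_query_only))
  cat(sprintf("  ancestral copy call (> 2 shared): %s\n", x$ancestral_call))
  invisible(x)
}

#' Predict frameshift and premature-stop truncation of a retrocopy ORF
#'
#' Aligns the retrocopy to the parent coding sequence, reads the copy in
#' the parent frame from the aligned start codon, and translates until the
#' first in-frame stop.  Alignment indels whose length is not a multiple
#' of 3 are reported as frameshifts.
#'
#' @param parent_cds Parent coding sequence: length divisible by 3, starts
#'   `ATG`, ends with a stop codon.
#' @param copy_seq Retrocopy DNA sequence.
#' @return Object of class `orf_prediction`: list with
#'   `parent_protein_length` (aa, stop excluded), `copy_protein_length`
#'   (codons translated before the first stop), `frameshift_positions`
#'   (parent coordinates of frame-disrupting indels), and
#'   `truncation_fraction` (`1 - copy/parent` when truncated, else 0).
#' @export
predict_orf_truncation <- function(parent_cds, copy_seq) {
  parent_cds <- toupper(parent_cds)
  n <- nchar(parent_cds)
  if (n %% 3 != 0) stop("parent_cds length must be divisible by 3")
  if (substr(parent_cds, 1, 3) != "ATG") stop("parent_cds must start ATG")
  if (!substr(parent_cds, n - 2, n) %in% c("TAA", "TAG", "TGA"))
    stop("parent_cds must end with a stop codon")

  aln <- align_global(parent_cds, copy_seq)
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  parent_pos <- cumsum(ca != "-")
  # the copy must align something onto the parent start codon
  start_cols <- which(ca != "-" & parent_pos <= 3)
  if (!any(cb[start_cols] != "-"))
    stop("copy has no alignable start: parent start codon unmatched")

  in_span <- seq_along(ca) >= min(start_cols)
  copy_frame <- paste(cb[in_span][cb[in_span] != "-"], collapse = "")
  n_codon <- nchar(copy_frame) %/% 3
  aa <- seqinr::translate(seqinr::s2c(substr(copy_frame, 1, 3 * n_codon)))
  stop_at <- which(aa == "*")
  copy_len <- if (length(stop_at)) stop_at[1] - 1L else n_codon

  parent_len <- n / 3 - 1
  truncation <- if (copy_len < parent_len) 1 - copy_len / parent_len else 0
  fs <- aln$indels[aln$indels$length %% 3 != 0, , drop = FALSE]
  structure(list(parent_protein_length = parent_len,
                 copy_protein_length = copy_len,
                 frameshift_positions = fs$pos,
                 truncation_fraction = truncation),
            class = "orf_prediction")
}

#' @export
print.orf_prediction <- function(x, ...) {
  cat(sprintf("<orf_prediction> parent %d aa -> copy %d aa (truncation %.1f%%)\n",
              x$parent_protein_length, x$copy_protein_length,
              100 * x$truncation_fraction))
  if (length(x$frameshift_positions))
    cat("  frameshift indel(s) near parent position:",
        paste(x$frameshift_positions, collapse = ", "), "\n")
  invisible(x)
}
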