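#' Biallelic genotype matrix with sample sex labels
#'
#' Container for array genotypes: an integer matrix of calls (samples in
#' rows, markers in columns) coded `0` = homozygous reference, `1` =
#' heterozygous, `2` = homozygous alternate, `NA` = missing, together with a
#' marker table and a sample table.
#'
#' @param calls Integer matrix, samples x markers, values in `{0, 1, 2, NA}`.
#' @param markers Data frame with columns `id`, `chrom`, `pos` and the two
#'   allele letters `ref`, `alt` (one row per column of `calls`).
#' @param samples Data frame with columns `id` and `sex`
#'   (`"male"`/`"female"`; one row per row of `calls`).
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `markers`, `samples`.
#' @examples
#' gm <- genotype_matrix(
#'   calls = matrix(c(0L, 1L, 1L, 2L), nrow = 2,
#'                  dimnames = list(c("s1", "s2"), c("m1", "m2"))),
#'   markers = tibble::tibble(id = c("m1", "m2"), chrom = c("1", "2"),
#'                            pos = c(100L, 200L), ref = c("A", "G"),
#'                            alt = c("C", "T")),
#'   samples = tibble::tibble(id = c("s1", "s2"), sex = c("male", "female")))
#' gm
#' @export
genotype_matrix <- function(calls, markers, samples) {
  markers <- as_tibble(markers)
  samples <- as_tibble(samples)
  stopifnot(is.matrix(calls),
            nrow(calls) == nrow(samples),
            ncol(calls) == nrow(markers),
            all(c("id", "chrom", "pos") %in% names(markers)),
            all(c("id", "sex") %in% names(samples)))
  if (!all(samples$sex %in% c("male", "female")))
    stop("sample sex must be 'male' or 'female' for every sample")
  if (any(markers$pos < 1)) stop("marker positions are 1-based (pos >= 1)")
  storage.mode(calls) <- "integer"
  if (!all(calls %in% c(0L, 1L, 2L) | is.na(calls)))
    stop("genotype calls must be 0 (hom ref), 1 (het), 2 (hom alt) or NA")
  dimnames(calls) <- list(samples$id, markers$id)
  structure(list(calls = calls, markers = markers, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  ns <- table(x$samples$sex)
  cat(sprintf("<genotype_matrix> %d samples (%d male / %d female) x %d markers\n",
              nrow(x$calls),
              sum(x$samples$sex == "male"), sum(x$samples$sex == "female"),
              ncol(x$calls)))
  cat(sprintf("  missing call fraction: %.4f\n", mean(is.na(x$calls))))
  invisible(x)
}

# Normalise genotype encodings: integers 0/1/2 or the character labels
# "hom_ref"/"het"/"hom_alt" ("missing"/"" -> NA).
.as_geno <- function(x) {
  if (is.logical(x) && all(is.na(x))) return(as.integer(x))
  if (is.numeric(x)) {
    bad <- !is.na(x) & !(x %in% c(0, 1, 2))
    if (any(bad)) stop("numeric genotype codes must be 0, 1, 2 or NA")
    return(as.integer(x))
  }
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    x[x %in% c("missing", "")] <- NA_character_
    lev <- c(hom_ref = 0L, het = 1L, hom_alt = 2L)
    bad <- !is.na(x) & !(x %in% names(lev))
    if (any(bad))
      stop("unknown genotype labels: ", paste(unique(x[bad]), collapse = ", "))
    return(unname(lev[x]))
  }
  stop("genotypes must be integer codes or character labels")
}

# Subset a genotype_matrix by logical/index vectors.
.gm_subset <- function(gm, sample_keep = NULL, marker_keep = NULL) {
  if (is.null(sample_keep)) sample_keep <- seq_len(nrow(gm$calls))
  if (is.null(marker_keep)) marker_keep <- seq_len(ncol(gm$calls))
  genotype_matrix(gm$calls[sample_keep, marker_keep, drop = FALSE],
                  gm$markers[marker_keep, , drop = FALSE],
                  gm$samples[sample_keep, , drop = FALSE])
}
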