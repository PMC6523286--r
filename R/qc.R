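#' Marker-level quality control
#'
#' Removes markers with low call rate or low minor allele frequency, the
#' standard array QC step run before a case-control scan.  Call rate is the
#' fraction of non-missing calls; MAF is computed from non-missing calls
#' only.  Boundary values (exactly at the threshold) are retained.
#'
#' @param gm A [genotype_matrix()].
#' @param min_call_rate Minimum per-marker call rate (default 0.95;
#'   retained when `call_rate >= min_call_rate`).
#' @param min_maf Minimum minor allele frequency (default 0.05; retained
#'   when `maf >= min_maf`).
#' @return List with `genotypes` (the filtered [genotype_matrix()]) and
#'   `report`: per-marker `stats` tibble (`id`, `call_rate`, `maf`,
#'   `retained`) and a `removed` tibble (`id`, `reason`).  A marker with no
#'   non-missing calls is removed with reason `"no data"`.
#' @export
filter_markers <- function(gm, min_call_rate = 0.95, min_maf = 0.05) {
  stopifnot(inherits(gm, "genotype_matrix"), ncol(gm$calls) > 0)
  calls <- gm$calls
  n <- nrow(calls)
  n_obs <- unname(colSums(!is.na(calls)))
  call_rate <- n_obs / n
  alt <- unname(colSums(calls, na.rm = TRUE))
  af <- ifelse(n_obs > 0, alt / (2 * n_obs), NA_real_)
  maf <- pmin(af, 1 - af)

  eps <- 1e-12
  no_data <- n_obs == 0
  low_cr <- !no_data & call_rate < min_call_rate - eps
  low_maf <- !no_data & !low_cr & maf < min_maf - eps
  keep <- !(no_data | low_cr | low_maf)

  reason <- character(0)
  removed_id <- character(0)
  if (any(!keep)) {
    removed_id <- gm$markers$id[!keep]
    reason <- ifelse(no_data[!keep], "no data",
                     ifelse(low_cr[!keep],
                            sprintf("call rate %.4f < %.4f",
                                    call_rate[!keep], min_call_rate),
                            sprintf("MAF %.4f < %.4f", maf[!keep], min_maf)))
  }
  list(genotypes = .gm_subset(gm, marker_keep = keep),
       report = list(
         stats = tibble(id = gm$markers$id, call_rate = call_rate,
                        maf = maf, retained = keep),
         removed = tibble(id = removed_id, reason = reason)))
}

#' Sample-level quality control
#'
#' Removes samples whose genotyping call rate is not strictly above the
#' threshold (retained when `call_rate > min_call_rate`).
#'
#' @param gm A [genotype_matrix()].
#' @param min_call_rate Minimum per-sample call rate, exclusive
#'   (default 0.97).
#' @return List with `genotypes` and `report` (as in [filter_markers()]).
#'   An error is raised if no sample survives.
#' @export
filter_samples <- function(gm, min_call_rate = 0.97) {
  stopifnot(inherits(gm, "genotype_matrix"), nrow(gm$calls) > 0)
  call_rate <- unname(rowMeans(!is.na(gm$calls)))
  keep <- call_rate > min_call_rate
  if (!any(keep))
    stop("all samples removed at call rate > ", min_call_rate,
         "; cohort unusable")
  list(genotypes = .gm_subset(gm, sample_keep = keep),
       report = list(
         stats = tibble(id = gm$samples$id, call_rate = call_rate,
                        retained = keep),
         removed = tibble(id = gm$samples$id[!keep],
                          reason = sprintf("call rate %.4f <= %.4f",
                                           call_rate[!keep], min_call_rate))))
}
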