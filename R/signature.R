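#' Thresholds for the male-specific duplication signature
#'
#' The underlying evidence is qualitative (a duplication shows increased
#' coverage, heterozygosity, discordant mates and low-mapQ reads in males
#' only), so each criterion carries an explicit, tunable threshold.  A
#' window is called a duplication when the depth-ratio criterion holds and
#' at least `min_supporting_criteria` of the three supporting excesses
#' exceed their thresholds.
#'
#' @param min_depth_ratio Minimum male/female mean-depth ratio
#'   (default 1.3).
#' @param min_het_excess Minimum male-minus-female het-site density excess
#'   in sites/kb (default 1.0).
#' @param min_discordant_excess,min_lowmapq_excess Minimum excess
#'   fractions (default 0.05 each).
#' @param min_supporting_criteria How many of the three supporting
#'   criteria must hold in addition to depth (default 2).
#' @return A `signature_thresholds` list.
#' @export
signature_thresholds <- function(min_depth_ratio = 1.3, min_het_excess = 1.0,
                                 min_discordant_excess = 0.05,
                                 min_lowmapq_excess = 0.05,
                                 min_supporting_criteria = 2) {
  vals <- c(min_depth_ratio, min_het_excess, min_discordant_excess,
            min_lowmapq_excess, min_supporting_criteria)
  if (any(vals < 0)) stop("thresholds must be >= 0")
  structure(list(min_depth_ratio = min_depth_ratio,
                 min_het_excess = min_het_excess,
                 min_discordant_excess = min_discordant_excess,
                 min_lowmapq_excess = min_lowmapq_excess,
                 min_supporting_criteria = as.integer(min_supporting_criteria)),
            class = "signature_thresholds")
}

#' Contrast male vs female alignment features per window
#'
#' Computes per-window sex-mean features from a feature track table and
#' calls male-specific duplication signatures.  With one sample per sex
#' this degrades gracefully to a single-sample contrast.  The depth ratio
#' divides by the female mean, substituting 0.5 when the female mean is
#' zero so zero-coverage windows do not divide by zero.  Windows where a
#' sex is absent are flagged `uninformative` and never called.
#'
#' @param tracks Feature track tibble as produced by
#'   [simulate_feature_tracks()] / [read_tracks()]: columns `sample`,
#'   `sex`, `window_start`, `window_end`, `depth`, `het_density`,
#'   `discordant_frac`, `lowmapq_frac`.
#' @param thresholds A [signature_thresholds()].
#' @return Tibble with one row per window: the four sex-mean contrasts
#'   (`depth_ratio`, `het_excess`, `discordant_excess`, `lowmapq_excess`),
#'   `n_criteria_met` (supporting criteria only), `is_duplication` and
#'   `uninformative`.
#' @export
contrast_windows <- function(tracks, thresholds = signature_thresholds()) {
  stopifnot(inherits(thresholds, "signature_thresholds"))
  tracks <- as_tibble(tracks)
  need <- c("sample", "sex", "window_start", "window_end", "depth",
            "het_density", "discordant_frac", "lowmapq_frac")
  stopifnot(all(need %in% names(tracks)))
  if (!all(tracks$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")

  key <- paste(tracks$window_start, tracks$window_end)
  rows <- lapply(split(seq_len(nrow(tracks)), key), function(i) {
    w <- tracks[i, ]
    mm <- w[w$sex == "male", ]
    ff <- w[w$sex == "female", ]
    uninformative <- nrow(mm) == 0 || nrow(ff) == 0
    if (uninformative) {
      return(tibble(window_start = w$window_start[1],
                    window_end = w$window_end[1], depth_ratio = NA_real_,
                    het_excess = NA_real_, discordant_excess = NA_real_,
                    lowmapq_excess = NA_real_, n_criteria_met = NA_integer_,
                    is_duplication = FALSE, uninformative = TRUE))
    }
    fd <- mean(ff$depth)
    depth_ratio <- mean(mm$depth) / (if (fd > 0) fd else 0.5)
    het_excess <- mean(mm$het_density) - mean(ff$het_density)
    disc_excess <- mean(mm$discordant_frac) - mean(ff$discordant_frac)
    lowq_excess <- mean(mm$lowmapq_frac) - mean(ff$lowmapq_frac)
    supporting <- sum(het_excess >= thresholds$min_het_excess,
                      disc_excess >= thresholds$min_discordant_excess,
                      lowq_excess >= thresholds$min_lowmapq_excess)
    tibble(window_start = w$window_start[1], window_end = w$window_end[1],
           depth_ratio = depth_ratio, het_excess = het_excess,
           discordant_excess = disc_excess, lowmapq_excess = lowq_excess,
           n_criteria_met = as.integer(supporting),
           is_duplication = depth_ratio >= thresholds$min_depth_ratio &&
             supporting >= thresholds$min_supporting_criteria,
           uninformative = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$window_start), , drop = FALSE]
}

#' Gene-level retrocopy-candidate verdict from window calls
#'
#' A retrocopy is spliced, so its duplication signature should appear in
#' exon windows only.  A gene is a retrocopy candidate when at least
#' `min_exon_frac` of its exon windows carry duplication calls and no
#' intron-only window does; intronic calls flag a tandem-duplication-like
#' event instead.
#'
#' @param calls Output of [contrast_windows()].
#' @param exon_windows,intron_windows `window_start` values of the gene's
#'   exon and intron-only windows (introns may be empty).
#' @param min_exon_frac Minimum fraction of called exon windows
#'   (default 0.5).
#' @return List with `candidate` (logical), `exon_call_frac`,
#'   `n_intron_called` and `flag` (`"retrocopy_candidate"`,
#'   `"intronic_signal"`, or `"no_signal"`).
#' @export
summarize_region_call <- function(calls, exon_windows,
                                  intron_windows = numeric(),
                                  min_exon_frac = 0.5) {
  if (length(exon_windows) == 0) stop("gene has no exon windows")
  ex <- calls[calls$window_start %in% exon_windows, ]
  if (nrow(ex) < length(exon_windows))
    stop("calls do not cover every exon window")
  intr <- calls[calls$window_start %in% intron_windows, ]
  exon_frac <- mean(ex$is_duplication)
  n_intron <- sum(intr$is_duplication)
  candidate <- exon_frac >= min_exon_frac && n_intron == 0
  list(candidate = candidate, exon_call_frac = exon_frac,
       n_intron_called = n_intron,
       flag = if (candidate) "retrocopy_candidate"
              else if (n_intron > 0) "intronic_signal" else "no_signal")
}
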