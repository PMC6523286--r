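#' Configuration for the alignment feature-track simulator
#'
#' Emulates per-window alignment summaries (mean depth, heterozygous-site
#' density, discordant-mate fraction, low-mapQ fraction) for a genomic
#' segment harbouring a gene whose exons have a diverged retrocopy on the
#' Y.  In male samples the exon windows show the duplication signature:
#' depth scaled by `dup_depth_factor` and elevated heterozygosity,
#' discordant-mate and low-mapQ rates; female samples and non-exon windows
#' stay at background.
#'
#' @param n_windows Number of windows.
#' @param exon_windows Integer indices (1-based, within `1:n_windows`) of
#'   windows overlapping exons of the retrocopied gene.
#' @param base_depth Expected background read depth.
#' @param dup_depth_factor Depth multiplier in male exon windows (> 1).
#' @param het_site_rate Per-bp heterozygous-site rate in male exon windows
#'   (elevated rate; background is `bg_het_rate`).
#' @param discordant_frac,lowmapq_frac Discordant-mate and low-mapQ read
#'   fractions in male exon windows.
#' @param bg_het_rate,bg_discordant,bg_lowmapq Background rates everywhere
#'   else.
#' @param window_bp Window width in bp.
#' @param depth_cv Coefficient of variation of per-window mean depth.
#' @param seed Integer seed.
#' @return A `track_sim_config` list.
#' @export
track_sim_config <- function(n_windows = 200, exon_windows = integer(),
                             base_depth = 30, dup_depth_factor = 1.5,
                             het_site_rate = 0.004, discordant_frac = 0.15,
                             lowmapq_frac = 0.20, bg_het_rate = 0.001,
                             bg_discordant = 0.01, bg_lowmapq = 0.02,
                             window_bp = 1000, depth_cv = 0.05, seed = 1) {
  exon_windows <- as.integer(exon_windows)
  if (length(exon_windows) &&
      (any(exon_windows < 1) || any(exon_windows > n_windows)))
    stop("exon_windows must lie within 1:n_windows")
  if (dup_depth_factor <= 1) stop("dup_depth_factor must be > 1")
  rates <- c(het_site_rate, discordant_frac, lowmapq_frac,
             bg_het_rate, bg_discordant, bg_lowmapq)
  if (any(rates < 0) || any(rates > 1)) stop("rates must be in [0, 1]")
  structure(list(n_windows = as.integer(n_windows),
                 exon_windows = exon_windows, base_depth = base_depth,
                 dup_depth_factor = dup_depth_factor,
                 het_site_rate = het_site_rate,
                 discordant_frac = discordant_frac,
                 lowmapq_frac = lowmapq_frac, bg_het_rate = bg_het_rate,
                 bg_discordant = bg_discordant, bg_lowmapq = bg_lowmapq,
                 window_bp = as.integer(window_bp), depth_cv = depth_cv,
                 seed = as.integer(seed)),
            class = "track_sim_config")
}

#' Simulate per-window alignment feature tracks
#'
#' @param cfg A [track_sim_config()].
#' @param sex_of_samples Named character vector mapping sample id to
#'   `"male"`/`"female"`.
#' @return Tibble with one row per sample x window: `sample`, `sex`,
#'   `window_start`, `window_end`, `depth`, `het_density` (het sites per
#'   kb), `discordant_frac`, `lowmapq_frac`.
#' @examples
#' cfg <- track_sim_config(n_windows = 20, exon_windows = c(5, 6), seed = 7)
#' tr <- simulate_feature_tracks(cfg, c(m1 = "male", f1 = "female"))
#' @export
simulate_feature_tracks <- function(cfg, sex_of_samples) {
  stopifnot(inherits(cfg, "track_sim_config"))
  if (is.null(names(sex_of_samples)) || !length(sex_of_samples))
    stop("sex_of_samples must be a non-empty named vector")
  if (!all(sex_of_samples %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")

  withr::with_seed(cfg$seed, {
    nw <- cfg$n_windows
    starts <- (seq_len(nw) - 1L) * cfg$window_bp + 1L
    ends <- seq_len(nw) * cfg$window_bp
    is_exon <- seq_len(nw) %in% cfg$exon_windows
    out <- vector("list", length(sex_of_samples))
    for (s in seq_along(sex_of_samples)) {
      sex <- sex_of_samples[[s]]
      dup <- is_exon & sex == "male"
      depth_mean <- ifelse(dup, cfg$base_depth * cfg$dup_depth_factor,
                           cfg$base_depth)
      depth <- pmax(0, rnorm(nw, depth_mean, cfg$depth_cv * depth_mean))
      het_rate <- ifelse(dup, cfg$het_site_rate, cfg$bg_het_rate)
      het_density <- rpois(nw, het_rate * cfg$window_bp) /
        (cfg$window_bp / 1000)
      # fractions observed on a finite read sample (~150 bp per read)
      n_reads <- pmax(1, rpois(nw, depth * cfg$window_bp / 150))
      disc <- rbinom(nw, n_reads,
                     ifelse(dup, cfg$discordant_frac, cfg$bg_discordant)) /
        n_reads
      lowq <- rbinom(nw, n_reads,
                     ifelse(dup, cfg$lowmapq_frac, cfg$bg_lowmapq)) / n_reads
      out[[s]] <- tibble(sample = names(sex_of_samples)[s], sex = sex,
                         window_start = starts, window_end = ends,
                         depth = depth, het_density = het_density,
                         discordant_frac = disc, lowmapq_frac = lowq)
    }
    do.call(rbind, out)
  })
}
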