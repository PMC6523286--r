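#' Classify the sex-genotype pattern of a marker
#'
#' A marker is `SHADOW_Y` when (up to `male_tolerance`) every non-missing
#' male is heterozygous and every non-missing female shares one homozygous
#' genotype - the pattern produced by a diverged, hemizygous Y paralog
#' cross-hybridizing with an autosomal/X probe.  It is `EXCLUDED_HOM` when
#' females are monoallelic but males mix heterozygous and homozygous calls
#' beyond tolerance (a pattern inconsistent with a simple hemizygous
#' paralog), and `OTHER` otherwise.  "Monoallelic" requires a homozygous
#' genotype: heterozygous females disqualify both non-OTHER patterns.
#'
#' @param male,female Genotype calls per sex (codes `0/1/2/NA` or labels).
#' @param male_tolerance Maximum fraction of non-missing males allowed to
#'   be non-heterozygous while still calling `SHADOW_Y` (default 0:
#'   strict perfect separation).
#' @return Object of class `pattern_call`: list with `pattern`,
#'   `n_male_het`, `n_male_hom_ref`, `n_male_hom_alt`,
#'   `n_female_distinct_genotypes`.
#' @examples
#' classify_marker(rep("het", 25), rep("hom_ref", 25))$pattern  # SHADOW_Y
#' @export
classify_marker <- function(male, female, male_tolerance = 0) {
  male <- .as_geno(male)
  female <- .as_geno(female)
  male <- male[!is.na(male)]
  female <- female[!is.na(female)]
  if (length(male) == 0 || length(female) == 0)
    stop("each sex needs at least one non-missing genotype call")

  n_het <- sum(male == 1L)
  n_hr <- sum(male == 0L)
  n_ha <- sum(male == 2L)
  fem_geno <- unique(female)
  fem_mono_hom <- length(fem_geno) == 1 && fem_geno %in% c(0L, 2L)
  frac_nonhet <- (n_hr + n_ha) / length(male)

  pattern <- if (fem_mono_hom && frac_nonhet <= male_tolerance + 1e-12)
    "SHADOW_Y"
  else if (fem_mono_hom && n_het > 0 && (n_hr + n_ha) > 0)
    "EXCLUDED_HOM"
  else "OTHER"

  structure(list(pattern = pattern, n_male_het = n_het,
                 n_male_hom_ref = n_hr, n_male_hom_alt = n_ha,
                 n_female_distinct_genotypes = length(fem_geno)),
            class = "pattern_call")
}

#' Classify a set of markers of a genotype matrix
#'
#' Applies [classify_marker()] across markers (by default all of them) and
#' returns one row per marker.
#'
#' @param gm A [genotype_matrix()].
#' @param marker_ids Markers to classify (default: all).
#' @param male_tolerance Passed to [classify_marker()].
#' @return Tibble with `id`, `chrom`, `pos`, `pattern` and the supporting
#'   counts.
#' @export
classify_markers <- function(gm, marker_ids = NULL, male_tolerance = 0) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(marker_ids)) marker_ids <- gm$markers$id
  idx <- match(marker_ids, gm$markers$id)
  if (anyNA(idx)) stop("unknown marker ids")
  male <- gm$samples$sex == "male"
  rows <- lapply(idx, function(j) {
    pc <- classify_marker(gm$calls[male, j], gm$calls[!male, j],
                          male_tolerance)
    tibble(id = gm$markers$id[j], chrom = gm$markers$chrom[j],
           pos = gm$markers$pos[j], pattern = pc$pattern,
           n_male_het = pc$n_male_het, n_male_hom_ref = pc$n_male_hom_ref,
           n_male_hom_alt = pc$n_male_hom_alt,
           n_female_distinct_genotypes = pc$n_female_distinct_genotypes)
  })
  do.call(rbind, rows)
}

#' Merge markers into genomic regions by single-linkage clustering
#'
#' Consecutive markers on one chromosome join a region when the gap
#' between them is at most `max_gap`; the region span runs from the lowest
#' to the highest member position (1-based inclusive coordinates).
#'
#' @param markers Data frame with columns `id`, `chrom`, `pos`.
#' @param max_gap Maximum gap in bp (default 1e6).
#' @return Tibble with `region_id`, `chrom`, `start`, `end`, `span_bp`
#'   (`end - start`), `n_markers` and a `markers` list-column of member
#'   ids (sorted by position).
#' @export
cluster_regions <- function(markers, max_gap = 1e6) {
  markers <- as_tibble(markers)
  if (nrow(markers) == 0)
    return(tibble(region_id = character(), chrom = character(),
                  start = integer(), end = integer(), span_bp = integer(),
                  n_markers = integer(), markers = list()))
  stopifnot(all(c("id", "chrom", "pos") %in% names(markers)))
  m <- markers[order(markers$chrom, markers$pos), ]
  m$pos <- as.integer(m$pos)
  nm <- nrow(m)
  new_grp <- c(TRUE, m$chrom[-1] != m$chrom[-nm] |
                 (m$pos[-1] - m$pos[-nm]) > max_gap)
  grp <- cumsum(new_grp)
  out <- lapply(split(seq_len(nm), grp), function(i) {
    tibble(chrom = m$chrom[i[1]], start = min(m$pos[i]),
           end = max(m$pos[i]), span_bp = max(m$pos[i]) - min(m$pos[i]),
           n_markers = length(i), markers = list(m$id[i]))
  })
  out <- do.call(rbind, out)
  out$region_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  out[, c("region_id", "chrom", "start", "end", "span_bp", "n_markers",
          "markers")]
}

#' Annotation intervals for region categorisation
#'
#' @param genes Data frame `chrom`, `start`, `end`, `name` with 1-based
#'   inclusive gene intervals (use [read_bed()] to ingest BED, which
#'   converts coordinates).
#' @param chrom_lengths Data frame `chrom`, `length`.
#' @param centromeres Optional data frame `chrom`, `start`, `end`.
#' @param telomere_window,centromere_window Window sizes in bp (default
#'   500 kb) within which a marker counts as telomeric/centromeric.
#' @return An `annotation_set` list.
#' @export
annotation_set <- function(genes, chrom_lengths, centromeres = NULL,
                           telomere_window = 5e5, centromere_window = 5e5) {
  genes <- as_tibble(genes)
  chrom_lengths <- as_tibble(chrom_lengths)
  stopifnot(all(c("chrom", "start", "end", "name") %in% names(genes)),
            all(c("chrom", "length") %in% names(chrom_lengths)))
  if (!is.null(centromeres)) centromeres <- as_tibble(centromeres)
  len <- setNames(chrom_lengths$length, chrom_lengths$chrom)
  ok <- genes$chrom %in% names(len) &
    genes$end <= len[genes$chrom] & genes$start >= 1
  if (!all(ok)) stop("gene intervals outside chromosome lengths")
  structure(list(genes = genes, chrom_lengths = chrom_lengths,
                 centromeres = centromeres,
                 telomere_window = telomere_window,
                 centromere_window = centromere_window),
            class = "annotation_set")
}

# category of a single marker position, in priority order
.marker_category <- function(chrom, pos, ann) {
  g <- ann$genes
  hit <- g$chrom == chrom & g$start <= pos & pos <= g$end
  if (any(hit))
    return(list(category = "genic", gene = g$name[hit][1]))
  len <- ann$chrom_lengths$length[match(chrom, ann$chrom_lengths$chrom)]
  if (is.na(len)) stop("chromosome ", chrom, " absent from lengths table")
  if (pos <= ann$telomere_window || pos > len - ann$telomere_window)
    return(list(category = "telomeric", gene = NA_character_))
  if (!is.null(ann$centromeres)) {
    ce <- ann$centromeres
    near <- ce$chrom == chrom & pos >= ce$start - ann$centromere_window &
      pos <= ce$end + ann$centromere_window
    if (any(near))
      return(list(category = "centromeric", gene = NA_character_))
  }
  list(category = "intergenic", gene = NA_character_)
}

#' Annotate regions against gene, telomere and centromere intervals
#'
#' Each member marker is categorised (genic with gene name, else telomeric
#' within `telomere_window` of a chromosome end, else centromeric within
#' `centromere_window` of a centromere interval, else intergenic); a
#' region's category set is the union over its members.
#'
#' @param regions Output of [cluster_regions()].
#' @param markers Data frame `id`, `chrom`, `pos` covering the region
#'   members.
#' @param ann An [annotation_set()].
#' @return `regions` with added `categories` (comma-joined union) and
#'   `genes` (comma-joined gene names, `NA` if none) columns, plus a
#'   `marker_annotation` attribute tibble (`id`, `category`, `gene`).
#' @export
annotate_regions <- function(regions, markers, ann) {
  stopifnot(inherits(ann, "annotation_set"))
  markers <- as_tibble(markers)
  per <- lapply(seq_len(nrow(markers)), function(i)
    .marker_category(markers$chrom[i], markers$pos[i], ann))
  marker_ann <- tibble(id = markers$id,
                       category = vapply(per, `[[`, character(1), "category"),
                       gene = vapply(per, `[[`, character(1), "gene"))
  cats <- character(nrow(regions))
  genes <- character(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    ids <- regions$markers[[i]]
    sub <- marker_ann[marker_ann$id %in% ids, ]
    cats[i] <- paste(sort(unique(sub$category)), collapse = ",")
    gg <- sort(unique(sub$gene[!is.na(sub$gene)]))
    genes[i] <- if (length(gg)) paste(gg, collapse = ",") else NA_character_
  }
  regions$categories <- cats
  regions$genes <- genes
  attr(regions, "marker_annotation") <- marker_ann
  regions
}

#' Summary counts for a classified marker catalog
#'
#' @param calls Data frame with one row per marker: `chrom`, `pattern`
#'   (`SHADOW_Y` / `EXCLUDED_HOM` / `OTHER`) and optionally `gene`
#'   (`NA` when not in a gene).
#' @param regions Optional output of [cluster_regions()].
#' @return List of counts: by pattern, by chromosome class
#'   (autosome/X/Y), `n_retained_nonY` (shadow-Y pattern off the Y
#'   chromosome), `n_genic_retained`, `n_genes_retained` with the gene
#'   names, and `n_regions`.
#' @export
summarize_catalog <- function(calls, regions = NULL) {
  calls <- as_tibble(calls)
  if (nrow(calls) == 0)
    return(list(n_markers = 0L, n_shadow = 0L, n_excluded = 0L,
                n_other = 0L, n_autosomal = 0L, n_x = 0L, n_y = 0L,
                n_retained_nonY = 0L, n_genic_retained = 0L,
                n_genes_retained = 0L, genes_retained = character(0),
                n_regions = if (is.null(regions)) NA_integer_ else 0L))
  stopifnot(all(c("chrom", "pattern") %in% names(calls)))
  chrom <- toupper(as.character(calls$chrom))
  is_y <- chrom == "Y"
  is_x <- chrom == "X"
  retained <- calls$pattern == "SHADOW_Y" & !is_y
  gene <- if ("gene" %in% names(calls)) calls$gene else
    rep(NA_character_, nrow(calls))
  genes_ret <- sort(unique(gene[retained & !is.na(gene)]))
  list(n_markers = nrow(calls),
       n_shadow = sum(calls$pattern == "SHADOW_Y"),
       n_excluded = sum(calls$pattern == "EXCLUDED_HOM"),
       n_other = sum(calls$pattern == "OTHER"),
       n_autosomal = sum(!is_x & !is_y),
       n_x = sum(is_x), n_y = sum(is_y),
       n_retained_nonY = sum(retained),
       n_genic_retained = sum(retained & !is.na(gene)),
       n_genes_retained = length(genes_ret),
       genes_retained = genes_ret,
       n_regions = if (is.null(regions)) NA_integer_ else nrow(regions))
}
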