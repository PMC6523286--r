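#' Published catalog of sex-associated CanineHD array markers
#'
#' The 50 genome-wide significant markers from a sex GWAS in a German
#' shepherd cohort (25 males vs 25 females on the Illumina CanineHD
#' array), all sharing the perfect-separation exact P-value.  The catalog
#' lists each marker's mapped chromosome and position and, where the
#' marker falls inside a gene, the gene symbol and sequence context.  The
#' marker at chrX:60395963 (in *PGK1*) is the one whose male genotypes
#' mixed heterozygous and homozygous calls and was excluded from the
#' shadow-Y set; two markers map to the Y itself.
#'
#' @return Tibble with `id` (`chr<chrom>:<pos>`), `chrom`, `pos`, `gene`
#'   (`NA` when intergenic/unannotated) and `context`.
#' @examples
#' cat50 <- sex_marker_catalog()
#' nrow(cat50)                         # 50
#' table(cat50$chrom)
#' @export
sex_marker_catalog <- function() {
  path <- system.file("extdata", "canid_sex_gwas_markers.tsv",
                      package = "shadowY", mustWork = TRUE)
  x <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  na.strings = "", fill = TRUE)
  tibble(id = sprintf("chr%s:%d", x$chrom, x$pos),
         chrom = as.character(x$chrom), pos = as.integer(x$pos),
         gene = x$gene, context = x$context)
}
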