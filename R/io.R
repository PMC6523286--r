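#' Write genotypes as PLINK ped/map text files
#'
#' Whitespace-delimited dialect: ped columns are family id, individual id,
#' paternal id (0), maternal id (0), sex (1 = male, 2 = female), phenotype
#' (-9), then two allele letters per marker with `0 0` for a missing call;
#' map columns are chromosome, marker id, genetic distance (0) and bp
#' position.
#'
#' @param gm A [genotype_matrix()].
#' @param prefix Output path prefix; writes `<prefix>.ped` and
#'   `<prefix>.map`.
#' @return Invisibly, the two file paths.
#' @export
write_plink <- function(gm, prefix) {
  stopifnot(inherits(gm, "genotype_matrix"))
  mk <- gm$markers
  map <- data.frame(chrom = mk$chrom, id = mk$id, cm = 0, bp = mk$pos)
  write.table(map, paste0(prefix, ".map"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)

  n <- nrow(gm$calls)
  k <- ncol(gm$calls)
  a1 <- matrix("0", n, k)
  a2 <- matrix("0", n, k)
  ref <- matrix(mk$ref, n, k, byrow = TRUE)
  alt <- matrix(mk$alt, n, k, byrow = TRUE)
  g <- gm$calls
  a1[!is.na(g) & g <= 1L] <- ref[!is.na(g) & g <= 1L]
  a1[!is.na(g) & g == 2L] <- alt[!is.na(g) & g == 2L]
  a2[!is.na(g) & g == 0L] <- ref[!is.na(g) & g == 0L]
  a2[!is.na(g) & g >= 1L] <- alt[!is.na(g) & g >= 1L]

  geno <- matrix(paste(a1, a2), n, k)
  lines <- vapply(seq_len(n), function(i)
    paste(c(gm$samples$id[i], gm$samples$id[i], "0", "0",
            if (gm$samples$sex[i] == "male") "1" else "2", "-9",
            geno[i, ]), collapse = " "),
    character(1))
  writeLines(lines, paste0(prefix, ".ped"))
  invisible(c(ped = paste0(prefix, ".ped"), map = paste0(prefix, ".map")))
}

#' Read PLINK ped/map text files into a genotype matrix
#'
#' Sex is taken from ped column 5 (1 = male, 2 = female); `0 0` is a
#' missing call.  Allele letters are ordered alphabetically per marker
#' (first observed letter = reference), so hom-ref/hom-alt labels may swap
#' relative to the writer; dominant-model results are invariant to this
#' because the minor allele is recomputed from the data.
#'
#' @param prefix Path prefix of `<prefix>.ped` / `<prefix>.map`, or use
#'   `ped`/`map` to point at the two files directly.
#' @param ped,map Optional explicit file paths.
#' @return A [genotype_matrix()].
#' @export
read_plink <- function(prefix = NULL, ped = NULL, map = NULL) {
  if (!is.null(prefix)) {
    ped <- paste0(prefix, ".ped")
    map <- paste0(prefix, ".map")
  }
  mp <- read.table(map, header = FALSE, colClasses = "character")
  names(mp) <- c("chrom", "id", "cm", "bp")
  k <- nrow(mp)
  pd <- read.table(ped, header = FALSE, colClasses = "character")
  if (ncol(pd) != 6 + 2 * k)
    stop("ped/map mismatch: expected ", 6 + 2 * k, " ped columns")
  sex_code <- pd[[5]]
  if (!all(sex_code %in% c("1", "2")))
    stop("ped column 5 must code sex as 1 (male) / 2 (female)")
  n <- nrow(pd)

  a1 <- as.matrix(pd[, 6 + 2 * seq_len(k) - 1, drop = FALSE])
  a2 <- as.matrix(pd[, 6 + 2 * seq_len(k), drop = FALSE])
  calls <- matrix(NA_integer_, n, k)
  ref <- character(k)
  alt <- character(k)
  for (j in seq_len(k)) {
    obs <- sort(setdiff(unique(c(a1[, j], a2[, j])), "0"))
    if (length(obs) > 2) stop("marker ", mp$id[j], " has >2 alleles")
    ref[j] <- if (length(obs) >= 1) obs[1] else "A"
    alt[j] <- if (length(obs) == 2) obs[2] else
      setdiff(c("A", "C", "G", "T"), ref[j])[1]
    ok <- a1[, j] != "0" & a2[, j] != "0"
    calls[ok, j] <- (a1[ok, j] == alt[j]) + (a2[ok, j] == alt[j])
  }
  genotype_matrix(
    calls,
    markers = tibble(id = mp$id, chrom = mp$chrom,
                     pos = as.integer(mp$bp), ref = ref, alt = alt),
    samples = tibble(id = pd[[2]],
                     sex = ifelse(sex_code == "1", "male", "female")))
}

#' Write / read feature tracks as TSV
#'
#' Header columns: `sample`, `sex`, `window_start`, `window_end`, `depth`,
#' `het_density`, `discordant_frac`, `lowmapq_frac`.
#'
#' @param tracks Feature track tibble.
#' @param path File path.
#' @return `write_tracks()` the path invisibly; `read_tracks()` a tibble.
#' @export
write_tracks <- function(tracks, path) {
  write.table(tracks, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  as_tibble(read.table(path, header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE))
}

#' Read / write FASTA
#'
#' Thin wrappers around seqinr returning/accepting plain named character
#' vectors of uppercase sequences; output wraps at 60 columns.
#'
#' @param path FASTA file path.
#' @param seqs Named character vector of sequences.
#' @return `read_fasta()` a named character vector.
#' @export
read_fasta <- function(path) {
  x <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  setNames(toupper(vapply(x, `[[`, character(1), 1)), names(x))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  seqinr::write.fasta(lapply(unname(seqs), function(s) seqinr::s2c(s)),
                      names = names(seqs), file.out = path, nbchar = 60)
  invisible(path)
}

#' Read a BED file of intervals into 1-based inclusive coordinates
#'
#' BED is 0-based half-open; on ingest `start` is incremented so the
#' returned intervals are 1-based inclusive, the convention used
#' throughout the package.
#'
#' @param path BED file path (3+ columns; column 4, when present, becomes
#'   `name`).
#' @return Tibble `chrom`, `start`, `end`, `name`.
#' @export
read_bed <- function(path) {
  x <- read.table(path, header = FALSE, sep = "\t",
                  stringsAsFactors = FALSE)
  if (ncol(x) < 3) stop("BED needs at least 3 columns")
  tibble(chrom = as.character(x[[1]]), start = as.integer(x[[2]]) + 1L,
         end = as.integer(x[[3]]),
         name = if (ncol(x) >= 4) as.character(x[[4]]) else NA_character_)
}
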