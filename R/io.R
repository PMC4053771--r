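#' Read and write genotype matrices as TSV
#'
#' The on-disk layout is rows = lines, columns = markers, values `A`/`B`/
#' `NA`, first column `line`. `read_genotypes()` also accepts the
#' `0/1/2/-` dialect (0 = A, 2 = B, 1 = heterozygous, `-` = missing);
#' heterozygous calls become `"H"` and are set missing by
#' [filter_markers()].
#'
#' @param geno Character matrix (lines x markers).
#' @param path File path.
#' @return `read_genotypes()` returns a character matrix with line ids as
#'   row names.
#' @export
write_genotypes <- function(geno, path) {
  df <- tibble::as_tibble(geno, rownames = "line")
  readr::write_tsv(df, path, na = "NA")
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        na = c("NA", ""))
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  numeric_dialect <- all(m %in% c("0", "1", "2", "-", NA))
  if (numeric_dialect && any(m %in% c("0", "1", "2", "-"))) {
    m[m == "-"] <- NA_character_
    m[m == "0"] <- "A"
    m[m == "2"] <- "B"
    m[m == "1"] <- "H"
  }
  m
}

#' Read or write a marker table
#'
#' Columns: `marker`, `chrom`, `bp` (1-based), optionally `cm`.
#'
#' @param markers Marker tibble.
#' @param path File path.
#' @export
write_marker_table <- function(markers, path) {
  readr::write_tsv(markers, path)
  invisible(path)
}

#' @rdname write_marker_table
#' @export
read_marker_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    marker = "c", chrom = "c", bp = "i", .default = "d"
  ))
}

#' Write a Marey map (grid, genetic position, provenance) as TSV
#'
#' @param map A `marey_map`.
#' @param path File path.
#' @export
write_marey <- function(map, path) {
  df <- tibble::as_tibble(map)
  df$chrom <- attr(map, "chrom")
  readr::write_tsv(df[, c("chrom", "pos_mbp", "gen_cm", "provenance")], path)
  invisible(path)
}

#' Read or write mask intervals in a BED-like layout
#'
#' Columns `chrom`, `start`, `end` are 0-based half-open bp coordinates;
#' Mbp-scaled columns are carried alongside for convenience.
#'
#' @param masks Tibble with `chrom`, `start_mbp`, `end_mbp`.
#' @param path File path.
#' @export
write_masks <- function(masks, path) {
  out <- tibble::tibble(
    chrom = masks$chrom,
    start = as.integer(round(masks$start_mbp * 1e6)),
    end = as.integer(round(masks$end_mbp * 1e6)),
    start_mbp = masks$start_mbp, end_mbp = masks$end_mbp
  )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_masks
#' @export
read_masks <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(chrom = "c", .default = "d"))
  if (!all(c("start_mbp", "end_mbp") %in% names(df))) {
    df$start_mbp <- df$start / 1e6
    df$end_mbp <- df$end / 1e6
  }
  tibble::as_tibble(df[, c("chrom", "start_mbp", "end_mbp")])
}

#' Published map-length summary of the 23 maize DH populations
#'
#' Summary statistics of the genetic maps of 23 doubled-haploid maize
#' populations from a European Dent/Flint half-sib crossing design (one
#' population per cross of a central line with a founder line): population
#' id, parents, cross type, number of DH lines, total genetic map length
#' (cM) and genome-wide recombination rate (cM/Mbp). Used for the pooled
#' map-length arithmetic.
#'
#' @return Tibble with columns `population`, `parent1`, `parent2`,
#'   `cross_type`, `n_lines`, `length_cm`, `gwrr`.
#' @export
maize_map_summary <- function() {
  path <- system.file("extdata", "maize_dh_map_summary.tsv",
                      package = "dhrecomb", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    population = "c", parent1 = "c", parent2 = "c", cross_type = "c",
    n_lines = "i", length_cm = "d", gwrr = "d"
  ))
}
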