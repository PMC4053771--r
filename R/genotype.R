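#' Haldane mapping function
#'
#' Converts a recombination fraction to an additive genetic distance assuming
#' no interference: `d = -50 log(1 - 2 r)` cM.
#'
#' @param r Recombination fraction(s) in \[0, 0.5).
#' @return Distance(s) in cM.
#' @export
haldane_cm <- function(r) {
  if (any(r < 0 | r >= 0.5, na.rm = TRUE)) {
    stop("recombination fraction must lie in [0, 0.5)")
  }
  -50 * log(1 - 2 * r)
}

#' @rdname haldane_cm
#' @param d Genetic distance(s) in cM.
#' @return `haldane_r()` returns the recombination fraction
#'   `(1 - exp(-d/50)) / 2`.
#' @export
haldane_r <- function(d) {
  if (any(d < 0, na.rm = TRUE)) stop("distance must be nonnegative")
  (1 - exp(-d / 50)) / 2
}

#' Filter a DH genotype matrix for mapping
#'
#' Heterozygous calls (symbol `"H"`, present when the input dialect encodes
#' them) are set to missing; markers with minor allele frequency at or below
#' `min_maf` over informative calls are removed, which also drops
#' monomorphic and all-missing markers.
#'
#' @param geno Character matrix (lines x markers), values `"A"`, `"B"`,
#'   optionally `"H"`, `NA`.
#' @param min_maf Minor-allele-frequency threshold; markers are kept only if
#'   MAF is strictly greater (default 0.1).
#' @return Filtered genotype matrix (possibly with zero columns, with a
#'   warning).
#' @export
filter_markers <- function(geno, min_maf = 0.1) {
  geno[geno == "H"] <- NA_character_
  if (ncol(geno) == 0) return(geno)
  na_count <- colSums(is.na(geno))
  a_count <- colSums(geno == "A", na.rm = TRUE)
  informative <- nrow(geno) - na_count
  fa <- ifelse(informative > 0, a_count / informative, NA_real_)
  maf <- pmin(fa, 1 - fa)
  keep <- !is.na(maf) & maf > min_maf
  if (!any(keep)) warning("all markers removed by filtering")
  geno[, keep, drop = FALSE]
}

# Set isolated single-marker alleles to NA: maximal chains of length-1 runs
# flanked on both sides by >= 2 consistent calls within `window_cm` are far
# more likely genotyping errors than genuine tight double crossovers on a
# dense map (interference makes close same-pathway pairs vanishingly rare).
# A chain next to a genuine crossover boundary collapses to the single true
# switch once its calls are removed.
clean_double_recombinants <- function(calls, cm, window_cm = 10) {
  inf_idx <- which(!is.na(calls))
  if (length(inf_idx) < 5) return(calls)
  v <- calls[inf_idx]
  r <- rle(v)
  nr <- length(r$lengths)
  if (nr < 3) return(calls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  j <- 2
  while (j <= nr - 1) {
    if (r$lengths[j] == 1) {
      k <- j
      while (k <= nr - 1 && r$lengths[k] == 1) k <- k + 1
      # chain spans runs j..(k-1); flanking runs are j-1 and k
      if (r$lengths[j - 1] >= 2 && r$lengths[k] >= 2) {
        left <- inf_idx[ends[j - 1]]
        right <- inf_idx[starts[k]]
        if (cm[right] - cm[left] <= window_cm) {
          calls[inf_idx[starts[j]:ends[k - 1]]] <- NA_character_
        }
      }
      j <- k + 1
    } else {
      j <- j + 1
    }
  }
  calls
}

#' Remove isolated single-marker calls from a genotype matrix
#'
#' Applies the double-recombinant cleaning rule of [extract_crossovers()] to
#' the matrix itself: isolated single-marker alleles flanked on both sides
#' by at least two consistent opposite calls within `window_cm` are set
#' missing. Cleaning the matrix (rather than only the extraction scan)
#' matters for map construction: every isolated genotyping error otherwise
#' inflates two adjacent recombination fractions and, through Haldane
#' accumulation, the total map length. The usual workflow is two-pass:
#' build a provisional map, clean against it, rebuild.
#'
#' @param geno Filtered genotype matrix.
#' @param map Genetic map tibble (`marker`, `chrom`, `bp`, `cm`).
#' @param window_cm Cleaning window (cM).
#' @return The cleaned genotype matrix.
#' @export
clean_genotype_errors <- function(geno, map, window_cm = 10) {
  map <- map[match(colnames(geno), map$marker), ]
  for (ch in unique(map$chrom)) {
    sel <- which(map$chrom == ch)
    sel <- sel[order(map$bp[sel])]
    cm <- map$cm[sel]
    for (i in seq_len(nrow(geno))) {
      geno[i, sel] <- clean_double_recombinants(geno[i, sel], cm, window_cm)
    }
  }
  geno
}

#' Extract crossover events from a DH genotype matrix
#'
#' For each line and chromosome, the physically ordered sequence of
#' informative (non-missing) calls is scanned; every adjacent pair of
#' informative markers carrying different alleles yields one crossover event
#' spanning the intervening missing markers. The genetic position assigned to
#' the event is the midpoint of the two flanking markers' map positions.
#'
#' @param geno Filtered genotype matrix (lines x markers).
#' @param map Genetic map tibble with columns `marker`, `chrom`, `bp`, `cm`
#'   covering all matrix columns (e.g. from [build_genetic_map()]).
#' @param clean If `TRUE` (default), isolated single-marker alleles flanked
#'   by >= 2 consistent opposite calls within `clean_window_cm` are treated
#'   as genotyping errors and set to missing before extraction.
#' @param clean_window_cm Window for the error cleaning rule (cM).
#' @return Tibble of crossover events: `line`, `chrom`, `left_marker`,
#'   `right_marker`, `left_bp`, `right_bp` (half-open physical interval),
#'   `mid_cm` (genetic midpoint).
#' @export
extract_crossovers <- function(geno, map, clean = TRUE, clean_window_cm = 10) {
  stopifnot(all(colnames(geno) %in% map$marker))
  map <- map[match(colnames(geno), map$marker), ]
  out <- list()
  for (ch in unique(map$chrom)) {
    sel <- which(map$chrom == ch)
    sel <- sel[order(map$bp[sel])]
    cm <- map$cm[sel]
    bp <- map$bp[sel]
    ids <- map$marker[sel]
    sub <- geno[, sel, drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      calls <- sub[i, ]
      if (clean) calls <- clean_double_recombinants(calls, cm, clean_window_cm)
      inf <- which(!is.na(calls))
      if (length(inf) < 2) next
      v <- calls[inf]
      sw <- which(v[-1] != v[-length(v)])
      if (length(sw) == 0) next
      li <- inf[sw]
      ri <- inf[sw + 1]
      out[[length(out) + 1]] <- tibble::tibble(
        line = rownames(geno)[i], chrom = ch,
        left_marker = ids[li], right_marker = ids[ri],
        left_bp = bp[li], right_bp = bp[ri],
        mid_cm = (cm[li] + cm[ri]) / 2
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(
      line = character(0), chrom = character(0),
      left_marker = character(0), right_marker = character(0),
      left_bp = integer(0), right_bp = integer(0), mid_cm = numeric(0)
    ))
  }
  dplyr::bind_rows(out)
}

#' Build a Haldane genetic map on fixed physical marker order
#'
#' Marker order is taken from physical positions; for each adjacent marker
#' pair the recombination fraction is the proportion of lines carrying
#' different alleles among lines informative at both markers
#' (pairwise-complete denominators), converted to cM with [haldane_cm()] and
#' accumulated.
#'
#' @param geno Filtered genotype matrix.
#' @param markers Marker table with columns `marker`, `chrom`, `bp`.
#' @param r_cap Recombination fractions at or above 0.5 (possible under
#'   sampling noise) are capped at this value with a warning.
#' @return Tibble with columns `marker`, `chrom`, `bp`, `cm`; per-chromosome
#'   lengths available via [map_lengths()].
#' @export
build_genetic_map <- function(geno, markers, r_cap = 0.499) {
  markers <- dplyr::filter(markers, .data$marker %in% colnames(geno))
  markers <- dplyr::arrange(markers, .data$chrom, .data$bp)
  capped <- 0L
  out <- lapply(split(markers, markers$chrom), function(mk) {
    m <- nrow(mk)
    if (m < 2) stop("need >= 2 markers per chromosome")
    sub <- geno[, mk$marker, drop = FALSE]
    r <- numeric(m - 1)
    for (j in seq_len(m - 1)) {
      a <- sub[, j]
      b <- sub[, j + 1]
      ok <- !is.na(a) & !is.na(b)
      n_ok <- sum(ok)
      r[j] <- if (n_ok == 0) 0 else sum(a[ok] != b[ok]) / n_ok
    }
    over <- r >= 0.5
    if (any(over)) {
      capped <<- capped + sum(over)
      r[over] <- r_cap
    }
    tibble::tibble(
      marker = mk$marker, chrom = mk$chrom[1], bp = mk$bp,
      cm = c(0, cumsum(haldane_cm(r)))
    )
  })
  if (capped > 0) {
    warning(sprintf("%d adjacent pairs had r >= 0.5; capped at %.3f", capped, r_cap))
  }
  dplyr::bind_rows(out)
}

#' Per-chromosome and total genetic map lengths
#'
#' @param map A genetic-map tibble from [build_genetic_map()].
#' @return Tibble `chrom`, `n_markers`, `length_cm`, plus a `"genome"` row
#'   with the total.
#' @export
map_lengths <- function(map) {
  per <- map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(n_markers = dplyr::n(),
                     length_cm = max(.data$cm) - min(.data$cm),
                     .groups = "drop")
  dplyr::bind_rows(
    per,
    tibble::tibble(chrom = "genome", n_markers = sum(per$n_markers),
                   length_cm = sum(per$length_cm))
  )
}

#' Tally crossover events per line and chromosome
#'
#' @param events Crossover tibble from [extract_crossovers()].
#' @param line_ids All line identifiers (so lines without events appear with
#'   zero counts).
#' @param chroms Optional chromosome labels to complete over.
#' @return Tibble `line`, `chrom`, `n_co`, completed with zeros.
#' @export
crossover_counts <- function(events, line_ids, chroms = NULL) {
  if (is.null(chroms)) chroms <- unique(events$chrom)
  grid <- tidyr::expand_grid(line = line_ids, chrom = chroms)
  tallies <- events |>
    dplyr::count(.data$line, .data$chrom, name = "n_co")
  grid |>
    dplyr::left_join(tallies, by = c("line", "chrom")) |>
    dplyr::mutate(n_co = tidyr::replace_na(.data$n_co, 0L))
}

#' Genome-wide crossover-count summary
#'
#' @param counts Output of [crossover_counts()].
#' @return One-row tibble: `total_co`, `n_lines`, `mean_per_line`.
#' @export
co_count_summary <- function(counts) {
  per_line <- counts |>
    dplyr::group_by(.data$line) |>
    dplyr::summarise(n_co = sum(.data$n_co), .groups = "drop")
  tibble::tibble(
    total_co = sum(per_line$n_co),
    n_lines = nrow(per_line),
    mean_per_line = mean(per_line$n_co)
  )
}

#' Segregation-distortion profile
#'
#' Per-marker frequency of the A (central-parent) allele over informative
#' calls, with the null confidence band `0.5 +/- z * sqrt(0.25 / n)` under
#' Mendelian segregation; markers outside the band are flagged as distorted.
#'
#' @param geno Filtered genotype matrix.
#' @param markers Marker table (`marker`, `chrom`, `bp`).
#' @param alpha Two-sided significance level of the band (default 0.01, a
#'   99 percent band).
#' @return Tibble `marker`, `chrom`, `bp`, `n_informative`, `freq_a`,
#'   `lower`, `upper`, `distorted`.
#' @export
distortion_profile <- function(geno, markers, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  markers <- markers[match(colnames(geno), markers$marker), ]
  n_inf <- unname(nrow(geno) - colSums(is.na(geno)))
  fa <- ifelse(n_inf > 0,
               unname(colSums(geno == "A", na.rm = TRUE)) / n_inf, NA_real_)
  z <- stats::qnorm(1 - alpha / 2)
  half <- z * sqrt(0.25 / pmax(n_inf, 1))
  tibble::tibble(
    marker = markers$marker, chrom = markers$chrom, bp = markers$bp,
    n_informative = as.integer(n_inf), freq_a = fa,
    lower = 0.5 - half, upper = 0.5 + half,
    distorted = !is.na(fa) & (fa < 0.5 - half | fa > 0.5 + half)
  )
}
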