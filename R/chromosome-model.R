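#' Define a chromosome for meiosis simulation
#'
#' A chromosome model couples a physical axis (Mbp) to a genetic axis (Morgan)
#' through a monotone Marey curve given as ordered control points. The curve
#' must start at (0, 0) and end at (`physical_length`, `genetic_length`).
#'
#' @param name Chromosome label.
#' @param physical_length Physical length in Mbp.
#' @param genetic_length Genetic length in Morgan (expected crossovers per
#'   gamete on the chromosome).
#' @param curve A data frame with columns `pos_mbp` and `gen_morgan` giving
#'   the Marey-curve control points, strictly increasing in `pos_mbp` and
#'   nondecreasing in `gen_morgan`. If `NULL`, a linear curve is used.
#' @return An object of class `chromosome_model`.
#' @export
chromosome_model <- function(name, physical_length, genetic_length, curve = NULL) {
  stopifnot(physical_length > 0, genetic_length > 0)
  if (is.null(curve)) {
    curve <- tibble::tibble(
      pos_mbp = c(0, physical_length),
      gen_morgan = c(0, genetic_length)
    )
  }
  curve <- tibble::as_tibble(curve)
  stopifnot(all(c("pos_mbp", "gen_morgan") %in% names(curve)))
  if (any(diff(curve$pos_mbp) <= 0)) {
    stop("Marey curve control points must be strictly increasing in pos_mbp")
  }
  if (any(diff(curve$gen_morgan) < 0)) {
    stop("Marey curve must be nondecreasing in gen_morgan")
  }
  if (abs(curve$pos_mbp[1]) > 1e-9 || abs(curve$gen_morgan[1]) > 1e-9) {
    stop("Marey curve must start at (0, 0)")
  }
  n <- nrow(curve)
  if (abs(curve$pos_mbp[n] - physical_length) > 1e-6 ||
      abs(curve$gen_morgan[n] - genetic_length) > 1e-6) {
    stop("Marey curve must end at (physical_length, genetic_length)")
  }
  structure(
    list(
      name = as.character(name),
      physical_length = physical_length,
      genetic_length = genetic_length,
      curve = curve
    ),
    class = "chromosome_model"
  )
}

#' @export
print.chromosome_model <- function(x, ...) {
  cat(sprintf(
    "<chromosome_model> %s: %.1f Mbp, %.3f Morgan (%d control points)\n",
    x$name, x$physical_length, x$genetic_length, nrow(x$curve)
  ))
  invisible(x)
}

# Piecewise-linear evaluation of the Marey curve (Mbp -> Morgan).
marey_fun <- function(chrom) {
  stats::approxfun(chrom$curve$pos_mbp, chrom$curve$gen_morgan, rule = 2)
}

# Inverse curve (Morgan -> Mbp). The default genomes keep a small positive
# baseline rate everywhere, so the curve is strictly increasing and invertible.
marey_inv_fun <- function(chrom) {
  g <- chrom$curve$gen_morgan
  if (any(diff(g) <= 0)) {
    # break exact plateaus by a negligible tilt so approxfun is well defined
    g <- g + seq_along(g) * 1e-12
  }
  stats::approxfun(g, chrom$curve$pos_mbp, rule = 2)
}

#' Synthetic maize-like genome for simulation
#'
#' Ten chromosomes with physical lengths between 150 and 301 Mbp and a total
#' genetic length of about 15 Morgan (genome-wide rate near 0.73 cM/Mbp).
#' Each Marey curve is sigmoid with a flat centromeric plateau: the local rate
#' rises quadratically from (almost) zero at the centromere towards the
#' telomeres, mirroring the suppression of crossovers in pericentromeric
#' heterochromatin seen in large plant genomes.
#'
#' @param rate_cm_per_mbp Genome-wide recombination rate used to scale the
#'   per-chromosome genetic lengths (cM/Mbp).
#' @param n_points Number of Marey-curve control points per chromosome.
#' @param centromere_fraction Relative position of the centromere (0.5 =
#'   metacentric); recycled across chromosomes.
#' @param plateau_fraction Half-width of the flat pericentromeric plateau as
#'   a fraction of chromosome length.
#' @param baseline_rate Small positive floor on the local rate so the curve
#'   stays strictly increasing (fraction of the mean rate).
#' @return A named list of [chromosome_model] objects.
#' @export
default_genome <- function(rate_cm_per_mbp = 0.73, n_points = 201,
                           centromere_fraction = c(0.48, 0.4, 0.45, 0.5, 0.45,
                                                   0.35, 0.4, 0.45, 0.4, 0.45),
                           plateau_fraction = 0.08,
                           baseline_rate = 0.02) {
  phys <- c(301, 237, 232, 242, 218, 169, 177, 175, 157, 150)
  centro <- rep_len(centromere_fraction, 10)
  genome <- purrr::map(seq_len(10), function(i) {
    P <- phys[i]
    L <- rate_cm_per_mbp * P / 100 # Morgan
    x <- seq(0, P, length.out = n_points)
    cpos <- centro[i] * P
    w <- plateau_fraction * P
    arm <- pmax(cpos, P - cpos)
    # flat suppressed plateau around the centromere, quadratic rise to the
    # telomeres
    u <- baseline_rate + (pmax(0, abs(x - cpos) - w) / (arm - w))^2
    gcum <- c(0, cumsum((u[-1] + u[-n_points]) / 2 * diff(x)))
    gcum <- gcum / gcum[n_points] * L
    chromosome_model(
      name = paste0("chr", i), physical_length = P, genetic_length = L,
      curve = tibble::tibble(pos_mbp = x, gen_morgan = gcum)
    )
  })
  names(genome) <- paste0("chr", seq_len(10))
  genome
}
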