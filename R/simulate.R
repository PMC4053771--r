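#' Meiosis parameters for the two-pathway interference model
#'
#' Crossovers form through two pathways: P1, an interfering pathway modelled
#' as a stationary renewal process with gamma-distributed inter-arrivals of
#' shape `nu` on the bivalent (four-chromatid) scale, and P2, a
#' non-interfering pathway contributing a proportion `p` of crossovers as an
#' independent Poisson process. The bivalent P1 process has inter-arrival
#' distribution Gamma(shape = `nu`, rate = `2 nu (1 - p)`), so after
#' independent thinning with retention 1/2 (no chromatid interference) the
#' gamete carries `1 - p` P1 crossovers per Morgan, and P2 adds `p` per
#' Morgan: the total intensity is exactly 1 per Morgan.
#'
#' @param nu Interference intensity of pathway P1 (gamma shape), >= 1.
#'   `nu = 1` is the no-interference (Poisson) limit.
#' @param p Proportion of crossovers from the non-interfering pathway P2,
#'   in \[0, 0.5\].
#' @return An object of class `meiosis_params`.
#' @export
meiosis_params <- function(nu = 5, p = 0.1) {
  if (!is.numeric(nu) || length(nu) != 1 || is.na(nu) || nu < 1) {
    stop("nu must be a single number >= 1")
  }
  if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 0.5) {
    stop("p must be a single number in [0, 0.5]")
  }
  structure(list(nu = nu, p = p), class = "meiosis_params")
}

# Equilibrium (forward-recurrence) CDF of a Gamma(nu, rate = beta) renewal
# process: F_e(x) = (beta/nu) * x * (1 - F_nu(x)) + F_{nu+1}(x).
gamma_equilibrium_cdf <- function(x, nu, beta) {
  (beta / nu) * x * (1 - stats::pgamma(x, nu, rate = beta)) +
    stats::pgamma(x, nu + 1, rate = beta)
}

# Draw the stationary first bivalent event on [0, L]; returns Inf where the
# first event falls beyond L. Vectorised bisection inversion of F_e.
r_first_event <- function(n, nu, beta, L) {
  u <- stats::runif(n)
  out <- rep(Inf, n)
  inside <- u <= gamma_equilibrium_cdf(L, nu, beta)
  if (any(inside)) {
    lo <- rep(0, sum(inside))
    hi <- rep(L, sum(inside))
    ui <- u[inside]
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      below <- gamma_equilibrium_cdf(mid, nu, beta) < ui
      lo[below] <- mid[below]
      hi[!below] <- mid[!below]
    }
    out[inside] <- (lo + hi) / 2
  }
  out
}

#' Simulate many gametes on one chromosome
#'
#' Vectorised workhorse behind [simulate_gamete_crossovers()]: realises `n`
#' independent gametes of genetic length `L` under the two-pathway model,
#' using the current RNG state.
#'
#' @param n Number of gametes.
#' @param L Chromosome genetic length (Morgan).
#' @param params A [meiosis_params].
#' @return List of `n` sorted crossover position vectors (Morgan).
#' @export
simulate_gametes <- function(n, L, params) {
  nu <- params$nu
  p <- params$p
  lambda1 <- 1 - p
  beta <- 2 * nu * lambda1

  # bivalent P1 events: stationary start, then gamma renewals until > L
  cur <- r_first_event(n, nu, beta, L)
  pos <- list()
  active <- which(is.finite(cur) & cur <= L)
  vals <- cur
  while (length(active) > 0) {
    pos[[length(pos) + 1]] <- cbind(active, vals[active])
    vals[active] <- vals[active] + stats::rgamma(length(active), nu, rate = beta)
    active <- active[vals[active] <= L]
  }
  if (length(pos) > 0) {
    ev <- do.call(rbind, pos)
    keep <- stats::runif(nrow(ev)) < 0.5 # thinning to the gamete, no chromatid interference
    ev <- ev[keep, , drop = FALSE]
    p1 <- split(ev[, 2], factor(ev[, 1], levels = seq_len(n)))
  } else {
    p1 <- rep(list(numeric(0)), n)
  }

  # non-interfering P2: homogeneous Poisson of intensity p per Morgan
  if (p > 0) {
    k2 <- stats::rpois(n, p * L)
    u2 <- stats::runif(sum(k2), 0, L)
    p2 <- split(u2, factor(rep(seq_len(n), k2), levels = seq_len(n)))
  } else {
    p2 <- rep(list(numeric(0)), n)
  }
  purrr::map2(p1, p2, ~ sort(c(.x, .y)))
}

#' Simulate crossover positions of one gamete
#'
#' Realises the two-pathway model on a chromosome: P1 crossovers come from a
#' stationary gamma renewal process on the bivalent (first event drawn from
#' the forward-recurrence distribution, so no burn-in is needed), thinned
#' with probability 1/2 to the gamete; P2 crossovers are an independent
#' Poisson process of intensity `p` per Morgan. The expected total count
#' equals the chromosome genetic length in Morgan.
#'
#' @param chrom A [chromosome_model].
#' @param params A [meiosis_params].
#' @param seed Optional integer seed for reproducibility.
#' @return Sorted numeric vector of crossover genetic positions (Morgan).
#' @export
simulate_gamete_crossovers <- function(chrom, params, seed = NULL) {
  stopifnot(inherits(chrom, "chromosome_model"), inherits(params, "meiosis_params"))
  if (!is.null(seed)) set.seed(seed)
  simulate_gametes(1, chrom$genetic_length, params)[[1]]
}

#' Convert crossover positions to a gamete genotype vector
#'
#' Marker physical positions are mapped to genetic positions through the
#' chromosome's Marey curve; the allele then alternates between the two
#' parental alleles at each crossover. Two crossovers falling inside the same
#' marker interval cancel and leave no observable switch.
#'
#' @param co_positions Crossover genetic positions (Morgan).
#' @param chrom A [chromosome_model].
#' @param marker_bp Marker physical positions in bp (1-based), sorted.
#' @param start_allele `"A"` or `"B"`: the allele carried at the chromosome
#'   start.
#' @return Character vector of alleles over the markers.
#' @export
crossovers_to_gamete <- function(co_positions, chrom, marker_bp, start_allele = "A") {
  stopifnot(start_allele %in% c("A", "B"))
  if (length(marker_bp) == 0) return(character(0))
  if (is.unsorted(marker_bp)) stop("marker positions must be sorted")
  mbp <- marker_bp / 1e6
  if (any(mbp < 0) || any(mbp > chrom$physical_length)) {
    stop("marker outside chromosome physical range")
  }
  gen <- marey_fun(chrom)(mbp)
  nflip <- findInterval(gen, sort(co_positions))
  other <- if (start_allele == "A") "B" else "A"
  ifelse(nflip %% 2 == 0, start_allele, other)
}

#' Design of a simulated DH population
#'
#' Describes the observable layer of a simulated doubled-haploid population:
#' marker panel, missing-call and genotyping-error rates, parental IBD
#' segments (forced monomorphic, hence uninformative), and segregation
#' distortion loci.
#'
#' @param n_lines Number of DH lines.
#' @param marker_positions Named list (one element per chromosome) of sorted
#'   marker physical positions in bp.
#' @param missing_rate Probability that a call is missing, in \[0, 1\].
#' @param error_rate Probability that a call is flipped, in \[0, 1\].
#' @param ibd_intervals Optional named list (per chromosome) of data frames
#'   with `start_mbp`/`end_mbp` columns: markers inside are set monomorphic.
#' @param distortion_loci Optional data frame with columns `chrom`,
#'   `pos_mbp`, `prob_a`: at each locus the A allele is transmitted with the
#'   stated probability (in (0, 1)), decaying to 0.5 with recombination
#'   distance.
#' @param seed Integer seed; the whole population is reproducible from it.
#' @return An object of class `population_design`.
#' @export
population_design <- function(n_lines, marker_positions,
                              missing_rate = 0.02, error_rate = 0.002,
                              ibd_intervals = NULL, distortion_loci = NULL,
                              seed = 1L) {
  if (!is.numeric(n_lines) || n_lines < 1) stop("n_lines must be a positive count")
  stopifnot(is.list(marker_positions), !is.null(names(marker_positions)))
  for (bp in marker_positions) {
    if (length(bp) > 1 && any(diff(bp) <= 0)) {
      stop("marker positions must be strictly increasing within a chromosome")
    }
  }
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate must be in [0, 1]")
  if (error_rate < 0 || error_rate > 1) stop("error_rate must be in [0, 1]")
  if (!is.null(distortion_loci)) {
    distortion_loci <- tibble::as_tibble(distortion_loci)
    stopifnot(all(c("chrom", "pos_mbp", "prob_a") %in% names(distortion_loci)))
    if (any(distortion_loci$prob_a <= 0 | distortion_loci$prob_a >= 1)) {
      stop("transmission probabilities must be in (0, 1)")
    }
  }
  structure(
    list(
      n_lines = as.integer(n_lines), marker_positions = marker_positions,
      missing_rate = missing_rate, error_rate = error_rate,
      ibd_intervals = ibd_intervals, distortion_loci = distortion_loci,
      seed = as.integer(seed)
    ),
    class = "population_design"
  )
}

#' Uniform marker panel over a genome
#'
#' @param genome Named list of [chromosome_model] objects.
#' @param per_mbp Marker density (markers per Mbp).
#' @return Named list of marker positions (bp) suitable for
#'   [population_design()].
#' @export
uniform_markers <- function(genome, per_mbp = 1) {
  purrr::map(genome, function(ch) {
    n <- max(2L, floor(ch$physical_length * per_mbp))
    round(seq(0.5 / per_mbp, ch$physical_length - 0.5 / per_mbp,
              length.out = n) * 1e6)
  })
}

#' Apply observation noise to a genotype matrix
#'
#' Independently flips calls with probability `error_rate`, sets calls
#' missing with probability `missing_rate`, and forces markers inside IBD
#' intervals to be monomorphic (all `"A"`, the central-parent allele), in
#' that order so IBD segments stay monomorphic.
#'
#' @param geno Character matrix (lines x markers) with values `"A"`, `"B"`,
#'   `NA`.
#' @param markers Marker table with columns `marker`, `chrom`, `bp` matching
#'   the matrix columns.
#' @param design A [population_design] supplying the rates and intervals.
#' @param seed Optional integer seed.
#' @return The noised genotype matrix.
#' @export
apply_observation_noise <- function(geno, markers, design, seed = NULL) {
  stopifnot(ncol(geno) == nrow(markers))
  if (!is.null(seed)) set.seed(seed)
  n <- length(geno)
  if (design$error_rate > 0 && n > 0) {
    flip <- matrix(stats::runif(n) < design$error_rate, nrow = nrow(geno))
    flip <- flip & !is.na(geno)
    geno[flip] <- ifelse(geno[flip] == "A", "B", "A")
  }
  if (design$missing_rate > 0 && n > 0) {
    miss <- matrix(stats::runif(n) < design$missing_rate, nrow = nrow(geno))
    geno[miss] <- NA_character_
  }
  if (!is.null(design$ibd_intervals)) {
    for (ch in names(design$ibd_intervals)) {
      iv <- design$ibd_intervals[[ch]]
      for (j in seq_len(nrow(iv))) {
        sel <- markers$chrom == ch &
          markers$bp / 1e6 >= iv$start_mbp[j] & markers$bp / 1e6 <= iv$end_mbp[j]
        if (any(sel)) {
          block <- geno[, sel, drop = FALSE]
          block[!is.na(block)] <- "A"
          geno[, sel] <- block
        }
      }
    }
  }
  geno
}

#' Simulate a doubled-haploid population with known crossover truth
#'
#' One female meiosis per line: crossovers are drawn per chromosome under the
#' two-pathway model, the start allele is uniform per line and chromosome,
#' and segregation distortion is produced by per-line acceptance sampling
#' keyed to the gamete allele at each distortion locus (accepted with
#' probability `prob_a` when carrying A, `1 - prob_a` otherwise), which
#' yields the stated local transmission probability with the natural
#' recombination-distance decay. Observation noise is then applied via
#' [apply_observation_noise()].
#'
#' @param genome Named list of [chromosome_model] objects.
#' @param params A single [meiosis_params] or a named list with one per
#'   chromosome.
#' @param design A [population_design].
#' @return A list of class `dh_population` with elements `genotypes`
#'   (character matrix lines x markers), `markers` (tibble: marker, chrom,
#'   bp, gen_morgan, gen_cm), `truth` (tibble: line, chrom, pos_morgan of
#'   every true crossover), and the `genome`, `params`, `design` used.
#' @export
simulate_population <- function(genome, params, design) {
  stopifnot(inherits(design, "population_design"))
  if (design$n_lines <= 0) stop("n_lines must be positive")
  if (inherits(params, "meiosis_params")) {
    params <- stats::setNames(rep(list(params), length(genome)), names(genome))
  }
  set.seed(design$seed)
  n <- design$n_lines
  line_ids <- sprintf("L%04d", seq_len(n))

  markers <- purrr::imap_dfr(design$marker_positions, function(bp, ch) {
    if (length(bp) == 0) return(tibble::tibble())
    gen <- marey_fun(genome[[ch]])(bp / 1e6)
    tibble::tibble(
      marker = sprintf("%s_m%04d", ch, seq_along(bp)),
      chrom = ch, bp = as.integer(bp), gen_morgan = gen, gen_cm = 100 * gen
    )
  })
  if (nrow(markers) == 0) {
    geno <- matrix(character(0), nrow = n, ncol = 0,
                   dimnames = list(line_ids, NULL))
    return(structure(list(genotypes = geno, markers = markers,
                          truth = tibble::tibble(line = character(0),
                                                 chrom = character(0),
                                                 pos_morgan = numeric(0)),
                          genome = genome, params = params, design = design),
                     class = "dh_population"))
  }

  geno <- matrix(NA_character_, nrow = n, ncol = nrow(markers),
                 dimnames = list(line_ids, markers$marker))
  truth <- list()
  dist_loci <- design$distortion_loci

  for (ch in names(design$marker_positions)) {
    chrom <- genome[[ch]]
    loci <- if (!is.null(dist_loci)) dist_loci[dist_loci$chrom == ch, ] else NULL
    gl <- if (!is.null(loci) && nrow(loci) > 0) {
      marey_fun(chrom)(loci$pos_mbp)
    } else NULL

    cos <- vector("list", n)
    starts <- character(n)
    todo <- seq_len(n)
    while (length(todo) > 0) {
      cand <- simulate_gametes(length(todo), chrom$genetic_length, params[[ch]])
      cand_start <- sample(c("A", "B"), length(todo), replace = TRUE)
      if (is.null(gl)) {
        acc <- rep(TRUE, length(todo))
      } else {
        # acceptance probability = product over loci of P(keep | allele there)
        pr <- rep(1, length(todo))
        for (j in seq_along(gl)) {
          nf <- vapply(cand, function(x) sum(x < gl[j]), integer(1))
          is_a <- (nf %% 2 == 0) == (cand_start == "A")
          pr <- pr * ifelse(is_a, loci$prob_a[j], 1 - loci$prob_a[j])
        }
        acc <- stats::runif(length(todo)) < pr
      }
      cos[todo[acc]] <- cand[acc]
      starts[todo[acc]] <- cand_start[acc]
      todo <- todo[!acc]
    }

    sel <- markers$chrom == ch
    bp <- markers$bp[sel]
    for (i in seq_len(n)) {
      geno[i, sel] <- crossovers_to_gamete(cos[[i]], chrom, bp, starts[i])
    }
    k <- lengths(cos)
    if (sum(k) > 0) {
      truth[[ch]] <- tibble::tibble(
        line = rep(line_ids, k), chrom = ch, pos_morgan = unlist(cos)
      )
    }
  }

  geno <- apply_observation_noise(geno, markers, design)
  truth <- if (length(truth) > 0) {
    dplyr::arrange(dplyr::bind_rows(truth), .data$line, .data$chrom, .data$pos_morgan)
  } else {
    tibble::tibble(line = character(0), chrom = character(0), pos_morgan = numeric(0))
  }
  structure(
    list(genotypes = geno, markers = markers, truth = truth,
         genome = genome, params = params, design = design),
    class = "dh_population"
  )
}

#' @export
print.dh_population <- function(x, ...) {
  cat(sprintf(
    "<dh_population> %d lines x %d markers on %d chromosomes, %d true crossovers\n",
    nrow(x$genotypes), ncol(x$genotypes),
    length(unique(x$markers$chrom)), nrow(x$truth)
  ))
  invisible(x)
}
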