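#' Analytic kernels of the gamma-sprinkling model
#'
#' Returns the renewal kernels of the gamete-level P1 process with bivalent
#' inter-arrival Gamma(shape `nu`, rate `2 nu (1 - p)`) thinned with
#' retention 1/2: the inter-crossover density
#' `g(d) = sum_m 2^-m dgamma(d; m nu, 2 nu (1-p))` (geometric mixture from
#' thinning), its CDF `G`, the stationary first-event density
#' `h(x) = (1-p) (1 - G(x))`, and the void probability
#' `V(L) = 1 - (1-p) int_0^L (1 - G)`. The mixture is truncated at 40 terms
#' (tail below 1e-12).
#'
#' @param nu Interference intensity (gamma shape), >= 1.
#' @param p P2 proportion, in \[0, 0.5\].
#' @return List of vectorized functions `g`, `G`, `h`, `V`, plus the
#'   parameters.
#' @export
renewal_kernels <- function(nu, p) {
  if (nu < 1) stop("nu must be >= 1")
  if (p < 0 || p > 0.5) stop("p must be in [0, 0.5]")
  list(
    g = function(d) g_kernel_cpp(as.numeric(d), nu, p),
    G = function(d) G_kernel_cpp(as.numeric(d), nu, p),
    h = function(x) (1 - p) * (1 - G_kernel_cpp(as.numeric(x), nu, p)),
    V = function(L) vapply(as.numeric(L), void_probability_cpp, numeric(1),
                           nu = nu, p = p),
    nu = nu, p = p, lambda1 = 1 - p
  )
}

#' Log-likelihood of one gamete's crossover configuration
#'
#' Sums over all assignments of the observed crossovers to the
#' non-interfering pathway P2 (exhaustive subset sum, refused for more than
#' 20 crossovers): the P2 part contributes `p^|A| exp(-p L)` and the P1
#' complement contributes the stationary ordered-point renewal density
#' `h(y1) prod g(gaps) (1 - G(L - y_k))`, with the empty complement
#' contributing the void probability `V(L)`.
#'
#' @param positions Sorted crossover genetic positions in (0, L), Morgan.
#' @param L Chromosome genetic length (Morgan).
#' @param nu,p Model parameters.
#' @return The log-likelihood contribution of the gamete.
#' @export
gamete_loglik <- function(positions, L, nu, p) {
  if (length(positions) > 20) {
    stop("more than 20 crossovers on one gamete: physically implausible ",
         "for chromosomes of a few Morgan; refusing the exhaustive sum")
  }
  if (any(positions <= 0 | positions >= L)) {
    stop("crossover positions must lie strictly inside (0, L)")
  }
  if (nu < 1) stop("nu must be >= 1")
  if (p < 0 || p > 0.5) stop("p must be in [0, 0.5]")
  gamete_loglik_cpp(sort(as.numeric(positions)), L, nu, p)
}

#' Assemble gamete crossover sets for interference analysis
#'
#' Builds the complete gamete list (every line x chromosome, including
#' gametes without crossovers, which carry likelihood information through
#' the void probability) from a crossover table in genetic coordinates.
#'
#' @param co Tibble with columns `line`, `chrom`, `pos_morgan`.
#' @param lengths Tibble with columns `chrom`, `L_morgan`.
#' @param line_ids All line identifiers.
#' @return Tibble `line`, `chrom`, `L`, and list-column `positions`.
#' @export
gamete_co_sets <- function(co, lengths, line_ids) {
  grid <- tidyr::expand_grid(line = line_ids, chrom = lengths$chrom)
  grid <- dplyr::left_join(grid, lengths, by = "chrom")
  pos <- purrr::map2(grid$line, grid$chrom, function(l, ch) {
    sort(co$pos_morgan[co$line == l & co$chrom == ch])
  })
  grid |>
    dplyr::rename(L = "L_morgan") |>
    dplyr::mutate(positions = pos)
}

sprinkle_negll <- function(par, positions, L) {
  nu <- exp(par[1])
  p <- par[2]
  if (nu < 1 || nu > 50 || p < 0 || p > 0.5) return(1e12)
  -sprinkle_loglik_cpp(positions, L, nu, p)
}

#' Fit the gamma-sprinkling interference model by maximum likelihood
#'
#' Maximizes the summed gamete log-likelihood over `nu` in \[1, 50\] and `p`
#' in \[0, 0.5\] (a coarse log-spaced grid followed by Nelder-Mead
#' refinement, deterministic throughout). Parameter variances come from the
#' inverse of the observed Fisher information (numerical Hessian, central
#' differences); optima on the parameter boundary are flagged, as is a
#' non-positive-definite Hessian (variances reported `NA`).
#'
#' @param gametes Tibble from [gamete_co_sets()] (columns `L`, `positions`).
#' @param nu_grid,p_grid Coarse search grids.
#' @return Object of class `gamma_sprinkle_fit`: estimates, log-likelihood,
#'   Fisher variances, gamete count, convergence/boundary flags.
#' @export
fit_gamma_sprinkle <- function(gametes,
                               nu_grid = exp(seq(log(1), log(50), length.out = 13)),
                               p_grid = seq(0, 0.5, length.out = 11)) {
  stopifnot(nrow(gametes) > 0)
  if (nrow(gametes) < 30) {
    warning("fewer than 30 gametes; interference estimates will be unstable")
  }
  kmax <- max(lengths(gametes$positions))
  if (kmax > 20) stop("a gamete carries more than 20 crossovers")
  ord <- order(gametes$L) # group equal lengths: void probabilities are cached
  positions <- gametes$positions[ord]
  L <- gametes$L[ord]

  grid <- tidyr::expand_grid(nu = nu_grid, p = p_grid)
  grid$ll <- purrr::map2_dbl(grid$nu, grid$p,
                             ~ sprinkle_loglik_cpp(positions, L, .x, .y))
  best <- grid[which.max(grid$ll), ]

  opt <- stats::optim(c(log(best$nu), best$p), sprinkle_negll,
                      positions = positions, L = L,
                      method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  nu_hat <- exp(opt$par[1])
  p_hat <- opt$par[2]
  ll <- -opt$value

  boundary <- nu_hat < 1.01 || nu_hat > 49.5 || p_hat < 1e-3 || p_hat > 0.499

  # observed information on the (nu, p) scale, central differences
  var_nu <- var_p <- NA_real_
  hess_ok <- FALSE
  f <- function(th) sprinkle_loglik_cpp(positions, L, th[1], th[2])
  step <- c(max(nu_hat * 1e-3, 1e-5), max(abs(p_hat) * 1e-3, 1e-5))
  th <- c(nu_hat, p_hat)
  lo <- c(1, 0); hi <- c(50, 0.5)
  if (all(th - step >= lo) && all(th + step <= hi)) {
    H <- matrix(NA_real_, 2, 2)
    f0 <- ll
    for (i in 1:2) {
      ei <- c(0, 0); ei[i] <- step[i]
      H[i, i] <- (f(th + ei) - 2 * f0 + f(th - ei)) / step[i]^2
    }
    e1 <- c(step[1], 0); e2 <- c(0, step[2])
    H[1, 2] <- H[2, 1] <- (f(th + e1 + e2) - f(th + e1 - e2) -
                             f(th - e1 + e2) + f(th - e1 - e2)) /
      (4 * step[1] * step[2])
    info <- -H
    if (all(is.finite(info)) && det(info) > 0 && info[1, 1] > 0) {
      v <- solve(info)
      if (v[1, 1] > 0 && v[2, 2] > 0) {
        var_nu <- v[1, 1]
        var_p <- v[2, 2]
        hess_ok <- TRUE
      }
    }
  }

  structure(
    list(nu = nu_hat, p = p_hat, loglik = ll,
         var_nu = var_nu, var_p = var_p,
         n_gametes = nrow(gametes),
         convergence = opt$convergence == 0,
         boundary = boundary, hessian_ok = hess_ok),
    class = "gamma_sprinkle_fit"
  )
}

#' @export
print.gamma_sprinkle_fit <- function(x, ...) {
  cat(sprintf(
    "<gamma_sprinkle_fit> nu = %.3f (se %.3f), p = %.4f (se %.4f)\n",
    x$nu, sqrt(x$var_nu), x$p, sqrt(x$var_p)
  ))
  cat(sprintf("  loglik = %.2f over %d gametes%s%s\n", x$loglik, x$n_gametes,
              if (!x$convergence) " [NOT CONVERGED]" else "",
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' Welch comparison of interference parameters between two fits
#'
#' Tests a difference in `nu` or `p` between two fitted populations using
#' the Welch statistic with variances from the Fisher information and a
#' Welch-Satterthwaite approximation based on the per-fit gamete counts.
#'
#' @param fit_a,fit_b `gamma_sprinkle_fit` objects.
#' @param parameter `"nu"` or `"p"`.
#' @param n_tests Bonferroni family size.
#' @param ids Identifiers of the two fits.
#' @return One-row comparison tibble; marked unreliable if either fit sits
#'   on a parameter boundary.
#' @export
compare_fits <- function(fit_a, fit_b, parameter = c("nu", "p"),
                         n_tests = 1, ids = c("A", "B")) {
  parameter <- match.arg(parameter)
  ea <- fit_a[[parameter]]; eb <- fit_b[[parameter]]
  va <- fit_a[[paste0("var_", parameter)]]
  vb <- fit_b[[paste0("var_", parameter)]]
  if (is.na(va) || is.na(vb) || va <= 0 || vb <= 0) {
    stop("both fits need positive Fisher-information variances")
  }
  stat <- (ea - eb) / sqrt(va + vb)
  df <- (va + vb)^2 /
    (va^2 / (fit_a$n_gametes - 1) + vb^2 / (fit_b$n_gametes - 1))
  raw_p <- 2 * stats::pt(-abs(stat), df)
  note <- if (fit_a$boundary || fit_b$boundary) "boundary fit: unreliable" else NA_character_
  comparison_result(ids[1], ids[2], statistic = stat, df = df,
                    raw_p = raw_p, n_tests = n_tests,
                    direction = if (ea > eb) ids[1] else if (eb > ea) ids[2] else "equal",
                    note = note)
}

#' Monte-Carlo test against the no-interference null
#'
#' Simulates the null of a homogeneous Poisson process at the data's
#' per-chromosome crossover rates and compares two statistics sensitive to
#' interference: the variance of per-gamete crossover counts (interference
#' reduces it below the Poisson value) and the mean nearest inter-crossover
#' distance (interference increases it). Two-sided Monte-Carlo p-values.
#'
#' @param gametes Tibble from [gamete_co_sets()].
#' @param n_sim Number of null simulations (>= 999).
#' @param seed Optional seed.
#' @return Tibble with one row per statistic: observed value and p-value.
#' @export
no_interference_test <- function(gametes, n_sim = 999, seed = NULL) {
  if (n_sim < 999) stop("n_sim must be at least 999")
  if (!is.null(seed)) set.seed(seed)
  count_stat <- function(k) stats::var(k)
  dist_stat <- function(pos_list) {
    gaps <- purrr::map_dbl(pos_list, function(x) {
      if (length(x) < 2) return(NA_real_)
      min(diff(x))
    })
    if (all(is.na(gaps))) NA_real_ else mean(gaps, na.rm = TRUE)
  }
  per_line_counts <- function(pos_list, line) {
    tapply(lengths(pos_list), line, sum)
  }

  obs_counts <- as.vector(per_line_counts(gametes$positions, gametes$line))
  obs_var <- count_stat(obs_counts)
  obs_dist <- dist_stat(gametes$positions)

  rates <- gametes |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(L = .data$L[1],
                     rate = sum(lengths(.data$positions)) / (dplyr::n() * .data$L[1]),
                     n = dplyr::n(), .groups = "drop")

  sim_var <- sim_dist <- numeric(n_sim)
  for (s in seq_len(n_sim)) {
    pos_list <- vector("list", nrow(gametes))
    for (r in seq_len(nrow(rates))) {
      idx <- which(gametes$chrom == rates$chrom[r])
      k <- stats::rpois(length(idx), rates$rate[r] * rates$L[r])
      pts <- stats::runif(sum(k), 0, rates$L[r])
      grp <- factor(rep(seq_along(idx), k), levels = seq_along(idx))
      pos_list[idx] <- purrr::map(split(pts, grp), sort)
    }
    sim_var[s] <- count_stat(as.vector(per_line_counts(pos_list, gametes$line)))
    sim_dist[s] <- dist_stat(pos_list)
  }

  mc_p <- function(obs, sim) {
    if (is.na(obs)) return(NA_real_)
    sim <- sim[!is.na(sim)]
    lo <- (1 + sum(sim <= obs)) / (1 + length(sim))
    hi <- (1 + sum(sim >= obs)) / (1 + length(sim))
    min(1, 2 * min(lo, hi))
  }
  tibble::tibble(
    statistic = c("count_variance", "mean_nearest_distance"),
    observed = c(obs_var, obs_dist),
    p_value = c(mc_p(obs_var, sim_var), mc_p(obs_dist, sim_dist))
  )
}

#' Proximity reduction factor of the interfering pathway
#'
#' The factor by which interference of intensity `nu` reduces the
#' probability that the next P1 crossover falls within genetic distance `d`
#' of a given one: the no-interference probability `1 - exp(-d)` divided by
#' the same probability under gamma inter-crossover spacing with shape `nu`
#' and unit mean, `F_Gamma(d; nu, rate = nu)`.
#'
#' @param nu Interference intensity, >= 1.
#' @param d Genetic distance in Morgan, > 0.
#' @return Dimensionless factor >= 1 (exactly 1 at `nu = 1`).
#' @export
reduction_factor <- function(nu, d) {
  if (any(nu < 1)) stop("nu must be >= 1")
  if (any(d <= 0)) stop("d must be positive")
  (1 - exp(-d)) / stats::pgamma(d, shape = nu, rate = nu)
}
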