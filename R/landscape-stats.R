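#' Per-chromosome and genome-wide recombination-rate summary
#'
#' Genetic lengths are measured on (imputed) Marey maps between the common
#' physical extremities of the grid; the genome scope sums genetic length
#' and physical span over chromosomes. The genome-wide recombination rate
#' (GWRR) is total genetic length (cM) divided by physical span (Mbp).
#'
#' @param maps Named list of `marey_map`s, one per chromosome, for one
#'   population.
#' @param n_lines Number of DH lines in the population.
#' @param population Population identifier.
#' @param genome_mbp Optional fixed physical denominator for the genome rate
#'   (Mbp); by default the sum of the per-chromosome grid spans.
#' @return Tibble with one row per chromosome plus a `"genome"` row:
#'   `population`, `scope`, `genetic_length_cm`, `physical_span_mbp`,
#'   `rate_cm_per_mbp`, `n_lines`.
#' @export
rate_summary <- function(maps, n_lines, population = "pop", genome_mbp = NULL) {
  per <- purrr::imap_dfr(maps, function(m, ch) {
    tibble::tibble(
      population = population, scope = ch,
      genetic_length_cm = max(m$gen_cm) - min(m$gen_cm),
      physical_span_mbp = max(m$pos_mbp) - min(m$pos_mbp)
    )
  })
  span <- if (is.null(genome_mbp)) sum(per$physical_span_mbp) else genome_mbp
  out <- dplyr::bind_rows(
    per,
    tibble::tibble(population = population, scope = "genome",
                   genetic_length_cm = sum(per$genetic_length_cm),
                   physical_span_mbp = span)
  )
  out |>
    dplyr::mutate(rate_cm_per_mbp = .data$genetic_length_cm / .data$physical_span_mbp,
                  n_lines = n_lines)
}

#' Pool populations by line-weighted averaging
#'
#' The pooled genetic length for each scope is the line-number-weighted mean
#' of the member lengths, and the pooled rate is recomputed from the pooled
#' length over the shared physical span.
#'
#' @param summaries A [rate_summary()]-style tibble covering several
#'   populations (shared physical support).
#' @param population Label for the pooled rows.
#' @return Pooled summary tibble, one row per scope.
#' @export
pool_populations <- function(summaries, population = "pooled") {
  if (nrow(summaries) == 0) stop("no summaries to pool")
  summaries |>
    dplyr::group_by(.data$scope) |>
    dplyr::summarise(
      genetic_length_cm = sum(.data$n_lines * .data$genetic_length_cm) /
        sum(.data$n_lines),
      physical_span_mbp = .data$physical_span_mbp[1],
      n_lines = sum(.data$n_lines),
      .groups = "drop"
    ) |>
    dplyr::mutate(population = population,
                  rate_cm_per_mbp = .data$genetic_length_cm / .data$physical_span_mbp) |>
    dplyr::select("population", "scope", "genetic_length_cm",
                  "physical_span_mbp", "rate_cm_per_mbp", "n_lines")
}

comparison_result <- function(id_a, id_b, statistic, df, raw_p, n_tests,
                              direction, note = NA_character_) {
  tibble::tibble(
    id_a = id_a, id_b = id_b, statistic = statistic, df = df,
    raw_p = raw_p, n_tests = n_tests,
    adjusted_p = pmin(1, raw_p * n_tests),
    direction = direction, note = note
  )
}

#' Welch test for a genetic-map-length difference
#'
#' Compares two populations' per-line genome-wide crossover counts (for DH
#' gametes, map length in cM is 100 times the mean count, and the per-line
#' counts supply the variance the Welch test needs) with an unequal-variance
#' two-sample t test and Bonferroni correction.
#'
#' @param counts_a,counts_b Per-line genome-wide crossover counts.
#' @param n_tests Bonferroni family size (default 1).
#' @param ids Identifiers of the two populations.
#' @return One-row comparison tibble: statistic, Welch df, raw and adjusted
#'   p, and which member is larger.
#' @export
compare_lengths <- function(counts_a, counts_b, n_tests = 1,
                            ids = c("A", "B")) {
  stopifnot(length(counts_a) >= 2, length(counts_b) >= 2)
  if (stats::var(counts_a) == 0 && stats::var(counts_b) == 0) {
    eq <- mean(counts_a) == mean(counts_b)
    return(comparison_result(ids[1], ids[2], statistic = if (eq) 0 else Inf,
                             df = NA_real_, raw_p = if (eq) 1 else 0,
                             n_tests = n_tests,
                             direction = direction_label(counts_a, counts_b, ids),
                             note = "zero variance"))
  }
  tt <- stats::t.test(counts_a, counts_b, var.equal = FALSE)
  comparison_result(ids[1], ids[2],
                    statistic = unname(tt$statistic), df = unname(tt$parameter),
                    raw_p = tt$p.value, n_tests = n_tests,
                    direction = direction_label(counts_a, counts_b, ids))
}

direction_label <- function(a, b, ids) {
  if (mean(a) > mean(b)) ids[1] else if (mean(b) > mean(a)) ids[2] else "equal"
}

#' Bin boundaries of equal genetic length
#'
#' Splits a chromosome into `n_bins` physical intervals each spanning
#' `1/n_bins` of the reference map's genetic length, by inverting the
#' (monotone) reference Marey map at equally spaced genetic quantiles.
#'
#' @param reference A monotone `marey_map` (typically the mean normalized
#'   map of the populations being compared).
#' @param n_bins Number of bins (default 10).
#' @return Tibble `bin`, `start_mbp`, `end_mbp`, `genetic_span_cm`.
#' @export
equal_genetic_bins <- function(reference, n_bins = 10) {
  g <- reference$gen_cm
  pos <- reference$pos_mbp
  if (any(diff(g) < -1e-9)) stop("reference map must be monotone")
  total <- g[length(g)] - g[1]
  if (total <= 0) stop("reference map has zero genetic span")
  targets <- g[1] + total * seq(0, 1, length.out = n_bins + 1)
  # invert; plateaus resolved to the leftmost attaining position
  bounds <- stats::approx(g, pos, xout = targets, ties = "min", rule = 2)$y
  bounds[1] <- pos[1]
  bounds[n_bins + 1] <- pos[length(pos)]
  tibble::tibble(
    bin = seq_len(n_bins),
    start_mbp = bounds[-(n_bins + 1)], end_mbp = bounds[-1],
    genetic_span_cm = total / n_bins
  )
}

#' Chi-squared comparison of recombination-landscape shapes
#'
#' Crossover physical positions of two populations are counted in bins of
#' equal genetic length on the shared reference map and compared with a
#' chi-squared test on the 2 x n_bins contingency table. Because binning is
#' genetic, overall map-length differences cancel and the test targets the
#' landscape shape. Bins whose expected count drops below `min_expected`
#' are merged pairwise with a warning. Per-bin standardized residuals are
#' attached as an attribute.
#'
#' @param co_a,co_b Crossover physical positions (Mbp) for the two
#'   populations on one chromosome.
#' @param bins Bin tibble from [equal_genetic_bins()].
#' @param n_tests Bonferroni family size (default 1).
#' @param ids Population identifiers.
#' @param min_expected Minimum expected cell count before merging (default
#'   1).
#' @return One-row comparison tibble with attribute `"residuals"`.
#' @export
compare_landscapes <- function(co_a, co_b, bins, n_tests = 1,
                               ids = c("A", "B"), min_expected = 1) {
  brks <- c(bins$start_mbp[1], bins$end_mbp)
  ca <- as.vector(table(cut(co_a, brks, include.lowest = TRUE)))
  cb <- as.vector(table(cut(co_b, brks, include.lowest = TRUE)))
  tab <- rbind(ca, cb)
  # merge adjacent bins while any expected count is too small
  merged <- FALSE
  repeat {
    exp_tab <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (all(exp_tab >= min_expected) || ncol(tab) <= 2) break
    j <- which.min(apply(exp_tab, 2, min))
    k <- if (j == ncol(tab)) j - 1 else j
    tab[, k] <- tab[, k] + tab[, k + 1]
    tab <- tab[, -(k + 1), drop = FALSE]
    merged <- TRUE
  }
  if (merged) warning("merged landscape bins with small expected counts")
  if (identical(ca, cb)) {
    res <- comparison_result(ids[1], ids[2], statistic = 0,
                             df = ncol(tab) - 1, raw_p = 1, n_tests = n_tests,
                             direction = "equal")
    attr(res, "residuals") <- matrix(0, 2, ncol(tab))
    return(res)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  res <- comparison_result(ids[1], ids[2],
                           statistic = unname(ct$statistic),
                           df = unname(ct$parameter),
                           raw_p = ct$p.value, n_tests = n_tests,
                           direction = NA_character_)
  attr(res, "residuals") <- ct$stdres
  res
}

#' Combine per-chromosome landscape comparisons into a population-level test
#'
#' Chi-squared statistics are additive over independent chromosomes: the
#' summed statistic with summed degrees of freedom tests whether two
#' populations share the shape of their recombination landscapes genome
#' wide (the population-wise comparison considering all chromosomes
#' together).
#'
#' @param results Comparison rows from [compare_landscapes()], one per
#'   chromosome, for the same population pair.
#' @param n_tests Bonferroni family size for the combined test.
#' @return One-row comparison tibble.
#' @export
combine_landscape_comparisons <- function(results, n_tests = 1) {
  stopifnot(nrow(results) >= 1)
  stat <- sum(results$statistic)
  df <- sum(results$df)
  comparison_result(results$id_a[1], results$id_b[1], statistic = stat,
                    df = df, raw_p = stats::pchisq(stat, df, lower.tail = FALSE),
                    n_tests = n_tests, direction = NA_character_)
}

#' Pairwise -log10(p) matrix with a clustering order
#'
#' Builds the symmetric matrix of `-log10(adjusted p)` over all pairs and
#' orders rows/columns by average-linkage hierarchical clustering on
#' Euclidean distances.
#'
#' @param results Comparison tibble with columns `id_a`, `id_b`,
#'   `adjusted_p` covering all unordered pairs.
#' @return List with `matrix` (ordered), `order` (labels), and `hclust`.
#' @export
pairwise_matrix <- function(results) {
  ids <- sort(unique(c(results$id_a, results$id_b)))
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 0
  for (i in seq_len(nrow(results))) {
    v <- -log10(max(results$adjusted_p[i], 1e-300))
    m[results$id_a[i], results$id_b[i]] <- v
    m[results$id_b[i], results$id_a[i]] <- v
  }
  if (any(is.na(m))) warning("missing pairs; NA cells excluded from distances")
  d <- stats::dist(m)
  d[is.na(d)] <- 0
  hc <- stats::hclust(d, method = "average")
  ord <- ids[hc$order]
  list(matrix = m[ord, ord], order = ord, hclust = hc)
}

#' Additive parental effects on genome-wide recombination rate
#'
#' Under an additive model where a cross's GWRR is the mean of two parental
#' effects, the effect of each founder (relative to B73) is the GWRR of its
#' cross with the central line minus the GWRR of the cross of the same
#' central line with B73. Effects are defined up to that common reference
#' constant.
#'
#' @param crosses Tibble with columns `population`, `central`, `founder`,
#'   `gwrr`; each founder appears in exactly one cross with a central line.
#' @param b73_id Identifier of the reference founder (default `"B73"`).
#' @return Tibble `founder`, `central`, `effect_cm_per_mbp`.
#' @export
parent_additive_effects <- function(crosses, b73_id = "B73") {
  anchors <- crosses |> dplyr::filter(.data$founder == b73_id)
  if (nrow(anchors) == 0) stop("no central x ", b73_id, " anchor cross present")
  anchor_gwrr <- stats::setNames(anchors$gwrr, anchors$central)
  eff <- crosses |> dplyr::filter(.data$founder != b73_id)
  missing_anchor <- setdiff(unique(eff$central), names(anchor_gwrr))
  if (length(missing_anchor) > 0) {
    stop("missing ", b73_id, " anchor for central line(s): ",
         paste(missing_anchor, collapse = ", "))
  }
  eff |>
    dplyr::transmute(
      founder = .data$founder, central = .data$central,
      effect_cm_per_mbp = .data$gwrr - unname(anchor_gwrr[.data$central])
    )
}

#' Regression of recombination rate on population structure
#'
#' Ordinary least squares of a per-item response (e.g. GWRR or a parental
#' effect) on a predictor (e.g. mean parental flintness), reporting the
#' slope, intercept, R-squared and the F-test p-value for zero slope.
#'
#' @param x Predictor values.
#' @param y Response values.
#' @return One-row tibble: `slope`, `intercept`, `r_squared`, `p_value`,
#'   `n`; the fitted `lm` object is attached as attribute `"fit"`.
#' @export
structure_regression <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::var(x) == 0) stop("predictor has zero variance")
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  out <- tibble::tibble(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = s$r.squared,
    p_value = unname(stats::pf(s$fstatistic[1], s$fstatistic[2],
                               s$fstatistic[3], lower.tail = FALSE)),
    n = length(x)
  )
  attr(out, "fit") <- fit
  out
}
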