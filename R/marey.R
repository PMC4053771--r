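new_marey_map <- function(df, chrom, grid_step, masks = NULL, outliers = NULL) {
  structure(
    tibble::as_tibble(df),
    chrom = chrom, grid_step = grid_step,
    masks = if (is.null(masks)) {
      tibble::tibble(start_mbp = numeric(0), end_mbp = numeric(0))
    } else tibble::as_tibble(masks),
    outliers = outliers,
    class = c("marey_map", class(tibble::tibble()))
  )
}

#' Fit a bare Marey map
#'
#' Smooths marker genetic-vs-physical positions with a cubic smoothing
#' spline (generalized cross-validation, with a degrees-of-freedom cap so the
#' fit never interpolates every point), iteratively discarding gross
#' outliers (absolute residual beyond `mad_k` robust MADs, at most
#' `max_rounds` rounds), evaluates the fit on a uniform physical grid,
#' projects it onto the nearest nondecreasing sequence (isotonic
#' projection), and anchors the first grid value at 0 cM.
#'
#' @param bp Marker physical positions (bp).
#' @param cm Marker genetic positions (cM).
#' @param chrom Chromosome label stored with the map.
#' @param grid_step Grid step in Mbp (default 0.5).
#' @param mad_k Outlier constant: points with |residual| > `mad_k` * MAD are
#'   dropped (default 4).
#' @param max_rounds Maximum outlier-rejection rounds (default 5).
#' @param df_cap Cap on spline degrees of freedom as a fraction of the
#'   number of points (default 0.8).
#' @param df_max Absolute cap on spline degrees of freedom. Cumulative map
#'   positions carry random-walk (not independent) noise, under which
#'   generalized cross-validation systematically undersmooths; the default
#'   allows one degree of freedom per 10 Mbp (at least 8), enough for the
#'   smooth chromosome-scale structure of a Marey curve.
#' @return A `marey_map`: tibble with columns `pos_mbp`, `gen_cm`,
#'   `provenance`, plus attributes `chrom`, `grid_step`, `masks`,
#'   `outliers`.
#' @export
fit_bare_marey <- function(bp, cm, chrom = "chr", grid_step = 0.5,
                           mad_k = 4, max_rounds = 5, df_cap = 0.8,
                           df_max = NULL) {
  if (length(bp) != length(cm)) stop("bp and cm must have equal length")
  ok <- !is.na(bp) & !is.na(cm)
  bp <- bp[ok]; cm <- cm[ok]
  if (length(bp) < 10) {
    stop("need at least 10 markers to fit a Marey map; got ", length(bp))
  }
  o <- order(bp)
  x <- bp[o] / 1e6
  y <- cm[o]
  if (stats::sd(y) == 0) {
    warning("all markers share one genetic position; returning a flat map")
    grid <- seq(min(x), max(x), by = grid_step)
    return(new_marey_map(
      tibble::tibble(pos_mbp = grid, gen_cm = 0, provenance = "observed"),
      chrom, grid_step
    ))
  }

  if (is.null(df_max)) df_max <- max(8, diff(range(x)) / 10)
  fit_once <- function(x, y) {
    n <- length(unique(x))
    lim <- min(df_cap * n, df_max)
    ss <- stats::smooth.spline(x, y)
    if (ss$df > lim) ss <- stats::smooth.spline(x, y, df = max(4, lim))
    ss
  }
  keep <- rep(TRUE, length(x))
  removed <- integer(0)
  ss <- fit_once(x, y)
  # residuals below this scale are numerical, not biological: never treat
  # them as outliers (0.001 cM is far under any array map resolution)
  mad_floor <- max(1e-3, 1e-9 * diff(range(y)))
  for (round in seq_len(max_rounds)) {
    res <- y[keep] - stats::predict(ss, x[keep])$y
    s <- stats::mad(res)
    if (s <= mad_floor) break
    bad <- abs(res) > mad_k * s
    if (!any(bad)) break
    removed <- c(removed, which(keep)[bad])
    keep[which(keep)[bad]] <- FALSE
    if (sum(keep) < 10) break
    ss <- fit_once(x[keep], y[keep])
  }

  grid <- seq(min(x), max(x), by = grid_step)
  if (grid[length(grid)] < max(x)) grid <- c(grid, max(x))
  fitted <- stats::predict(ss, grid)$y
  mono <- stats::isoreg(grid, fitted)$yf
  mono <- mono - mono[1]
  new_marey_map(
    tibble::tibble(pos_mbp = grid, gen_cm = mono, provenance = "observed"),
    chrom, grid_step,
    outliers = tibble::tibble(bp = bp[o][removed], cm = y[removed])
  )
}

#' Parental similarity in sliding windows
#'
#' Fraction of markers at which the two parents carry identical non-missing
#' alleles, in sliding physical windows (default 10 Mbp windows stepped by
#' 2 Mbp). Windows with fewer than `min_markers` informative markers are
#' flagged low-confidence.
#'
#' @param parent1,parent2 Allele vectors over the marker table.
#' @param markers Marker table (`marker`, `chrom`, `bp`) for one chromosome.
#' @param window_mbp,step_mbp Window size and step (Mbp).
#' @param min_markers Informative-marker floor per window (default 20).
#' @return Tibble `chrom`, `center_mbp`, `similarity`, `n_markers`,
#'   `low_confidence`.
#' @export
similarity_track <- function(parent1, parent2, markers,
                             window_mbp = 10, step_mbp = 2, min_markers = 20) {
  stopifnot(length(parent1) == nrow(markers), length(parent2) == nrow(markers))
  pos <- markers$bp / 1e6
  half <- window_mbp / 2
  centers <- seq(min(pos) + half, max(max(pos) - half, min(pos) + half),
                 by = step_mbp)
  purrr::map_dfr(centers, function(cen) {
    sel <- pos >= cen - half & pos <= cen + half
    p1 <- parent1[sel]; p2 <- parent2[sel]
    ok <- !is.na(p1) & !is.na(p2)
    n <- sum(ok)
    tibble::tibble(
      chrom = markers$chrom[1], center_mbp = cen,
      similarity = if (n > 0) mean(p1[ok] == p2[ok]) else NA_real_,
      n_markers = n, low_confidence = n < min_markers
    )
  })
}

# merge overlapping/adjacent [start, end] intervals
merge_intervals <- function(iv) {
  if (nrow(iv) == 0) return(iv)
  iv <- iv[order(iv$start_mbp), ]
  out <- iv[1, ]
  for (i in seq_len(nrow(iv))[-1]) {
    j <- nrow(out)
    if (iv$start_mbp[i] <= out$end_mbp[j]) {
      out$end_mbp[j] <- max(out$end_mbp[j], iv$end_mbp[i])
    } else {
      out <- dplyr::bind_rows(out, iv[i, ])
    }
  }
  out
}

#' Detect mask intervals for a Marey map
#'
#' Regions where mapping information is lacking are masked: maximal runs of
#' windows whose parental similarity reaches `sim_threshold` (IBD-like
#' segments) or whose polymorphic-marker density falls below
#' `density_threshold`, unioned with any user-supplied intervals (e.g. known
#' non-colinear regions).
#'
#' @param track A [similarity_track()] result (may be `NULL` if only user
#'   masks are wanted).
#' @param markers Marker table of the polymorphic markers retained for
#'   mapping on this chromosome.
#' @param user_masks Optional tibble of intervals (`start_mbp`, `end_mbp`).
#' @param sim_threshold Similarity at or above which a window is masked
#'   (default 0.97).
#' @param density_threshold Minimum polymorphic markers per Mbp (default
#'   0.5, i.e. 1 marker per 2 Mbp).
#' @param window_mbp Window size used by the track (Mbp).
#' @return Tibble of merged mask intervals (`start_mbp`, `end_mbp`).
#' @export
detect_masks <- function(track, markers, user_masks = NULL,
                         sim_threshold = 0.97, density_threshold = 0.5,
                         window_mbp = 10) {
  masks <- tibble::tibble(start_mbp = numeric(0), end_mbp = numeric(0))
  if (!is.null(track) && nrow(track) > 0) {
    half <- window_mbp / 2
    pos <- markers$bp / 1e6
    dens <- vapply(track$center_mbp, function(cen) {
      sum(pos >= cen - half & pos <= cen + half) / window_mbp
    }, numeric(1))
    bad <- (!is.na(track$similarity) & track$similarity >= sim_threshold) |
      dens < density_threshold
    if (any(bad)) {
      masks <- tibble::tibble(
        start_mbp = track$center_mbp[bad] - half,
        end_mbp = track$center_mbp[bad] + half
      )
    }
  }
  if (!is.null(user_masks) && nrow(user_masks) > 0) {
    masks <- dplyr::bind_rows(masks, tibble::as_tibble(user_masks))
  }
  merge_intervals(masks)
}

#' Attach masks to a Marey map
#'
#' @param map A `marey_map`.
#' @param masks Tibble of intervals (`start_mbp`, `end_mbp`).
#' @return The map with its `masks` attribute set (a "masked" Marey map).
#' @export
set_masks <- function(map, masks) {
  attr(map, "masks") <- merge_intervals(tibble::as_tibble(masks))
  map
}

#' Mask intervals attached to a Marey map
#'
#' @param map A `marey_map`.
#' @return Tibble of intervals (`start_mbp`, `end_mbp`).
#' @export
marey_masks <- function(map) attr(map, "masks")

grid_in_masks <- function(pos, masks) {
  inside <- rep(FALSE, length(pos))
  for (j in seq_len(nrow(masks))) {
    inside <- inside | (pos >= masks$start_mbp[j] & pos <= masks$end_mbp[j])
  }
  inside
}

#' Impute masked regions of a Marey map from other populations
#'
#' Within each target mask, the per-grid-interval genetic increments are
#' taken from the comparison partner (first donor) where it is unmasked, and
#' otherwise from the pointwise average of all unmasked donors, each donor
#' increment rescaled by the ratio of target-to-donor mean recombination
#' rate over the shared unmasked support of the chromosome. The imputed
#' increments are spliced into the target and re-accumulated, preserving
#' continuity and monotonicity. A mask covered by no donor is filled by
#' linear interpolation with a warning.
#'
#' @param target A masked `marey_map`.
#' @param donors List of `marey_map`s on the same grid (the first is the
#'   comparison partner).
#' @return The imputed `marey_map`, with provenance `"imputed"` inside
#'   masks.
#' @export
impute_masked <- function(target, donors) {
  if (inherits(donors, "marey_map")) donors <- list(donors)
  pos <- target$pos_mbp
  for (d in donors) {
    if (length(d$pos_mbp) != length(pos) || max(abs(d$pos_mbp - pos)) > 1e-9) {
      stop("all maps must share the same grid")
    }
  }
  masks <- marey_masks(target)
  if (nrow(masks) == 0) return(target)

  mid <- (pos[-1] + pos[-length(pos)]) / 2
  h <- diff(pos)
  t_masked <- grid_in_masks(mid, masks)
  inc_t <- diff(target$gen_cm)
  d_masked <- lapply(donors, function(d) grid_in_masks(mid, marey_masks(d)))
  inc_d <- lapply(donors, function(d) diff(d$gen_cm))

  # scale ratio per donor: mean rate over intervals unmasked in both maps
  scale_for <- function(k) {
    shared <- !t_masked & !d_masked[[k]]
    if (!any(shared)) return(NA_real_)
    rt <- sum(inc_t[shared]) / sum(h[shared])
    rd <- sum(inc_d[[k]][shared]) / sum(h[shared])
    if (rd <= 0) NA_real_ else rt / rd
  }
  scales <- vapply(seq_along(donors), scale_for, numeric(1))

  inc_new <- inc_t
  unmatched <- FALSE
  for (i in which(t_masked)) {
    avail <- which(!vapply(d_masked, `[`, logical(1), i) & !is.na(scales))
    if (length(avail) == 0) {
      inc_new[i] <- NA_real_ # fill later by interpolation
      unmatched <- TRUE
    } else if (!vapply(d_masked, `[`, logical(1), i)[1] && !is.na(scales[1])) {
      inc_new[i] <- scales[1] * inc_d[[1]][i]
    } else {
      inc_new[i] <- mean(vapply(avail, function(k) scales[k] * inc_d[[k]][i],
                                numeric(1)))
    }
  }
  if (unmatched) {
    warning("some masked intervals had no unmasked donor; linear fill used")
    na <- is.na(inc_new)
    # spread: constant rate equal to the chromosome mean over observed part
    mean_rate <- sum(inc_new[!na]) / sum(h[!na])
    inc_new[na] <- mean_rate * h[na]
  }
  gen <- cumsum(c(0, pmax(inc_new, 0)))
  out <- target
  out$gen_cm <- gen
  out$provenance <- ifelse(grid_in_masks(pos, masks), "imputed", "observed")
  out
}

#' Derive a recombination landscape from a Marey map
#'
#' The landscape is the derivative of the map: centered finite differences
#' on the grid interior, one-sided at the ends. Because the map is monotone,
#' the rate is nonnegative, and the trapezoidal integral of the rate exactly
#' reproduces the map's genetic span.
#'
#' @param map A `marey_map`.
#' @return A `recombination_landscape`: tibble `pos_mbp`,
#'   `rate_cm_per_mbp`, with attributes `chrom`, `chromosome_rate`
#'   (cM/Mbp) and `genetic_span` (cM).
#' @export
landscape_from_marey <- function(map) {
  pos <- map$pos_mbp
  g <- map$gen_cm
  n <- length(pos)
  stopifnot(n >= 3)
  if (any(diff(g) < -1e-9)) stop("Marey map must be monotone")
  rate <- numeric(n)
  rate[1] <- (g[2] - g[1]) / (pos[2] - pos[1])
  rate[n] <- (g[n] - g[n - 1]) / (pos[n] - pos[n - 1])
  rate[2:(n - 1)] <- (g[3:n] - g[1:(n - 2)]) / (pos[3:n] - pos[1:(n - 2)])
  rate <- pmax(rate, 0)
  span <- g[n] - g[1]
  structure(
    tibble::tibble(pos_mbp = pos, rate_cm_per_mbp = rate),
    chrom = attr(map, "chrom"),
    chromosome_rate = span / (pos[n] - pos[1]),
    genetic_span = span,
    normalized = FALSE,
    class = c("recombination_landscape", class(tibble::tibble()))
  )
}

#' Normalize a landscape by its chromosome-wide rate
#'
#' After normalization the mean local rate is 1 and the landscape integrates
#' to the chromosome's physical span, so comparisons focus on shape rather
#' than overall rate.
#'
#' @param ls A `recombination_landscape`.
#' @return The normalized landscape (chromosome rate attribute set to 1).
#' @export
normalize_landscape <- function(ls) {
  cr <- attr(ls, "chromosome_rate")
  if (is.null(cr) || cr <= 0) stop("chromosome rate must be positive")
  ls$rate_cm_per_mbp <- ls$rate_cm_per_mbp / cr
  attr(ls, "chromosome_rate") <- 1
  attr(ls, "genetic_span") <- attr(ls, "genetic_span") / cr
  attr(ls, "normalized") <- TRUE
  ls
}

#' Trapezoidal integral of a landscape
#'
#' @param ls A `recombination_landscape`.
#' @return The integral of the local rate over the grid (cM for an
#'   unnormalized landscape).
#' @export
landscape_integral <- function(ls) {
  r <- ls$rate_cm_per_mbp
  x <- ls$pos_mbp
  sum((r[-1] + r[-length(r)]) / 2 * diff(x))
}
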