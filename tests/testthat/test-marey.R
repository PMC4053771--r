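test_that("a linear Marey relation is reproduced without outlier removal", {
  bp <- seq(1e6, 100e6, length.out = 200)
  cm <- bp / 1e6 # 1 cM/Mbp
  map <- fit_bare_marey(bp, cm, grid_step = 1)
  expect_equal(nrow(attr(map, "outliers")), 0)
  expect_lt(max(abs(map$gen_cm - (map$pos_mbp - map$pos_mbp[1]))), 0.05)
  expect_true(all(diff(map$gen_cm) >= 0))
})

test_that("a gross outlier is rejected and the fit is unaffected", {
  bp <- seq(1e6, 100e6, length.out = 200)
  cm <- bp / 1e6
  cm[100] <- cm[100] + 50
  map <- fit_bare_marey(bp, cm, grid_step = 1)
  expect_gte(nrow(attr(map, "outliers")), 1)
  expect_lt(max(abs(map$gen_cm - (map$pos_mbp - map$pos_mbp[1]))), 0.5)
})

test_that("a noisy sigmoid curve is recovered within 2 cM", {
  set.seed(31)
  ch <- test_genome()[[1]]
  bp <- sort(runif(1000, 0, ch$physical_length)) * 1e6
  true_cm <- 100 * marey_fun_for_tests(ch)(bp / 1e6)
  map <- fit_bare_marey(bp, true_cm + rnorm(1000, 0, 0.5), grid_step = 1)
  anchor <- 100 * marey_fun_for_tests(ch)(map$pos_mbp[1] / 1)
  truth <- 100 * marey_fun_for_tests(ch)(map$pos_mbp) - anchor
  expect_lt(max(abs(map$gen_cm - truth)), 2)
})

test_that("degenerate Marey inputs are refused or degraded gracefully", {
  expect_error(fit_bare_marey(1:5 * 1e6, 1:5), "at least 10")
  expect_warning(map <- fit_bare_marey(seq(1e6, 5e7, length.out = 20),
                                       rep(3, 20)), "flat")
  expect_true(all(map$gen_cm == 0))
})

test_that("similarity track hits the trivial bounds and IBD segments", {
  markers <- tibble::tibble(marker = sprintf("m%04d", 1:300), chrom = "c1",
                            bp = seq(1e6, 300e6, by = 1e6))
  p1 <- rep(c("A", "B"), length.out = 300)
  tr_same <- similarity_track(p1, p1, markers)
  expect_true(all(tr_same$similarity == 1))
  p2 <- ifelse(p1 == "A", "B", "A")
  expect_true(all(similarity_track(p1, p2, markers)$similarity == 0))

  # IBD segment: identical alleles from 100 to 150 Mbp
  set.seed(32)
  p3 <- sample(c("A", "B"), 300, replace = TRUE)
  p4 <- sample(c("A", "B"), 300, replace = TRUE)
  ibd <- markers$bp / 1e6 >= 100 & markers$bp / 1e6 <= 150
  p4[ibd] <- p3[ibd]
  tr <- similarity_track(p3, p4, markers)
  inside <- tr$center_mbp >= 106 & tr$center_mbp <= 144
  expect_true(all(tr$similarity[inside] >= 0.99))
})

test_that("mask detection covers simulated IBD and honours user masks", {
  markers <- tibble::tibble(marker = sprintf("m%04d", 1:300), chrom = "c1",
                            bp = seq(1e6, 300e6, by = 1e6))
  set.seed(33)
  p1 <- sample(c("A", "B"), 300, replace = TRUE)
  p2 <- sample(c("A", "B"), 300, replace = TRUE)
  ibd <- markers$bp / 1e6 >= 40 & markers$bp / 1e6 <= 80
  p2[ibd] <- p1[ibd]
  tr <- similarity_track(p1, p2, markers)
  masks <- detect_masks(tr, markers)
  covered <- sum(pmin(masks$end_mbp, 80) - pmax(masks$start_mbp, 40))
  expect_gt(covered / 40, 0.95)

  # uniform 50% similarity with dense markers produces no masks
  p5 <- rep(c("A", "B"), length.out = 300)
  p6 <- rep(c("A", "A"), length.out = 300)
  expect_equal(nrow(detect_masks(similarity_track(p5, p6, markers), markers)), 0)

  user <- tibble::tibble(start_mbp = 10, end_mbp = 20)
  expect_equal(detect_masks(NULL, markers, user_masks = user),
               user)
})

test_that("landscapes integrate exactly to the map's genetic span", {
  bp <- seq(1e6, 200e6, length.out = 400)
  ch <- test_genome()[[2]]
  cm <- 100 * marey_fun_for_tests(ch)(bp / 1e6 * ch$physical_length / 200)
  map <- fit_bare_marey(bp, cm, grid_step = 0.5)
  ls <- landscape_from_marey(map)
  span <- max(map$gen_cm) - min(map$gen_cm)
  expect_lt(abs(landscape_integral(ls) - span) / span, 0.001)
  expect_true(all(ls$rate_cm_per_mbp >= 0))

  # linear map: constant landscape
  lin <- fit_bare_marey(seq(1e6, 100e6, length.out = 100),
                        seq(1e6, 100e6, length.out = 100) / 5e5,
                        grid_step = 1)
  lsl <- landscape_from_marey(lin)
  expect_lt(diff(range(lsl$rate_cm_per_mbp)), 0.05)
})

test_that("normalization rescales to unit mean and is scale invariant", {
  bp <- seq(1e6, 100e6, length.out = 200)
  cm <- (bp / 1e6)^2 / 100
  map <- fit_bare_marey(bp, cm, grid_step = 0.5)
  ls <- landscape_from_marey(map)
  nls <- normalize_landscape(ls)
  mean_rate <- landscape_integral(nls) /
    (max(nls$pos_mbp) - min(nls$pos_mbp))
  expect_equal(mean_rate, 1, tolerance = 1e-3)

  doubled <- map
  doubled$gen_cm <- 2 * doubled$gen_cm
  nls2 <- normalize_landscape(landscape_from_marey(doubled))
  expect_equal(nls$rate_cm_per_mbp, nls2$rate_cm_per_mbp, tolerance = 1e-12)
})

test_that("masking plus self-imputation is the identity", {
  bp <- seq(1e6, 150e6, length.out = 300)
  ch <- test_genome()[[1]]
  cm <- 100 * marey_fun_for_tests(ch)(bp / 1e6 * ch$physical_length / 150)
  map <- fit_bare_marey(bp, cm, grid_step = 0.5)
  masked <- set_masks(map, tibble::tibble(start_mbp = 40, end_mbp = 70))
  donor <- map # unmasked copy of itself
  imputed <- impute_masked(masked, list(donor))
  expect_lt(max(abs(imputed$gen_cm - map$gen_cm)), 1e-6)
  expect_true(any(imputed$provenance == "imputed"))
  expect_true(all(diff(imputed$gen_cm) >= -1e-12))

  # fully unmasked target passes through untouched
  expect_identical(impute_masked(map, list(donor)), map)
})

test_that("imputed increments are rescaled by the shared-support rate ratio", {
  grid <- seq(0, 100, by = 0.5)
  base <- tibble::tibble(pos_mbp = grid, gen_cm = grid, # 1 cM/Mbp
                         provenance = "observed")
  target <- dhrecomb:::new_marey_map(
    dplyr::mutate(base, gen_cm = 2 * gen_cm), "c1", 0.5
  ) # twice the donor's rate everywhere
  target <- set_masks(target, tibble::tibble(start_mbp = 30, end_mbp = 50))
  donor <- dhrecomb:::new_marey_map(base, "c1", 0.5)
  imputed <- impute_masked(target, list(donor))
  # imputed increments are 2x the donor's, so the map equals the original
  expect_lt(max(abs(imputed$gen_cm - 2 * grid)), 1e-9)
})

test_that("imputation without any donor coverage falls back with a warning", {
  grid <- seq(0, 100, by = 1)
  mk <- dhrecomb:::new_marey_map(
    tibble::tibble(pos_mbp = grid, gen_cm = grid, provenance = "observed"),
    "c1", 1
  )
  target <- set_masks(mk, tibble::tibble(start_mbp = 20, end_mbp = 40))
  donor <- set_masks(mk, tibble::tibble(start_mbp = 10, end_mbp = 50))
  expect_warning(out <- impute_masked(target, list(donor)), "no unmasked donor")
  expect_true(all(diff(out$gen_cm) >= 0))
})

test_that("fitted landscape correlates with the simulator's truth", {
  set.seed(34)
  pop <- clean_population(n_lines = 200, nu = 6, p = 0.1, per_mbp = 3.3,
                          seed = 35, genome = test_genome()[1])
  filtered <- filter_markers(pop$genotypes)
  gm <- build_genetic_map(filtered, pop$markers)
  map <- fit_bare_marey(gm$bp, gm$cm, grid_step = 1)
  ls <- landscape_from_marey(map)
  ch <- pop$genome[[1]]
  true_rate <- 100 * diff(marey_fun_for_tests(ch)(ls$pos_mbp)) /
    diff(ls$pos_mbp)
  mid_rate <- (ls$rate_cm_per_mbp[-1] + ls$rate_cm_per_mbp[-nrow(ls)]) / 2
  expect_gt(cor(mid_rate, true_rate), 0.95)
})
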