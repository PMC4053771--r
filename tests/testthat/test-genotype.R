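test_that("Haldane map function and its inverse are exact", {
  expect_equal(haldane_cm(0), 0)
  expect_equal(haldane_cm(0.25), -50 * log(0.5)) # 34.657 cM
  r <- seq(0, 0.49, by = 0.01)
  expect_equal(haldane_r(haldane_cm(r)), r, tolerance = 1e-12)
  expect_error(haldane_cm(0.5), "0.5")
  # large distances asymptote to r = 0.5
  expect_lt(0.5 - haldane_r(1e4), 1e-12)
})

test_that("marker filtering applies the MAF rule over informative calls", {
  geno <- matrix(NA_character_, 100, 4,
                 dimnames = list(NULL, paste0("m", 1:4)))
  geno[, 1] <- c(rep("A", 95), rep("B", 5))   # MAF 0.05 -> removed
  geno[, 2] <- c(rep("A", 50), rep("B", 50))  # MAF 0.5 -> kept
  geno[, 3] <- NA_character_                  # all missing -> removed
  geno[, 4] <- c(rep("A", 60), rep("H", 40))  # H set NA, MAF 0 -> removed
  out <- filter_markers(geno)
  expect_identical(colnames(out), "m2")
  expect_warning(filter_markers(geno[, 1, drop = FALSE]), "all markers")
})

test_that("crossover extraction finds switches and spans missing calls", {
  map <- tibble::tibble(marker = paste0("m", 1:4), chrom = "c1",
                        bp = c(10, 20, 30, 40) * 1e6, cm = c(0, 10, 20, 30))
  g <- matrix(c("A", "A", "B", "B"), 1, 4,
              dimnames = list("l1", map$marker))
  ev <- extract_crossovers(g, map, clean = FALSE)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$left_marker, "m2")
  expect_equal(ev$right_marker, "m3")
  expect_equal(ev$mid_cm, 15)

  g2 <- matrix(c("A", NA, "B", "B"), 1, 4, dimnames = list("l1", map$marker))
  ev2 <- extract_crossovers(g2, map, clean = FALSE)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$left_marker, "m1") # event spans the missing marker
  expect_equal(ev2$right_marker, "m3")

  g3 <- matrix(c("A", "B", "A", "A"), 1, 4, dimnames = list("l1", map$marker))
  expect_equal(nrow(extract_crossovers(g3, map, clean = FALSE)), 2)

  # a line with < 2 informative markers yields no events
  g4 <- matrix(c("A", NA, NA, NA), 1, 4, dimnames = list("l1", map$marker))
  expect_equal(nrow(extract_crossovers(g4, map, clean = FALSE)), 0)
})

test_that("double-recombinant cleaning removes isolated singletons", {
  map <- tibble::tibble(marker = paste0("m", 1:7), chrom = "c1",
                        bp = (1:7) * 1e6, cm = (0:6) * 0.5)
  calls <- c("A", "A", "A", "B", "A", "A", "A") # singleton within 1 cM flanks
  g <- matrix(calls, 1, 7, dimnames = list("l1", map$marker))
  expect_equal(nrow(extract_crossovers(g, map, clean = TRUE)), 0)
  expect_equal(nrow(extract_crossovers(g, map, clean = FALSE)), 2)
  # a genuine-looking double (flanks far apart) is retained
  map_far <- dplyr::mutate(map, cm = (0:6) * 10)
  g2 <- matrix(calls, 1, 7, dimnames = list("l1", map_far$marker))
  expect_equal(nrow(extract_crossovers(g2, map_far, clean = TRUE)), 2)

  # an error chain adjacent to a genuine crossover collapses to one event
  map9 <- tibble::tibble(marker = paste0("m", 1:9), chrom = "c1",
                         bp = (1:9) * 1e6, cm = (0:8) * 0.5)
  chain <- c("A", "A", "A", "B", "A", "B", "B", "B", "B")
  g3 <- matrix(chain, 1, 9, dimnames = list("l1", map9$marker))
  ev3 <- extract_crossovers(g3, map9, clean = TRUE)
  expect_equal(nrow(ev3), 1)
})

test_that("genetic map distances follow Haldane on pairwise-complete data", {
  markers <- tibble::tibble(marker = c("m1", "m2"), chrom = "c1",
                            bp = c(1e6, 2e6))
  g <- matrix("A", 100, 2, dimnames = list(NULL, markers$marker))
  g[1:25, 2] <- "B" # 25 recombinants of 100
  map <- build_genetic_map(g, markers)
  expect_equal(max(map$cm), -50 * log(0.5), tolerance = 1e-9)

  g0 <- matrix("A", 50, 2, dimnames = list(NULL, markers$marker))
  g0[1:25, ] <- "B" # perfectly correlated: zero recombinants
  expect_equal(max(build_genetic_map(g0, markers)$cm), 0)

  g5 <- matrix("A", 10, 2, dimnames = list(NULL, markers$marker))
  g5[1:6, 2] <- "B" # r = 0.6 under noise: capped with a warning
  expect_warning(m5 <- build_genetic_map(g5, markers), "capped")
  expect_equal(max(m5$cm), haldane_cm(0.499))
})

test_that("map length is recovered on simulated data", {
  pop <- clean_population(n_lines = 200, nu = 6, p = 0.1, seed = 21)
  filtered <- filter_markers(pop$genotypes)
  map <- build_genetic_map(filtered, pop$markers)
  true_cm <- 100 * sum(vapply(pop$genome, function(ch) ch$genetic_length,
                              numeric(1)))
  est <- map_lengths(map)
  est_cm <- est$length_cm[est$chrom == "genome"]
  # Haldane on interfering data is mildly biased; 10% brackets it comfortably
  expect_lt(abs(est_cm - true_cm) / true_cm, 0.10)
})

test_that("two-pass error cleaning deflates the map back to the truth", {
  genome <- test_genome()[1]
  design <- population_design(150, uniform_markers(genome, 1),
                              missing_rate = 0.02, error_rate = 0.002,
                              seed = 24)
  pop <- simulate_population(genome, meiosis_params(6, 0.1), design)
  filtered <- filter_markers(pop$genotypes)
  raw_map <- build_genetic_map(filtered, pop$markers)
  cleaned <- clean_genotype_errors(filtered, raw_map)
  clean_map <- build_genetic_map(cleaned, pop$markers)
  true_cm <- 100 * pop$genome[[1]]$genetic_length
  raw_len <- max(raw_map$cm)
  clean_len <- max(clean_map$cm)
  expect_gt(raw_len, 1.2 * true_cm) # errors inflate Haldane accumulation
  expect_lt(abs(clean_len - true_cm) / true_cm, 0.08)
})

test_that("crossover counts are conserved and recall is high on clean data", {
  pop <- clean_population(n_lines = 120, nu = 6, p = 0.1, seed = 22)
  filtered <- filter_markers(pop$genotypes)
  map <- build_genetic_map(filtered, pop$markers)
  ev <- extract_crossovers(filtered, map, clean = FALSE)
  counts <- crossover_counts(ev, rownames(filtered), unique(map$chrom))
  expect_equal(sum(counts$n_co), nrow(ev))

  # recall against the simulator's truth at 1 marker/Mbp, restricted to the
  # observable region (crossovers beyond the terminal markers cannot be seen)
  truth <- pop$truth
  span <- lapply(pop$genome, function(ch) {
    bp <- pop$markers$bp[pop$markers$chrom == ch$name]
    marey_fun_for_tests(ch)(range(bp) / 1e6)
  })
  inside <- mapply(function(ch, pos) {
    pos >= span[[ch]][1] & pos <= span[[ch]][2]
  }, truth$chrom, truth$pos_morgan)
  truth <- truth[inside, ]
  recovered <- 0
  for (i in seq_len(nrow(truth))) {
    pos_mbp <- marey_inv_for_test(pop$genome[[truth$chrom[i]]])(truth$pos_morgan[i])
    hit <- ev$line == truth$line[i] & ev$chrom == truth$chrom[i] &
      ev$left_bp / 1e6 <= pos_mbp & ev$right_bp / 1e6 >= pos_mbp
    recovered <- recovered + as.integer(any(hit))
  }
  expect_gt(recovered / nrow(truth), 0.99)

  # every event lies within its chromosome's marker span
  for (ch in unique(ev$chrom)) {
    mk <- pop$markers[pop$markers$chrom == ch, ]
    sub <- ev[ev$chrom == ch, ]
    expect_true(all(sub$left_bp >= min(mk$bp) & sub$right_bp <= max(mk$bp)))
  }
})

test_that("empty event sets tally to zero and summaries divide correctly", {
  empty <- extract_crossovers(
    matrix("A", 2, 2, dimnames = list(c("a", "b"), c("m1", "m2"))),
    tibble::tibble(marker = c("m1", "m2"), chrom = "c1",
                   bp = c(1e6, 2e6), cm = c(0, 1)),
    clean = FALSE
  )
  counts <- crossover_counts(empty, c("a", "b"), "c1")
  expect_true(all(counts$n_co == 0))
  expect_equal(co_count_summary(counts)$mean_per_line, 0)
})

test_that("distortion profile uses the exact normal band", {
  geno <- matrix(rep(c("A", "B"), each = 50), 100, 1,
                 dimnames = list(NULL, "m1"))
  markers <- tibble::tibble(marker = "m1", chrom = "c1", bp = 1e6)
  prof <- distortion_profile(geno, markers, alpha = 0.01)
  expect_equal(prof$lower, 0.5 - qnorm(0.995) * 0.05, tolerance = 1e-12)
  expect_equal(prof$upper, 0.5 + qnorm(0.995) * 0.05, tolerance = 1e-12)
  expect_false(prof$distorted) # frequency exactly 0.5 is never flagged

  # type-I calibration: balanced markers flag at about the nominal 1%
  set.seed(23)
  g <- matrix(sample(c("A", "B"), 200 * 2000, replace = TRUE), 200, 2000,
              dimnames = list(NULL, sprintf("m%04d", 1:2000)))
  mk <- tibble::tibble(marker = colnames(g), chrom = "c1",
                       bp = seq_len(2000) * 1e5)
  rate <- mean(distortion_profile(g, mk, alpha = 0.01)$distorted)
  expect_lt(abs(rate - 0.01), 0.01)
})

test_that("genotype TSV round-trips, including the numeric dialect", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  g <- matrix(c("A", "B", NA, "A"), 2, 2,
              dimnames = list(c("l1", "l2"), c("m1", "m2")))
  write_genotypes(g, tmp)
  expect_identical(read_genotypes(tmp), g)

  tmp2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("line\tm1\tm2", "l1\t0\t1", "l2\t2\t-"), tmp2)
  g2 <- read_genotypes(tmp2)
  expect_identical(g2["l1", ], c(m1 = "A", m2 = "H"))
  expect_identical(g2["l2", ], c(m1 = "B", m2 = NA_character_))
})
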