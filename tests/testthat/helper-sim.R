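# Small synthetic setups shared across tests.

# two-chromosome genome scaled down from the default for fast simulation
test_genome <- function(rate = 0.73) {
  default_genome(rate)[1:2]
}

# simulate a small clean population (no observation noise)
clean_population <- function(n_lines = 100, nu = 6, p = 0.1, per_mbp = 1,
                             seed = 1, genome = test_genome()) {
  design <- population_design(
    n_lines = n_lines,
    marker_positions = uniform_markers(genome, per_mbp),
    missing_rate = 0, error_rate = 0, seed = seed
  )
  simulate_population(genome, meiosis_params(nu, p), design)
}

# gamete tibble for interference fitting from raw simulated gametes
gamete_tibble <- function(cos, L, chrom = "c1") {
  tibble::tibble(
    line = sprintf("L%05d", seq_along(cos)),
    chrom = chrom, L = L, positions = cos
  )
}

# marey_map-like tibble from a chromosome model's true curve
true_marey_tibble <- function(chrom, step = 1) {
  grid <- seq(0, chrom$physical_length, by = step)
  tibble::tibble(
    pos_mbp = grid,
    gen_cm = 100 * marey_fun_for_tests(chrom)(grid)
  )
}

marey_fun_for_tests <- function(chrom) {
  stats::approxfun(chrom$curve$pos_mbp, chrom$curve$gen_morgan, rule = 2)
}

# Morgan -> Mbp inverse of a model curve
marey_inv_for_test <- function(chrom) {
  stats::approxfun(chrom$curve$gen_morgan, chrom$curve$pos_mbp, rule = 2)
}
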