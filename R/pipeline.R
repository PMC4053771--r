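#' Configuration of an end-to-end synthetic run
#'
#' Collects every documented constant of the pipeline with its default, so a
#' run is fully described by its config (echoed to disk with every run).
#'
#' @param seed Integer seed for the whole run.
#' @param n_lines DH lines to simulate.
#' @param n_chrom Number of chromosomes of the synthetic genome (<= 10).
#' @param rate_cm_per_mbp Genome-wide rate of the synthetic genome.
#' @param nu,p Interference parameters of the simulated meiosis.
#' @param markers_per_mbp Marker density.
#' @param missing_rate,error_rate Observation-noise rates.
#' @param min_maf Marker filtering threshold.
#' @param clean_window_cm Double-recombinant cleaning window.
#' @param grid_step_mbp Marey grid step.
#' @param n_bins Equal-genetic-length bins for landscape comparison.
#' @param alpha Distortion-band significance level.
#' @param run_interference Toggle the (slower) interference stage.
#' @return A validated list of class `run_config`.
#' @export
pipeline_config <- function(seed = 1L, n_lines = 100, n_chrom = 10,
                            rate_cm_per_mbp = 0.73, nu = 5, p = 0.1,
                            markers_per_mbp = 1,
                            missing_rate = 0.02, error_rate = 0.002,
                            min_maf = 0.1, clean_window_cm = 10,
                            grid_step_mbp = 0.5, n_bins = 10, alpha = 0.01,
                            run_interference = TRUE) {
  cfg <- as.list(environment())
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_lines < 1) stop("n_lines must be positive")
  if (n_chrom < 1 || n_chrom > 10) stop("n_chrom must be in 1..10")
  if (nu < 1 || p < 0 || p > 0.5) stop("invalid interference parameters")
  if (grid_step_mbp <= 0 || n_bins < 2) stop("invalid grid/bin settings")
  structure(cfg, class = "run_config")
}

#' Run the full synthetic analysis pipeline
#'
#' Executes simulate -> filter -> extract -> map -> marey -> landscape
#' statistics -> interference in order, writing each stage's tables, a
#' config echo, and a run manifest (versions, seed, config hash, per-stage
#' row counts) into `out_dir`. A stage failure is recorded in the manifest
#' and downstream stages are skipped. Reruns with the same config are
#' bit-identical for the deterministic stages.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("dhrecomb")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    stages = list()
  )
  completed <- TRUE
  stage <- function(name, expr) {
    if (!completed) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(NULL)
    }
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       message = conditionMessage(res))
      completed <<- FALSE
      NULL
    } else {
      manifest$stages[[name]] <<- list(status = "ok", rows = res$rows)
      res$value
    }
  }

  sim <- stage("simulate", {
    genome <- default_genome(config$rate_cm_per_mbp)[seq_len(config$n_chrom)]
    design <- population_design(
      n_lines = config$n_lines,
      marker_positions = uniform_markers(genome, config$markers_per_mbp),
      missing_rate = config$missing_rate, error_rate = config$error_rate,
      seed = config$seed
    )
    s <- simulate_population(genome, meiosis_params(config$nu, config$p), design)
    write_genotypes(s$genotypes, file.path(out_dir, "genotypes.tsv"))
    write_marker_table(s$markers, file.path(out_dir, "markers.tsv"))
    readr::write_tsv(s$truth, file.path(out_dir, "truth.tsv"))
    list(value = s, rows = nrow(s$truth))
  })

  filtered <- stage("filter", {
    g <- filter_markers(sim$genotypes, config$min_maf)
    list(value = g, rows = ncol(g))
  })

  gmap <- stage("map", {
    # iterated two-pass: provisional map, error cleaning against it, rebuild;
    # repeated because cleaning deflates the map, tightening the window
    m <- build_genetic_map(filtered, sim$markers)
    for (pass in 1:3) {
      cleaned <- clean_genotype_errors(filtered, m, config$clean_window_cm)
      if (identical(cleaned, filtered)) break
      filtered <- cleaned
      m <- build_genetic_map(filtered, sim$markers)
    }
    readr::write_tsv(m, file.path(out_dir, "genetic_map.tsv"))
    readr::write_tsv(map_lengths(m), file.path(out_dir, "map_lengths.tsv"))
    list(value = m, rows = nrow(m))
  })

  events <- stage("extract", {
    ev <- extract_crossovers(filtered, gmap, clean = TRUE,
                             clean_window_cm = config$clean_window_cm)
    readr::write_tsv(ev, file.path(out_dir, "crossovers.tsv"))
    counts <- crossover_counts(ev, rownames(filtered),
                               unique(sim$markers$chrom))
    readr::write_tsv(counts, file.path(out_dir, "crossover_counts.tsv"))
    prof <- distortion_profile(filtered, sim$markers, config$alpha)
    readr::write_tsv(prof, file.path(out_dir, "distortion.tsv"))
    list(value = ev, rows = nrow(ev))
  })

  mareys <- stage("marey", {
    maps <- lapply(split(gmap, gmap$chrom), function(mk) {
      fit_bare_marey(mk$bp, mk$cm, chrom = mk$chrom[1],
                     grid_step = config$grid_step_mbp)
    })
    all_maps <- dplyr::bind_rows(lapply(maps, function(m) {
      df <- tibble::as_tibble(m)
      df$chrom <- attr(m, "chrom")
      df
    }))
    readr::write_tsv(all_maps, file.path(out_dir, "marey_maps.tsv"))
    list(value = maps, rows = nrow(all_maps))
  })

  stats_out <- stage("stats", {
    summ <- rate_summary(mareys, n_lines = config$n_lines, population = "sim")
    readr::write_tsv(summ, file.path(out_dir, "rate_summary.tsv"))
    landscapes <- dplyr::bind_rows(lapply(mareys, function(m) {
      ls <- landscape_from_marey(m)
      df <- tibble::as_tibble(ls)
      df$chrom <- attr(ls, "chrom")
      df
    }))
    readr::write_tsv(landscapes, file.path(out_dir, "landscapes.tsv"))
    list(value = summ, rows = nrow(summ))
  })

  stage("interference", {
    if (!config$run_interference) {
      list(value = NULL, rows = 0)
    } else {
      lens <- map_lengths(gmap)
      lens <- lens[lens$chrom != "genome", ]
      gam <- gamete_co_sets(
        dplyr::transmute(events, line = .data$line, chrom = .data$chrom,
                         pos_morgan = .data$mid_cm / 100),
        tibble::tibble(chrom = lens$chrom, L_morgan = lens$length_cm / 100),
        rownames(filtered)
      )
      fit <- fit_gamma_sprinkle(gam)
      jsonlite::write_json(
        list(nu = fit$nu, p = fit$p, loglik = fit$loglik,
             var_nu = fit$var_nu, var_p = fit$var_p,
             n_gametes = fit$n_gametes, convergence = fit$convergence,
             boundary = fit$boundary),
        file.path(out_dir, "interference_fit.json"),
        auto_unbox = TRUE, digits = NA
      )
      list(value = fit, rows = nrow(gam))
    }
  })

  manifest$completed <- completed
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Summarise a completed run directory
#'
#' Writes a population-summary table (lengths, rates, line numbers, fitted
#' interference parameters where available) assembled from the stage
#' outputs of [run_pipeline()]. Missing stages are marked.
#'
#' @param out_dir A run directory.
#' @return The report tibble, invisibly; written to `report.tsv`.
#' @export
write_report <- function(out_dir) {
  manifest_path <- file.path(out_dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    report <- tibble::tibble(section = "run", status = "no stages completed")
    readr::write_tsv(report, file.path(out_dir, "report.tsv"))
    return(invisible(report))
  }
  manifest <- jsonlite::read_json(manifest_path)
  sections <- list()
  rs_path <- file.path(out_dir, "rate_summary.tsv")
  if (file.exists(rs_path)) {
    rs <- readr::read_tsv(rs_path, col_types = readr::cols())
    gen <- rs[rs$scope == "genome", ]
    sections$rates <- tibble::tibble(
      section = "rates",
      population = gen$population,
      length_cm = gen$genetic_length_cm,
      gwrr = gen$rate_cm_per_mbp,
      n_lines = gen$n_lines
    )
  } else {
    sections$rates <- tibble::tibble(section = "rates", status = "missing")
  }
  fit_path <- file.path(out_dir, "interference_fit.json")
  if (file.exists(fit_path)) {
    fit <- jsonlite::read_json(fit_path)
    sections$interference <- tibble::tibble(
      section = "interference", nu = fit$nu, p = fit$p,
      loglik = fit$loglik, n_gametes = fit$n_gametes
    )
  } else {
    sections$interference <- tibble::tibble(section = "interference",
                                            status = "missing")
  }
  report <- dplyr::bind_rows(sections)
  readr::write_tsv(report, file.path(out_dir, "report.tsv"))
  invisible(report)
}
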