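log_stage <- function(stage, msg, level = "INFO") {
  message(sprintf("[%s] %s %s: %s",
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"), level, stage, msg))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  path
}

#' Run the full analysis pipeline
#'
#' Executes load/simulate, QC filtering, deduplication, gamete inference,
#' inheritance estimation, segregation testing, recombination profiling,
#' linkage mapping and neighbor-joining clustering, writing every table to
#' \code{out_dir} plus a JSON summary.  Deterministic given the seed.
#'
#' @param config either a path to a JSON file or a list with entries:
#'   \code{simulate} (logical); when simulating, \code{sim} (list of
#'   \code{\link{giant_key_config}} overrides: \code{n_gametes},
#'   \code{mode}, \code{missing_rate}); otherwise \code{dose_path} and
#'   \code{markers_path}; optional \code{max_marker_missing},
#'   \code{max_sample_missing} (default 0.10 each), \code{lod_threshold}
#'   (default 5), \code{run_map} (default \code{TRUE}).
#' @param out_dir output directory (created if absent).
#' @param seed integer seed overriding the config's.
#' @return invisibly, a list with every intermediate result and the
#'   summary.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- jsonlite::read_json(config,
                                                          simplifyVector = TRUE)
  stage <- "config"
  result <- tryCatch({
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    simulate <- isTRUE(config$simulate)
    seed <- as.integer(if (!is.null(seed)) seed
                       else if (!is.null(config$seed)) config$seed else 1L)

    stage <- "load"
    if (simulate) {
      sim <- config$sim
      cfg <- giant_key_config(
        n_gametes = if (!is.null(sim$n_gametes)) sim$n_gametes else 269,
        seed = seed,
        mode = if (!is.null(sim$mode)) sim$mode else "locus_wise",
        missing_rate = if (!is.null(sim$missing_rate)) sim$missing_rate
                       else 0.02)
      g_true <- simulate_gametes(cfg)
      m <- make_triploid_doses(g_true)
      log_stage(stage, sprintf("simulated %d gametes x %d markers",
                               nrow(m$dose), ncol(m$dose)))
    } else {
      if (is.null(config$dose_path) || is.null(config$markers_path))
        stop("config must give dose_path and markers_path when simulate is false")
      m <- read_dose_matrix(config$dose_path, config$markers_path)
      log_stage(stage, sprintf("read %d samples x %d markers",
                               nrow(m$dose), ncol(m$dose)))
    }

    stage <- "filter"
    thr_m <- if (!is.null(config$max_marker_missing))
      config$max_marker_missing else 0.10
    thr_s <- if (!is.null(config$max_sample_missing))
      config$max_sample_missing else 0.10
    flt <- filter_matrix(m, thr_m, thr_s)
    log_stage(stage, sprintf("%d markers, %d samples removed",
                             nrow(flt$qc$removed_markers),
                             nrow(flt$qc$removed_samples)))

    stage <- "dedupe"
    dd <- dedupe(flt$matrix)
    m_clean <- dd$matrix
    log_stage(stage, sprintf("%d duplicate markers, %d duplicate samples",
                             nrow(dd$qc$removed_markers),
                             nrow(dd$qc$removed_samples)))

    stage <- "infer"
    g <- doses_to_gametes(m_clean)
    write_dose_matrix(m_clean, file.path(out_dir, "dose_matrix.tsv"),
                      file.path(out_dir, "markers.tsv"))

    stage <- "inherit"
    mt <- marker_table(g)
    est <- estimate_chromosome(g, on_missing_centromere = "skip")
    phr <- phr_summary(g)
    write_tsv(mt, file.path(out_dir, "marker_table.tsv"))
    write_tsv(est, file.path(out_dir, "inheritance.tsv"))
    write_tsv(phr$per_chromosome, file.path(out_dir, "phr_chromosome.tsv"))
    log_stage(stage, sprintf("genome PHR %.3f", phr$genome$phr_mean))

    stage <- "segtest"
    seg <- distortion_table(g)
    write_tsv(seg$per_marker, file.path(out_dir, "distortion_markers.tsv"))
    write_tsv(seg$per_chromosome,
              file.path(out_dir, "distortion_chromosomes.tsv"))

    stage <- "recomb"
    comp <- genome_composition(g)
    runs <- graphical_genotypes(g)
    write_tsv(comp$per_gamete, file.path(out_dir, "gamete_composition.tsv"))
    write_tsv(comp$crossover_dist,
              file.path(out_dir, "crossover_distribution.tsv"))
    write_tsv(runs, file.path(out_dir, "graphical_genotypes.tsv"))
    log_stage(stage, sprintf("mean crossovers per gamete %.2f",
                             comp$mean_crossovers))

    stage <- "map"
    gm <- NULL
    marey <- NULL
    if (!isFALSE(config$run_map)) {
      lod_thr <- if (!is.null(config$lod_threshold)) config$lod_threshold
                 else 5
      gm <- build_map(g, lod_threshold = lod_thr)
      marey <- marey_diagnostics(gm)
      write_tsv(gm$map, file.path(out_dir, "genetic_map.tsv"))
      write_tsv(gm$lengths, file.path(out_dir, "map_lengths.tsv"))
      write_tsv(gm$pairwise, file.path(out_dir, "pairwise_linkage.tsv"))
      write_tsv(marey$per_lg, file.path(out_dir, "marey.tsv"))
      log_stage(stage, sprintf("%d LGs, %.1f cM, synteny %.1f%%",
                               nrow(gm$lengths), sum(gm$lengths$length_cM),
                               marey$synteny_pct))
    }

    stage <- "nj"
    nj <- NULL
    if (nrow(m_clean$dose) >= 3) {
      nj <- nj_tree(euclidean_distances(m_clean))
      write_newick(nj, file.path(out_dir, "gametes_nj.nwk"))
    }

    stage <- "summary"
    summary <- list(
      seed = seed,
      n_samples = nrow(m_clean$dose), n_markers = ncol(m_clean$dose),
      qc = list(markers_removed_missing = nrow(flt$qc$removed_markers),
                samples_removed_missing = nrow(flt$qc$removed_samples),
                markers_removed_duplicate = nrow(dd$qc$removed_markers),
                samples_removed_duplicate = nrow(dd$qc$removed_samples),
                max_marker_missing = thr_m, max_sample_missing = thr_s),
      genome_phr = phr$genome$phr_mean,
      inheritance = est,
      composition = as.list(comp$composition),
      mean_crossovers = comp$mean_crossovers,
      map = if (!is.null(gm)) list(
        n_lg = nrow(gm$lengths),
        total_cM = sum(gm$lengths$length_cM),
        synteny_pct = marey$synteny_pct) else NULL)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE,
                         dataframe = "rows")
    invisible(list(dose = m_clean, gametes = g, qc_filter = flt$qc,
                   qc_dedupe = dd$qc, marker_table = mt,
                   inheritance = est, phr = phr, distortion = seg,
                   composition = comp, runs = runs, map = gm,
                   marey = marey, nj = nj, summary = summary))
  }, error = function(e) {
    log_stage(stage, conditionMessage(e), level = "ERROR")
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  result
}
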