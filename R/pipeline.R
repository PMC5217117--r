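# End-to-end orchestration: simulate/load -> assign -> traits -> gwas ->
# fine-map -> compete, with a reproducible manifest.

#' Build a run configuration
#'
#' Either `world` (arguments for [world_config()]; the run simulates its
#' inputs) or `inputs` (named paths: `records`, `stations`, `observations`,
#' `genotypes`, optionally `annotations`, `kinship_genotypes`) must be
#' given. A YAML file with the same structure can be loaded via
#' [read_run_config()].
#'
#' @param world list of [world_config()] arguments, or `NULL`.
#' @param inputs named list of input paths, or `NULL`.
#' @param windows analysis windows to run.
#' @param traits trait prefixes to map (matched as `<prefix>_<window>`
#'   columns of the trait table), e.g. `"temp_mean"`.
#' @param alpha family-wise error rate.
#' @param min_maf MAF threshold for tested markers.
#' @param coverage_threshold trait-coverage threshold.
#' @param merge_radius QTL merge radius (markers).
#' @param fine_map_top_fraction candidate-gene shortlist fraction.
#' @param competition_counts optional path to a ddPCR count CSV.
#' @param seed run seed (also seeds the simulated world unless it sets its
#'   own).
#' @param out_dir output directory.
#' @return list of class `run_config`.
#' @export
run_config <- function(world = NULL, inputs = NULL,
                       windows = c("three_year"),
                       traits = c("temp_mean"),
                       alpha = 0.05, min_maf = 0.05,
                       coverage_threshold = 0.90, merge_radius = 50L,
                       fine_map_top_fraction = 0.05,
                       competition_counts = NULL, seed = 1L,
                       out_dir = tempfile("nichemap_run_")) {
  stopifnot(alpha > 0, alpha < 1)
  if (is.null(world) && is.null(inputs))
    stop("either 'world' or 'inputs' is required")
  if (!is.null(inputs)) {
    need <- c("records", "stations", "observations", "genotypes")
    miss <- setdiff(need, names(inputs))
    if (length(miss)) stop("missing inputs: ", paste(miss, collapse = ", "))
    bad <- !vapply(unlist(inputs), file.exists, logical(1))
    if (any(bad)) stop("input path(s) do not exist: ",
                       paste(unlist(inputs)[bad], collapse = ", "))
  }
  windows <- match.arg(windows, c("three_month", "one_year", "three_year"),
                       several.ok = TRUE)
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file mirroring [run_config()] arguments.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

.log_line <- function(log, ...) {
  msg <- sprintf(...)
  cat(msg, "\n", sep = "", file = log, append = TRUE)
  message(msg)
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> station assignment -> trait tables ->
#' kinship-corrected mapping -> QTL fine mapping -> competition fitness for
#' every requested window and trait, writing per-stage TSV outputs, a log
#' with dropped-strain warnings, and a JSON manifest with md5 digests of
#' every output. Identical config + seed reproduces identical digests.
#'
#' @param config a [run_config()].
#' @return invisibly, the manifest list.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(config$out_dir, "run.log")
  cat("", file = log)
  outputs <- character()
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    outputs <<- c(outputs, path)
    path
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  # --- inputs ---------------------------------------------------------
  if (!is.null(config$world)) {
    .log_line(log, "stage simulate: generating synthetic world")
    world <- stage("simulate", {
      wc_args <- config$world
      wc_args$seed <- wc_args$seed %||% config$seed
      wc <- do.call(world_config, wc_args)
      generate_world(wc)
    })
    records <- world$records; stations <- world$stations
    obs <- harmonize_units(world$obs)
    genotypes <- world$genotypes
    annotations <- world$annotations
    kinship_G <- genotypes
    elev_provider <- synthetic_elevation_provider(world)
  } else {
    .log_line(log, "stage load: reading inputs")
    world <- NULL
    records <- stage("load", read_isolation_records(config$inputs$records))
    stations <- stage("load", read_stations(config$inputs$stations))
    obs <- stage("load",
                 harmonize_units(read_observations(config$inputs$observations)))
    gp <- config$inputs$genotypes
    genotypes <- stage("load", if (grepl("\\.vcf$", gp))
      read_genotypes_vcf(gp) else read_genotypes_tsv(gp))
    annotations <- if (!is.null(config$inputs$annotations))
      read.delim(config$inputs$annotations) else NULL
    kinship_G <- if (!is.null(config$inputs$kinship_genotypes)) {
      kp <- config$inputs$kinship_genotypes
      if (grepl("\\.vcf$", kp)) read_genotypes_vcf(kp)
      else read_genotypes_tsv(kp)
    } else genotypes
    elev_provider <- station_elevation_provider(stations)
  }
  K <- kinship(kinship_G)
  # --- traits + mapping ----------------------------------------------
  scans <- list()
  for (win in config$windows) {
    .log_line(log, "stage traits: window %s", win)
    tab <- stage("traits", withCallingHandlers(
      build_trait_table(records, stations, obs, window = win,
                        elevation_provider = elev_provider,
                        coverage_threshold = config$coverage_threshold),
      warning = function(w) {
        .log_line(log, "  warning: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      }))
    emit(data.frame(strain = rownames(tab), tab, check.names = FALSE),
         sprintf("traits_%s.tsv", win))
    emit(attr(tab, "assignment"), sprintf("assignment_%s.tsv", win))
    for (tr in config$traits) {
      cn <- paste(tr, win, sep = "_")
      if (!cn %in% names(tab)) {
        .log_line(log, "  trait %s absent after coverage filter; skipped", cn)
        next
      }
      .log_line(log, "stage gwas: %s", cn)
      y <- setNames(tab[[cn]], rownames(tab))
      scan <- stage("gwas",
        gwas_scan(y, genotypes, K = K, min_maf = config$min_maf,
                  alpha = config$alpha,
                  merge_radius = config$merge_radius))
      scans[[cn]] <- scan
      emit(scan$mapping, sprintf("mapping_%s.tsv", cn))
      qtl <- scan$qtl
      if (nrow(qtl)) {
        splits <- do.call(rbind, lapply(seq_len(nrow(qtl)), function(i) {
          s <- split_by_peak_genotype(scan$y, scan$G[, qtl$peak_marker[i]])
          cbind(peak_marker = qtl$peak_marker[i], s)
        }))
        emit(splits, sprintf("peak_splits_%s.tsv", cn))
      }
      emit(qtl, sprintf("qtl_%s.tsv", cn))
      if (nrow(qtl) && !is.null(annotations)) {
        .log_line(log, "stage finemap: %s (%d QTL)", cn, nrow(qtl))
        for (i in seq_len(nrow(qtl))) {
          vars <- select_interval_variants(annotations, qtl[i, ])
          if (!nrow(vars)) next
          rk <- stage("finemap", spearman_fine_map(y, genotypes, vars))
          emit(rk$variants, sprintf("finemap_%s_%s.tsv", cn,
                                    qtl$peak_marker[i]))
          emit(data.frame(gene = candidate_genes(
                 rk, top_fraction = config$fine_map_top_fraction)),
               sprintf("candidates_%s_%s.tsv", cn, qtl$peak_marker[i]))
        }
      }
    }
  }
  # --- competition ----------------------------------------------------
  comp <- NULL
  if (!is.null(config$competition_counts)) {
    .log_line(log, "stage compete: %s", config$competition_counts)
    comp <- stage("compete",
      competition_fit(read_competition_counts(config$competition_counts)))
    emit(comp$estimates, "fitness.tsv")
    emit(comp$trajectory, "trajectory.tsv")
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("nichemap")),
    seed = config$seed, windows = config$windows, traits = config$traits,
    n_qtl = sum(vapply(scans, function(s) nrow(s$qtl), integer(1))),
    outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                               basename(outputs))))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  .log_line(log, "done: %d QTL across %d scans", manifest$n_qtl,
            length(scans))
  invisible(list(manifest = manifest, scans = scans, competition = comp,
                 world = world, out_dir = config$out_dir))
}
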