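#' Run the full free-energy-landscape analysis pipeline
#'
#' Orchestrates the analysis stages end to end: read replica CV tables and
#' bias grids, assign post-equilibration frames to microstates,
#' reconstruct microstate free energies by WHAM, estimate block-analysis
#' errors, slice the landscape, compute per-microstate and ensemble
#' averages of the requested observables (columns of the CV tables), and
#' optionally evaluate two-state thermal stability curves. Results are
#' written as TSV files plus a JSON run manifest; given the same inputs
#' and seed the outputs are byte-identical.
#'
#' @param config A configuration list, or path to a YAML/JSON file, with
#'   fields:
#'   \describe{
#'     \item{replicas}{list of entries with `id`, `biased_cv`, `cv_table`
#'       (COLVAR path) and `bias_grid` (two-column grid path).}
#'     \item{binning}{list with `cvs`, `widths`, optional `ranges`,
#'       `t_eq`.}
#'     \item{kT}{thermal energy, kJ/mol (default 2.9).}
#'     \item{slice_width}{free-energy slice width, kJ/mol (default 6).}
#'     \item{observables}{CV-table columns to average (default: the
#'       binning CVs).}
#'     \item{thermo}{optional path to a two-state YAML config (see
#'       [read_two_state_config()]).}
#'     \item{outdir}{output directory.}
#'     \item{seed}{integer recorded in the manifest and used for any
#'       randomized stage.}
#'   }
#' @return Invisibly, a list with the `fes`, `slices`, paths of all
#'   written files, and the manifest.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  need <- setdiff(c("replicas", "binning", "outdir"), names(config))
  if (length(need))
    stop("pipeline config is missing field(s): ", paste(need, collapse = ", "))
  kT <- if (is.null(config$kT)) 2.9 else config$kT
  slice_width <- if (is.null(config$slice_width)) 6 else config$slice_width
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  set.seed(seed)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  stage <- "read_replicas"
  runs <- tryCatch(
    lapply(config$replicas, function(rr) {
      for (f in c("cv_table", "bias_grid"))
        if (is.null(rr[[f]]) || !file.exists(rr[[f]]))
          stop("replica ", rr$id, ": missing ", f,
               if (!is.null(rr[[f]])) paste0(" file '", rr[[f]], "'"))
      replica_run(id = rr$id, biased_cv = rr$biased_cv,
                  cv_table = read_colvar(rr$cv_table),
                  bias_grid = read_bias_grid(rr$bias_grid))
    }),
    error = function(e) stop("pipeline stage '", stage, "': ",
                             conditionMessage(e), call. = FALSE))

  bn <- config$binning
  spec <- binning_spec(cvs = bn$cvs, widths = bn$widths,
                       ranges = bn$ranges,
                       t_eq = if (is.null(bn$t_eq)) 0 else bn$t_eq)
  run_stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  occ <- run_stage("assign_microstates", assign_microstates(runs, spec))
  fes <- run_stage("reconstruct_fes", reconstruct_fes(occ, runs, spec, kT = kT))
  fes$microstates$error <-
    run_stage("estimate_errors", estimate_errors(occ, runs, spec, kT = kT))
  slices <- run_stage("slice_landscape", slice_landscape(fes, slice_width))

  obs_names <- if (is.null(config$observables)) spec$cvs else config$observables
  obs_ms <- run_stage("observables", {
    vals <- lapply(occ$frames, function(f) as.matrix(f[, obs_names, drop = FALSE]))
    microstate_observable(occ, vals)
  })
  ens <- ensemble_average(fes, obs_ms, T = kT / .R_GAS)

  paths <- list()
  tsv <- function(df, name) {
    p <- file.path(config$outdir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[name]] <<- p
    p
  }
  tsv(cbind(fes$microstates,
            stats::setNames(as.data.frame(obs_ms), paste0("mean_", obs_names))),
      "microstates.tsv")
  tsv(data.frame(observable = obs_names, ensemble_mean = as.numeric(ens)),
      "ensemble_averages.tsv")
  slice_df <- do.call(rbind, lapply(slices$slices, function(s) {
    w <- .slice_weights(fes, s$members, "boltzmann")
    means <- colSums(w * obs_ms[s$members, , drop = FALSE])
    cbind(data.frame(slice_lo = s$lo, slice_hi = s$hi,
                     n_microstates = length(s$members),
                     n_frames = sum(fes$microstates$n[s$members])),
          stats::setNames(as.data.frame(t(means)), paste0("mean_", obs_names)))
  }))
  tsv(slice_df, "slices.tsv")

  if (!is.null(config$thermo)) {
    ts <- run_stage("thermo", read_two_state_config(config$thermo))
    curves <- population_curves(ts$models)
    tsv(curves, "thermo_curves.tsv")
    if (!is.null(ts$rg_unstructured) &&
        all(vapply(ts$models, function(m) !is.null(m$rg), logical(1))))
      tsv(mixture_rg(ts$models, ts$rg_unstructured), "mixture_rg.tsv")
  }

  min_bin <- which.min(fes$microstates$F)
  manifest <- list(
    package = "idpfel",
    version = as.character(utils::packageVersion("idpfel")),
    seed = seed,
    parameters = list(kT = kT, slice_width = slice_width,
                      binning = list(cvs = spec$cvs, widths = spec$widths,
                                     t_eq = spec$t_eq)),
    n_replicas = length(runs),
    frames_retained = occ$n_retained,
    frames_dropped_out_of_range = occ$dropped,
    wham = list(converged = TRUE, iterations = fes$iterations,
                residual = fes$residual),
    min_microstate = as.list(fes$microstates[min_bin,
      c("id", grep("^center_", names(fes$microstates), value = TRUE))]),
    outputs = names(paths))
  mp <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  paths[["manifest.json"]] <- mp

  invisible(list(fes = fes, slices = slices, ensemble = ens,
                 paths = paths, manifest = manifest))
}
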