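#' @importFrom utils packageVersion write.table
NULL

.defaultConfig <- function() list(
  seed = 1L,
  sample_times = defaultSampleTimes(),
  n_cells_per_time = 200L,
  chain = list(nA = 7L, nB = 18L, q = 1 / 5.3, qb = 0),
  emission = list(p_on = 0.95, p_off = 0.10),
  states = list(k = 3L, n_boot = 1000L, n_refs = 50L),
  fit = list(lambda = 1e-4, use_lcurve = FALSE),
  bulk = list(n_genes = 1000L, n_deg = 100L, effect_size = 4),
  network = list(retention = 0.05, p0 = 0.05, enabled = TRUE),
  classifier = list(n_profiles = 10L, n_genes = 200L, fraction = 0.05),
  stages = c("simulate", "states", "fit", "variability", "network",
             "preprocess", "classify"))

.validateConfig <- function(config) {
  def <- .defaultConfig()
  bad <- setdiff(names(config), names(def))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (nm in names(config)) {
    if (is.list(def[[nm]]) && !is.null(names(def[[nm]]))) {
      badSub <- setdiff(names(config[[nm]]), names(def[[nm]]))
      if (length(badSub))
        stop("unknown config key(s) under '", nm, "': ",
             paste(badSub, collapse = ", "))
      def[[nm]][names(config[[nm]])] <- config[[nm]]
    } else {
      def[[nm]] <- config[[nm]]
    }
  }
  def
}

# stage seed fan-out: one master seed, offset by a stage-name hash so no two
# stages share a stream
.stageSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  (as.integer(seed) * 1009L + h) %% 2147483562L
}

#' Run the end-to-end analysis pipeline
#'
#' Orchestrates simulate, state calling, model fitting, variability,
#' network inference, bulk preprocessing and lineage classification on
#' synthetic data, in dependency order, with one master seed fanned out per
#' stage. All tabular outputs are written as TSV (fit results and the run
#' manifest as JSON) and checksummed in the manifest.
#'
#' @param config named list overriding the defaults (see the `statefate`
#'   vignette), or a path to a YAML file of the same shape. Unknown keys
#'   raise an error naming the key.
#' @param out_dir output directory (created if needed).
#' @return list with `manifest` (also written to `manifest.json`) and the
#'   in-memory stage results.
#' @export
runPipeline <- function(config = list(), out_dir = tempfile("statefate_run_")) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  cfg <- .validateConfig(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- proc.time()[["elapsed"]]
  outputs <- character(0)
  timings <- list()
  seeds <- list()
  results <- list(config = cfg)
  stage <- function(name, fun) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    t0 <- proc.time()[["elapsed"]]
    seeds[[name]] <<- .stageSeed(cfg$seed, name)
    results[[name]] <<- fun(seeds[[name]])
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
  }
  emit <- function(path) { outputs <<- c(outputs, path); path }

  chain <- ChainParams(cfg$chain$nA, cfg$chain$nB,
                       N = if (is.null(cfg$chain$N)) cfg$chain$nB + 1
                       else cfg$chain$N,
                       q = cfg$chain$q, qb = cfg$chain$qb)

  stage("simulate", function(s) {
    traj <- simulateChainCells(chain, cfg$sample_times,
                               cfg$n_cells_per_time, seed = s)
    se <- emitExpression(
      traj, defaultEmissionModel(cfg$emission$p_on, cfg$emission$p_off),
      seed = s + 1L)
    writeCellsTsv(se, emit(file.path(out_dir, "cells.tsv")))
    se
  })

  stage("states", function(s) {
    se <- results$simulate
    if (is.null(se)) stop("states stage needs the simulate stage output; ",
                          "run the 'simulate' stage first")
    call <- callStates(se, k = cfg$states$k, seed = s,
                       n_refs = cfg$states$n_refs)
    props <- macrostateProportions(
      call$macrostate, SummarizedExperiment::colData(se)$time_h,
      n_boot = cfg$states$n_boot, seed = s + 1L)
    df <- data.frame(cell_id = SummarizedExperiment::colData(se)$cell_id,
                     time_h = SummarizedExperiment::colData(se)$time_h,
                     cluster = call$cluster, macrostate = call$macrostate)
    write.table(df, emit(file.path(out_dir, "states.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(trajAsDataFrame(props),
                emit(file.path(out_dir, "proportions.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(call = call, proportions = props)
  })

  stage("fit", function(s) {
    props <- results$states$proportions
    if (is.null(props)) stop("fit stage needs the states stage output; ",
                             "run the 'states' stage first")
    fit <- if (isTRUE(cfg$fit$use_lcurve)) {
      sel <- selectLambdaLcurve(props)
      sel$fit
    } else fitChain(props, lambda = cfg$fit$lambda)
    jsonlite::write_json(
      list(model = fit@model, par = fit@par, rss = fit@objective,
           lambda = fit@lambda, seed = s),
      emit(file.path(out_dir, "fit.json")), auto_unbox = TRUE, digits = NA)
    fit
  })

  stage("variability", function(s) {
    se <- results$simulate
    disp <- dispersionByTime(se)
    ent <- entropyByTime(se)
    write.table(disp, emit(file.path(out_dir, "dispersion.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(gene = rownames(ent$entropy), ent$entropy,
                           check.names = FALSE),
                emit(file.path(out_dir, "entropy.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(dispersion = disp, entropy = ent)
  })

  stage("network", function(s) {
    se <- results$simulate
    net <- inferNetwork(se, retention = cfg$network$retention,
                        p0 = cfg$network$p0)
    writeNetworkTsv(net, emit(file.path(out_dir, "network_edges.tsv")))
    write.table(nodeMetrics(net),
                emit(file.path(out_dir, "node_metrics.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    net
  })

  stage("preprocess", function(s) {
    bulk <- synthBulkTimecourse(cfg$bulk$n_genes, cfg$bulk$n_deg,
                                cfg$bulk$effect_size, cfg$sample_times,
                                seed = s)
    cre <- computeCre(bulk$mat)
    degs <- callDegs(cre)
    write.table(degs, emit(file.path(out_dir, "degs.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(bulk = bulk, cre = cre, degs = degs)
  })

  stage("classify", function(s) {
    lib <- synthReferenceLibrary(cfg$classifier$n_profiles,
                                 cfg$classifier$n_genes, seed = s)
    scores <- scoreLibrary(matrix(lib$test, dimnames = list(names(lib$test),
                                                            "t168")),
                           lib$baseline, lib$profiles,
                           fraction = cfg$classifier$fraction)
    write.table(data.frame(profile = rownames(scores), scores,
                           check.names = FALSE),
                emit(file.path(out_dir, "scores.tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(library = lib, scores = scores)
  })

  manifest <- list(
    package_version = as.character(packageVersion("statefate")),
    seed = cfg$seed,
    stage_seeds = seeds,
    config = cfg,
    timings_s = timings,
    total_s = round(proc.time()[["elapsed"]] - t_start, 3),
    outputs = lapply(setNames(outputs, basename(outputs)), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  results$out_dir <- out_dir
  invisible(results)
}
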