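#' Pipeline configuration
#'
#' Describes one end-to-end analysis: either a synthetic dataset (via a
#' [synthetic_config()]) or user-supplied files (`regions.csv`,
#' `strata.csv`, and `edges.csv` or a GeoJSON polygon file), the covariates
#' to model, optional log transforms, the VIF threshold, and the MCMC
#' profile.
#'
#' @param synthetic a [synthetic_config()], or `NULL` when reading files.
#' @param regions_file,strata_file,edges_file,polygons_file input paths
#'   (exactly one of `edges_file`/`polygons_file` when not synthetic);
#'   `polygons_id_field` names the GeoJSON id property.
#' @param polygons_id_field id property for [graph_from_polygons()].
#' @param covariates covariate names to model; `NULL` means every
#'   non-id/non-count column of the regions table.
#' @param log_transform covariate names to log-transform before modelling
#'   (for heavily skewed variables such as population density).
#' @param vif_threshold VIF cutoff for [screen_covariates()].
#' @param protected covariates exempt from VIF removal.
#' @param mcmc an [mcmc_config()] (default desk profile).
#' @param n_permutations permutations for the Moran's I test.
#' @param outdir output directory; `NULL` disables file output.
#' @param seed root seed for every stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = NULL,
                            regions_file = NULL, strata_file = NULL,
                            edges_file = NULL, polygons_file = NULL,
                            polygons_id_field = "id",
                            covariates = NULL, log_transform = character(),
                            vif_threshold = 2.5, protected = character(),
                            mcmc = mcmc_config(profile = "desk"),
                            n_permutations = 999,
                            outdir = NULL, seed = 1L) {
  from_files <- !is.null(regions_file)
  if (is.null(synthetic) == !from_files) {
    stop("exactly one of `synthetic` or input files must be given")
  }
  if (from_files) {
    if (is.null(strata_file)) stop("strata_file is required with regions_file")
    if (is.null(edges_file) == is.null(polygons_file)) {
      stop("exactly one of edges_file or polygons_file is required")
    }
  } else if (!inherits(synthetic, "synthetic_config")) {
    stop("`synthetic` must be a synthetic_config")
  }
  structure(list(synthetic = synthetic, regions_file = regions_file,
                 strata_file = strata_file, edges_file = edges_file,
                 polygons_file = polygons_file,
                 polygons_id_field = polygons_id_field,
                 covariates = covariates, log_transform = log_transform,
                 vif_threshold = vif_threshold, protected = protected,
                 mcmc = mcmc, n_permutations = n_permutations,
                 outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Load or generate data; indirectly standardize (national stratum rates,
#' expected deaths, SMR); test the SMR for spatial autocorrelation with
#' Moran's I; apply log transforms and the VIF screen; fit the Leroux CAR
#' model; check Geweke diagnostics (warn when any `|z| >= 1.96`); fit the
#' non-spatial baseline; compare by WAIC. When `outdir` is set, writes
#' `smr.csv`, `moran.json`, `screening.json`, `summary.csv` (RR-scale
#' rows: intercept, covariates, rho), `diagnostics.json`,
#' `comparison.csv`, per-variable choropleth CSVs (`choropleth_*.csv`,
#' columns `region_id`, `value`), and `manifest.json`. On failure, partial
#' outputs stay in place and a `FAILED` marker names the failing stage.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result`: `smr`, `moran`, `screening`,
#'   `fit`, `summary`, `geweke`, `fit_nonspatial`, `waic`
#'   (a [compare_waic()] result), plus the `graph`, modelling `dataset`,
#'   and (for synthetic runs) the `truth` record.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    unlink(file.path(outdir, "FAILED"))
  }
  on_fail <- function(e) {
    if (!is.null(outdir)) writeLines(conditionMessage(e),
                                     file.path(outdir, "FAILED"))
    stop(e)
  }
  tryCatch(run_pipeline_impl(config, outdir), error = on_fail)
}

run_pipeline_impl <- function(config, outdir) {
  truth <- NULL
  if (!is.null(config$synthetic)) {
    sim <- stage("generate", {
      sc <- config$synthetic
      sc$seed <- substream_seed(config$seed, "synthetic")
      generate_dataset(sc)
    })
    graph <- sim$graph; counts <- sim$counts; regions <- sim$regions
    truth <- sim$truth
    if (!is.null(outdir)) write_dataset(sim, file.path(outdir, "data"))
  } else {
    regions <- stage("load", read.csv(config$regions_file,
                                      stringsAsFactors = FALSE))
    graph <- stage("load", {
      if (!is.null(config$edges_file)) {
        graph_from_edge_csv(config$edges_file,
                            region_ids = as.character(regions$region_id))
      } else {
        graph_from_polygons(config$polygons_file, config$polygons_id_field)
      }
    })
    counts <- stage("load", stratified_counts(
      read.csv(config$strata_file, stringsAsFactors = FALSE),
      region_ids = graph$region_ids))
  }

  covariates <- config$covariates
  if (is.null(covariates)) {
    covariates <- setdiff(names(regions), c("region_id", "observed"))
  }
  unknown <- setdiff(c(covariates, config$log_transform), names(regions))
  if (length(unknown)) {
    stop("pipeline stage 'config' failed: unknown covariate(s): ",
         paste(unknown, collapse = ", "))
  }

  smr_tab <- stage("standardize", smr(counts))
  if (!identical(smr_tab$region_id, graph$region_ids)) {
    stop("pipeline stage 'standardize' failed: region order mismatch")
  }

  moran <- stage("moran", morans_i_test(
    graph, smr_tab$smr, n_permutations = config$n_permutations,
    seed = substream_seed(config$seed, "moran")))

  design <- regions[, covariates, drop = FALSE]
  for (v in intersect(config$log_transform, covariates)) {
    if (any(design[[v]] <= 0)) {
      stop("pipeline stage 'transform' failed: non-positive values in log(",
           v, ")")
    }
    design[[v]] <- log(design[[v]])
    names(design)[names(design) == v] <- paste0("log_", v)
  }

  screening <- stage("screen", screen_covariates(
    design, threshold = config$vif_threshold, protected = config$protected))

  dataset <- stage("assemble", region_dataset(
    cbind(region_id = regions$region_id, screening$design),
    covariates = names(screening$design),
    observed = smr_tab$observed, expected = smr_tab$expected))

  mcfg <- config$mcmc
  mcfg$seed <- substream_seed(config$seed, "mcmc")
  fit <- stage("fit", fit_leroux(dataset, graph, mcfg))
  summ <- stage("summarize", summarize_fit(fit))
  gz <- stage("geweke", geweke_all(fit))
  if (any(abs(gz) >= 1.96)) {
    warning("absolute value of Geweke's diagnostic >= 1.96 for: ",
            paste(names(gz)[abs(gz) >= 1.96], collapse = ", "),
            " - chains may not have converged", call. = FALSE)
  }

  mcfg_ns <- config$mcmc
  mcfg_ns$seed <- substream_seed(config$seed, "mcmc_nonspatial")
  fit_ns <- stage("fit_nonspatial", fit_nonspatial(dataset, mcfg_ns))
  cmp <- stage("waic", compare_waic(fit, fit_ns))

  result <- structure(list(
    smr = smr_tab, moran = moran, screening = screening,
    fit = fit, summary = summ, geweke = gz,
    fit_nonspatial = fit_ns, waic = cmp,
    graph = graph, dataset = dataset, truth = truth,
    config = config
  ), class = "pipeline_result")

  if (!is.null(outdir)) {
    stage("write", write_pipeline_outputs(result, regions, covariates, outdir))
  }
  result
}

write_pipeline_outputs <- function(result, regions, covariates, outdir) {
  write.csv(result$smr, file.path(outdir, "smr.csv"), row.names = FALSE)
  m <- result$moran
  jsonlite::write_json(
    list(I = m$I, expected_I = m$expected_I, p_value = m$p_value,
         n_permutations = m$n_permutations, method = m$method),
    file.path(outdir, "moran.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(threshold = result$screening$threshold,
         removed = result$screening$removed,
         vif = as.list(result$screening$vif)),
    file.path(outdir, "screening.json"), auto_unbox = TRUE, digits = NA)
  summ <- result$summary
  out <- data.frame(Parameter = summ$parameter, Median = summ$median,
                    `2.50%` = summ$lower, `97.50%` = summ$upper,
                    check.names = FALSE)
  write.csv(out, file.path(outdir, "summary.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(geweke_z = as.list(result$geweke),
         accept = result$fit$accept,
         converged = all(abs(result$geweke) < 1.96)),
    file.path(outdir, "diagnostics.json"), auto_unbox = TRUE, digits = NA)
  write.csv(result$waic$table, file.path(outdir, "comparison.csv"),
            row.names = FALSE)
  # choropleth-ready region,value tables: SMR and each modelled covariate
  chor <- c(list(smr = result$smr$smr),
            stats::setNames(lapply(covariates, function(v) regions[[v]]),
                            covariates))
  for (nm in names(chor)) {
    write.csv(data.frame(region_id = result$smr$region_id,
                         value = chor[[nm]]),
              file.path(outdir, paste0("choropleth_", nm, ".csv")),
              row.names = FALSE)
  }
  cfg <- result$config
  manifest <- list(
    seed = cfg$seed,
    synthetic = !is.null(cfg$synthetic),
    covariates = covariates,
    log_transform = cfg$log_transform,
    vif_threshold = cfg$vif_threshold,
    mcmc = unclass(cfg$mcmc),
    package_version = as.character(utils::packageVersion("lerouxmap")),
    r_version = R.version.string
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result:", length(x$graph$region_ids), "regions\n")
  cat(sprintf("  mean SMR %.3f; Moran's I %.3f (p = %.3g)\n",
              mean(x$smr$smr, na.rm = TRUE), x$moran$I, x$moran$p_value))
  cat(sprintf("  WAIC spatial %.1f vs nonspatial %.1f (better: %s)\n",
              x$waic$table$waic[1], x$waic$table$waic[2], x$waic$better))
  invisible(x)
}
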