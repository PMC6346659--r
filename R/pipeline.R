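#' Pipeline configuration defaults
#'
#' @param ... Overrides for any field: `simulate` (list passed to
#'   [simulate_experiment()]; set to `NULL` and supply `input` to read
#'   data instead), `input` (`list(path, format)`), `fitness`
#'   (`"uncond_height"` or `"survival"`), `window` (`"from_2009"` or
#'   `"from_2010"`), `stratify_by`, `traits`, `factors`, `random`,
#'   `alpha`, `grid_size`, `surface_pair`, `out_dir`, `seed`.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  base <- list(
    simulate = list(experiment = 1),
    input = NULL,
    fitness = "uncond_height",
    window = "from_2009",
    stratify_by = "treatment",
    traits = c("seed_density", "emergence_day"),
    factors = character(0),
    random = NULL,
    alpha = 0.05,
    grid_size = 25,
    surface_pair = NULL,
    out_dir = tempfile("asterchain_run_"),
    seed = 1L
  )
  cfg <- utils::modifyList(base, list(...), keep.null = TRUE)
  if (!cfg$fitness %in% c("uncond_height", "survival")) {
    stop("fitness must be 'uncond_height' or 'survival'")
  }
  if (!cfg$window %in% c("from_2009", "from_2010")) {
    stop("window must be 'from_2009' or 'from_2010'")
  }
  if (is.null(cfg$simulate) && is.null(cfg$input)) {
    stop("config needs either a simulate block or an input block")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

graph_for <- function(fitness, window) {
  lh_graph(switch(paste(fitness, window),
                  "survival from_2009" = "a",
                  "survival from_2010" = "b",
                  "uncond_height from_2009" = "c",
                  "uncond_height from_2010" = "d"))
}

#' Run the full selection-analysis pipeline
#'
#' Simulates (or reads) a common-garden dataset, validates it, subsets
#' the analysis window, screens trait correlations per stratum, runs the
#' forward-stepwise gradient selection per stratum, evaluates a fitness
#' surface and classifies the selection form per trait, and writes every
#' artifact (dataset CSVs, truth JSON, per-stratum model-comparison
#' ledgers, surface grids, classification summaries) plus a manifest
#' with MD5 checksums to the output directory.  Deterministic under a
#' fixed config seed.
#'
#' @param config A [pipeline_config()] (or a YAML path understood by
#'   [read_pipeline_config()]).
#' @return The manifest, invisibly (list with `files`, `config`,
#'   `counts`, `strata`, `warnings`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logged <- character(0)
  manifest <- list(config = unclass(config), files = character(0),
                   warnings = character(0), stage = NULL)
  persist <- function() {
    mpath <- file.path(out_dir, "manifest.json")
    manifest$checksums <- as.list(tools::md5sum(
      file.path(out_dir, manifest$files)))
    names(manifest$checksums) <- manifest$files
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    mpath
  }
  run_stage <- function(name, expr) {
    manifest$stage <<- name
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        manifest$warnings <<- c(manifest$warnings,
                                paste0("ERROR in stage ", name, ": ",
                                       conditionMessage(e)))
        persist()
        stop("pipeline stage '", name, "' failed: ",
             conditionMessage(e), call. = FALSE)
      }),
      warning = function(w) {
        manifest$warnings <<- c(manifest$warnings,
                                paste0(name, ": ", conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
  }

  set.seed(config$seed)
  truth <- NULL
  sim <- NULL
  data <- run_stage("load", {
    if (!is.null(config$simulate)) {
      sim <- do.call(simulate_experiment, config$simulate)
      truth <- sim$truth
      paths <- export_dataset(sim$data, out_dir)
      manifest$files <- c(manifest$files, basename(paths))
      export_truth(truth, file.path(out_dir, "truth.json"))
      manifest$files <- c(manifest$files, "truth.json")
      manifest$counts <- sim$counts
      sim$data
    } else {
      read_records(config$input$path,
                   config$input$format %||% "wide")
    }
  })

  graph <- graph_for(config$fitness, config$window)
  run_stage("validate", {
    v <- validate_records(data, graph)
    if (v$n_violations > 0) {
      stop("input data fail validation (", v$n_violations,
           " violations)")
    }
  })
  data <- run_stage("window", subset_cohort(data, config$window))

  traits <- config$traits
  screen <- run_stage("screen", {
    s <- screen_traits(data, traits, strata = config$stratify_by,
                       alive = graph_terminal_surv(graph))
    df <- do.call(rbind, lapply(names(s$strata), function(nm) {
      r <- s$strata[[nm]]$r
      cbind(data.frame(stratum = nm, trait = rownames(r)),
            as.data.frame(r))
    }))
    utils::write.csv(df, file.path(out_dir, "trait_screen.csv"),
                     row.names = FALSE)
    manifest$files <- c(manifest$files, "trait_screen.csv")
    s
  })

  key <- if (is.null(config$stratify_by)) rep("all", nrow(data)) else
    interaction(data[config$stratify_by], drop = TRUE, sep = ":")
  strata_out <- list()
  for (stratum in levels(factor(key))) {
    sd_ <- data[key == stratum, , drop = FALSE]
    res <- run_stage(paste0("stepwise:", stratum), {
      d <- standardize_traits(sd_, traits)
      cand <- candidate_terms(
        traits, factors = config$factors, screen = screen,
        stratum = if (is.null(config$stratify_by)) NULL else stratum)
      sw <- forward_stepwise(d, graph, cand, alpha = config$alpha,
                             random = config$random)
      lg <- sw$ledger
      names(lg) <- c("Step", "Terms", "Action", "Model df",
                     "Model deviance", "Test df", "Test p-value")
      f <- paste0("ledger_", gsub("[^A-Za-z0-9_.-]", "_", stratum),
                  ".csv")
      utils::write.csv(lg, file.path(out_dir, f), row.names = FALSE)
      manifest$files <- c(manifest$files, f)
      list(stepwise = sw, data = d)
    })
    sw <- res$stepwise
    pair <- config$surface_pair %||% traits[1:2]
    if (length(pair) == 2L &&
        any(grepl(paste0("z_", pair[1L]), sw$retained, fixed = TRUE)) &&
        any(grepl(paste0("z_", pair[2L]), sw$retained, fixed = TRUE))) {
      run_stage(paste0("surface:", stratum), {
        fs <- fitness_surface(sw, pair[1L], pair[2L], data = res$data,
                              grid_size = config$grid_size)
        stem <- paste0("surface_", gsub("[^A-Za-z0-9_.-]", "_", stratum))
        utils::write.csv(as.data.frame(fs$z),
                         file.path(out_dir, paste0(stem, ".csv")),
                         row.names = FALSE)
        utils::write.csv(data.frame(axis = c(rep("x", length(fs$x)),
                                             rep("y", length(fs$y))),
                                    trait = c(rep(fs$trait_x,
                                                  length(fs$x)),
                                              rep(fs$trait_y,
                                                  length(fs$y))),
                                    value = c(fs$x, fs$y)),
                         file.path(out_dir, paste0(stem, "_axes.csv")),
                         row.names = FALSE)
        manifest$files <- c(manifest$files, paste0(stem, ".csv"),
                            paste0(stem, "_axes.csv"))
      })
    }
    cls <- run_stage(paste0("classify:", stratum), {
      lapply(traits, function(t) {
        sf <- classify_selection(sw, t, data = res$data)
        list(trait = t, classification = sf$classification,
             optimum = sf$optimum)
      })
    })
    strata_out[[stratum]] <- list(
      retained = sw$retained,
      classification = cls,
      gradients = selection_gradients(sw))
    f <- paste0("classification_",
                gsub("[^A-Za-z0-9_.-]", "_", stratum), ".json")
    jsonlite::write_json(cls, file.path(out_dir, f), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    manifest$files <- c(manifest$files, f)
  }

  if (!is.null(truth)) {
    run_stage("truth_report", {
      rep_ <- lapply(names(strata_out), function(nm) {
        g <- strata_out[[nm]]$gradients
        list(stratum = nm, retained = strata_out[[nm]]$retained,
             gradients = g,
             truth_surv1 = truth$surv1[c("beta_emergence",
                                         "gamma_emergence",
                                         "beta_density",
                                         "gamma_density")])
      })
      jsonlite::write_json(rep_, file.path(out_dir,
                                           "truth_vs_estimate.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           force = TRUE)
      manifest$files <- c(manifest$files, "truth_vs_estimate.json")
    })
  }
  manifest$stage <- "done"
  manifest$strata <- lapply(strata_out, function(s)
    list(retained = s$retained,
         classification = s$classification))
  persist()
  manifest$files <- c(manifest$files, "manifest.json")
  invisible(manifest)
}

#' Serialize a fit or test result to CSV and JSON
#'
#' Writes the coefficient table (block, term, estimate, SE) as CSV and
#' a JSON summary (log-likelihood, deviance, df, dispersion, variance
#' components, convergence flags) so fits can be archived or consumed
#' outside R.
#'
#' @param fit An [asterchain()] fit or an [aster_lrt()] result.
#' @param dir Output directory (created if needed).
#' @param name File stem.
#' @return Invisibly, the paths written.
#' @export
export_fit <- function(fit, dir, name = "fit") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  json <- file.path(dir, paste0(name, ".json"))
  if (inherits(fit, "aster_lrt")) {
    jsonlite::write_json(unclass(fit), json, auto_unbox = TRUE,
                         digits = NA)
    return(invisible(c(json = json)))
  }
  stopifnot(inherits(fit, "asterchain"))
  csv <- file.path(dir, paste0(name, "_coefficients.csv"))
  cf <- data.frame(
    block = c(rep("surv", length(fit$coefficients$surv)),
              rep("height", length(fit$coefficients$height))),
    term = c(names(fit$coefficients$surv),
             names(fit$coefficients$height)),
    estimate = c(fit$coefficients$surv, fit$coefficients$height),
    se = c(fit$se$surv, fit$se$height),
    row.names = NULL)
  utils::write.csv(cf, csv, row.names = FALSE, na = "")
  jsonlite::write_json(
    list(loglik = fit$loglik, deviance = fit$deviance, df = fit$df,
         n = fit$n, sigma2 = fit$sigma2, converged = fit$converged,
         flags = fit$flags, random = fit$random,
         graph = fit$graph$id),
    json, auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(c(csv = csv, json = json))
}
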