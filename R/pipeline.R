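#' Default cost/benefit directions for the 18 indicators
#'
#' Range standardization needs a declared direction per indicator: whether
#' larger raw values support ("benefit") or erode ("cost") psychological
#' tolerance. No canonical assignment exists for this evaluation system,
#' so this mapping is the package's documented convention: haze burden
#' (air quality as PM2.5, pollution days), crowding (population density),
#' heavy-industry share, the volume of haze posts and the coupling of
#' post volume to pollution are costs; everything else — milder weather,
#' wealth, infrastructure, green space, education, mean sentiment and the
#' (signed) sentiment-pollution correlation — is a benefit.
#'
#' @return named character vector over [panel_indicators()], values
#'   `"benefit"` / `"cost"`.
#' @export
default_directions <- function() {
  dirs <- stats::setNames(rep("benefit", 18), panel_indicators())
  dirs[c("air_quality", "pollution_days", "population_density",
         "secondary_industry_share", "n_microblogs", "corr_number")] <- "cost"
  dirs
}

#' Pipeline run configuration
#'
#' @param sim a [sim_config()] describing the synthetic study (ignored at
#'   the simulate stage if `bundle` is supplied to [run_pipeline()]).
#' @param stages character vector of enabled stages, a subset of
#'   `c("simulate", "sentiment", "indicators", "weights", "tolerance",
#'   "trajectory")`.
#' @param alpha naive-Bayes smoothing pseudo-count.
#' @param n_classes tolerance classes for binning (>= 2).
#' @param directions indicator direction map (see [default_directions()]).
#' @param out_dir optional directory; when set, every stage writes its
#'   outputs there (CSV / JSON-lines) and the manifest records their
#'   MD5 hashes.
#' @return a `run_config` list.
#' @export
run_config <- function(sim = sim_config(),
                       stages = c("simulate", "sentiment", "indicators",
                                  "weights", "tolerance", "trajectory"),
                       alpha = 1,
                       n_classes = 5,
                       directions = default_directions(),
                       out_dir = NULL) {
  all_stages <- c("simulate", "sentiment", "indicators", "weights",
                  "tolerance", "trajectory")
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) stop("unknown stages: ", paste(bad, collapse = ", "))
  if (n_classes < 2) stop("n_classes must be at least 2")
  structure(
    list(sim = sim, stages = stages, alpha = alpha, n_classes = n_classes,
         directions = directions, out_dir = out_dir),
    class = "run_config"
  )
}

# stage -> stages whose outputs it consumes
stage_dependencies <- list(
  simulate = character(0),
  sentiment = "simulate",
  indicators = c("simulate", "sentiment"),
  weights = "simulate",
  tolerance = c("simulate", "sentiment"),
  trajectory = c("simulate", "sentiment", "tolerance")
)

#' Run the full analysis pipeline on a synthetic bundle
#'
#' Executes the enabled stages in dependency order: simulate the bundle;
#' train and apply the sentiment model; compute the social-media
#' indicators; derive AHP, entropy and combined weights and the composite
#' score z per region-year; compute the tolerance index T and its 5-class
#' reclassification per region-season; and code the per-region class
#' trajectories. All randomness flows from the single seed in the sim
#' config. Disabling a stage another enabled stage depends on is an error
#' naming the missing dependency. When `out_dir` is set, outputs are
#' written as they are produced and the manifest records their MD5
#' hashes, so two runs with identical config and seed yield identical
#' hashes.
#'
#' @param config a [run_config()].
#' @param bundle optional pre-generated `syn_bundle`; when supplied, the
#'   simulate stage reuses it instead of regenerating.
#' @return list of stage results (`bundle`, `model`, `scored`,
#'   `aggregates`, `indicators`, `weights`, `composite`, `tolerance`,
#'   `trajectory`) plus `manifest`, a tibble of per-stage parameters,
#'   outputs and hashes.
#' @export
run_pipeline <- function(config = run_config(), bundle = NULL) {
  stopifnot(inherits(config, "run_config"))
  stages <- config$stages
  for (s in stages) {
    miss <- setdiff(stage_dependencies[[s]], stages)
    if (length(miss) > 0) {
      stop("stage '", s, "' needs output of disabled stage(s): ",
           paste(miss, collapse = ", "))
    }
  }
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  res <- list()
  manifest <- list()
  note <- function(stage, params, files) {
    hashes <- if (length(files) > 0) unname(tools::md5sum(files)) else character(0)
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = stage,
      params = as.character(jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA)),
      outputs = paste(basename(files), collapse = ";"),
      md5 = paste(hashes, collapse = ";"),
      elapsed_s = as.numeric(Sys.time()) - t0
    )
  }
  emit_csv <- function(df, name) {
    if (is.null(out_dir)) return(character(0))
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, fileEncoding = "UTF-8")
    p
  }
  t0 <- as.numeric(Sys.time())

  if ("simulate" %in% stages) {
    res$bundle <- bundle %||% simulate_bundle(config$sim)
    files <- character(0)
    if (!is.null(out_dir)) {
      files <- c(
        emit_csv(res$bundle$pm25, "pm25.csv"),
        emit_csv(res$bundle$panel, "panel.csv"),
        emit_csv(res$bundle$class_raster, "class_raster.csv"),
        {
          p <- file.path(out_dir, "corpus.jsonl")
          write_corpus_jsonl(res$bundle$corpus, p)
          p
        }
      )
    }
    note("simulate", list(seed = config$sim$seed,
                          n_regions = length(config$sim$regions),
                          years = range(config$sim$years)), files)
  }

  if ("sentiment" %in% stages) {
    res$model <- nb_train(res$bundle$train_corpus, alpha = config$alpha)
    sc <- score_corpus(res$model, res$bundle$corpus)
    res$scored <- sc$corpus
    res$aggregates <- sc$aggregates
    note("sentiment", list(alpha = config$alpha,
                           n_train = nrow(res$bundle$train_corpus)),
         emit_csv(res$aggregates, "sentiment_aggregates.csv"))
  }

  if ("indicators" %in% stages) {
    res$indicators <- compute_indicators(res$scored, res$bundle$pm25)
    note("indicators", list(), emit_csv(res$indicators, "indicators.csv"))
  }

  if ("weights" %in% stages) {
    Y <- standardize_panel(res$bundle$panel, config$directions)
    wt <- weight_table(load_judgment_matrices(), Y)
    res$weights <- wt
    w <- stats::setNames(wt$table$combined, wt$table$indicator)
    res$composite <- composite_score(w, Y,
                                     ids = res$bundle$panel[, c("region", "year")])
    note("weights", list(directions = unname(config$directions)),
         c(emit_csv(wt$table, "weights.csv"),
           emit_csv(res$composite, "composite.csv")))
  }

  if ("tolerance" %in% stages) {
    pm_means <- dplyr::summarise(
      dplyr::group_by(res$bundle$pm25, .data$region, .data$season),
      CPM25 = mean(.data$concentration), .groups = "drop"
    )
    res$tolerance <- tolerance_panel(res$aggregates, pm_means,
                                     n_classes = config$n_classes)
    note("tolerance", list(n_classes = config$n_classes),
         emit_csv(res$tolerance, "tolerance.csv"))
  }

  if ("trajectory" %in% stages) {
    states <- tibble::tibble(
      unit_id = res$tolerance$region,
      period = res$tolerance$season,
      state = res$tolerance$class
    )
    res$trajectory <- trajectory_table(states)
    note("trajectory", list(),
         emit_csv(res$trajectory$table, "trajectory.csv"))
  }

  res$manifest <- dplyr::bind_rows(manifest)
  res
}
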