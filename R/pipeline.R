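#' Experiment configuration
#'
#' Validates a configuration for [run_experiment()]. Unknown keys are
#' errors, preventing silent typos in `D` or `K`. Groups are either
#' preset names from [colony_presets()] (synthetic data) or directories
#' containing masks plus a `dataset.json` sidecar (real data).
#'
#' @param groups character vector of preset names or directories (>= 2).
#' @param D number of chord angles (>= 2; the reference settings are 4
#'   and 12).
#' @param K clusters per group (>= 1; the reference settings are 5 and 10).
#' @param protocol one of `"train_test"`, `"loocv"`, `"feature_analysis"`.
#' @param n repetitions for the train/test protocol.
#' @param seed master seed.
#' @param output_dir directory for reports, or `NULL` for none.
#' @return Validated list of class `experiment_config`.
#' @export
experiment_config <- function(groups, D = 4, K = 10, protocol = "train_test",
                              n = 30, seed = 1L, output_dir = NULL) {
  protocol <- match.arg(protocol, c("train_test", "loocv", "feature_analysis"))
  if (length(groups) < 2L) stop("at least 2 groups are required")
  if (D < 2 || D != round(D)) stop("`D` must be an integer >= 2")
  if (K < 1 || K != round(K)) stop("`K` must be an integer >= 1")
  if (n < 1 || n != round(n)) stop("`n` must be an integer >= 1")
  structure(list(groups = groups, D = as.integer(D), K = as.integer(K),
                 protocol = protocol, n = as.integer(n),
                 seed = as.integer(seed), output_dir = output_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from JSON or YAML
#'
#' @param path configuration file. Recognized keys: `groups`, `D`, `K`,
#'   `protocol`, `n`, `seed`, `output_dir`; anything else is an error.
#' @return An [experiment_config()].
#' @export
read_experiment_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("groups", "D", "K", "protocol", "n", "seed", "output_dir")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown configuration key(s): ", paste(extra, collapse = ", "))
  do.call(experiment_config, cfg)
}

#' Run a full classification experiment
#'
#' Loads or generates the images of each group, measures shape primitives
#' and spatial indices, fits CSPs, builds augmented features and runs the
#' configured evaluation protocol. Fully seeded: rerunning with the same
#' configuration reproduces the result exactly. When `output_dir` is set,
#' a JSON report, a per-run CSV and a manifest sufficient to reproduce the
#' run are written there.
#'
#' @param config an [experiment_config()] (or path to one).
#' @return The protocol's `csp_experiment` result, with the config
#'   attached as attribute `config`.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- read_experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  presets <- names(colony_presets())
  images <- unlist(lapply(config$groups, function(g) {
    if (g %in% presets) generate_grouped_dataset(g, seed = config$seed)
    else if (dir.exists(g)) load_dataset(g)
    else stop("group '", g, "' is neither a preset nor a directory")
  }), recursive = FALSE)
  prepared <- prepare_colony_data(images, D = config$D, seed = config$seed)
  result <- switch(config$protocol,
    train_test = repeated_evaluation(D = config$D, K = config$K, n = config$n,
                                     seed = config$seed, prepared = prepared),
    loocv = loocv_evaluate(D = config$D, K = config$K, seed = config$seed,
                           prepared = prepared),
    feature_analysis = feature_analysis(D = config$D, K = config$K,
                                        split_seed = config$seed,
                                        kmeans_seed = config$seed + 1L,
                                        prepared = prepared))
  attr(result, "config") <- config
  if (!is.null(config$output_dir)) write_experiment_report(result, config)
  result
}

# JSON + CSV report and a reproduction manifest
write_experiment_report <- function(result, config) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  base <- unclass(result)
  base$csp_centres <- if (!is.null(result$csp_centres))
    apply(result$csp_centres, 1, as.numeric, simplify = FALSE)
  base$model <- NULL
  jsonlite::write_json(base, file.path(config$output_dir, "result.json"),
                       auto_unbox = TRUE, digits = NA)
  if (identical(result$protocol, "train_test")) {
    write.csv(data.frame(run = seq_along(result$accuracies),
                         accuracy = result$accuracies,
                         best_feature = result$best_features),
              file.path(config$output_dir, "runs.csv"), row.names = FALSE)
  } else if (identical(result$protocol, "loocv")) {
    write.csv(data.frame(fold = seq_along(result$correct),
                         correct = result$correct,
                         best_feature = result$best_features),
              file.path(config$output_dir, "runs.csv"), row.names = FALSE)
  }
  manifest <- list(package = "cspshapes",
                   version = as.character(utils::packageVersion("cspshapes")),
                   r_version = R.version.string,
                   config = unclass(config))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(config$output_dir)
}

#' Accuracy grid over the reference (D, K) settings
#'
#' Runs [repeated_evaluation()] for every combination of `D` in `Ds` and
#' `K` in `Ks` and tabulates mean and standard deviation, the summary
#' format used for the repeated train/test protocol.
#'
#' @param images list of labelled [binary_image] objects.
#' @param Ds,Ks settings to cross (defaults 4/12 and 5/10).
#' @param n repetitions per cell.
#' @param seed master seed.
#' @return Data frame with columns `D`, `K`, `mu`, `sigma`.
#' @export
accuracy_grid <- function(images, Ds = c(4, 12), Ks = c(5, 10), n = 30,
                          seed = 1L) {
  rows <- list()
  for (D in Ds) {
    prepared <- prepare_colony_data(images, D = D, seed = seed)
    for (K in Ks) {
      r <- repeated_evaluation(D = D, K = K, n = n, seed = seed,
                               prepared = prepared)
      rows[[length(rows) + 1L]] <- data.frame(D = D, K = K, mu = r$mu,
                                              sigma = r$sigma)
    }
  }
  do.call(rbind, rows)
}

#' Plot a CSP centre as a length-per-angle histogram
#'
#' Renders one clustered shape primitive as a bar chart: one bin per
#' chord angle, bar height the physical length (micrometres) measured at
#' that angle. This is the standard way of visualizing which local shape
#' pattern a winning CSP feature encodes.
#'
#' @param centre numeric length-D CSP centre vector (a row of
#'   `model$centres`).
#' @param main plot title.
#' @export
plot_csp_centre <- function(centre, main = "CSP centre") {
  D <- length(centre)
  graphics::barplot(centre, names.arg = paste0(round(0:(D - 1) / D, 2), "π"),
                    xlab = "chord angle", ylab = "length (µm)", main = main)
  invisible(centre)
}
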