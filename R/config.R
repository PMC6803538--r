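#' Build a full pipeline run configuration
#'
#' Nested configuration covering every stage.  Unknown keys are rejected,
#' so a typo in a config file fails loudly instead of silently using a
#' default.
#'
#' @param paradigm Named list of [paradigm_config()] overrides.
#' @param truth Named list of [ground_truth()] overrides (scalar fields and
#'   the `noise` sub-list).
#' @param preprocessing Named list of [preprocess_subject()] overrides.
#' @param nvc Named list: `threshold`, `X_ms_range`, `Y_ms_max`.
#' @param network Named list: `density`, `window_s`.
#' @param classification Named list: `n_reps`, `n_folds`, `n_keep`,
#'   `k_neighbors`, `C_grid`, `gamma_grid`, `inner_folds`, `tuning`,
#'   `modalities`.
#' @param seed Global integer seed.
#' @param out Output root directory.
#' @return A `run_config` list.
#' @export
run_config <- function(paradigm = list(), truth = list(),
                       preprocessing = list(), nvc = list(),
                       network = list(), classification = list(),
                       seed = 1L, out = "neurointent_run") {
  defaults <- list(
    paradigm = formals(paradigm_config),
    truth = formals(ground_truth),
    preprocessing = formals(preprocess_subject)[-1],
    nvc = list(threshold = 0.8, X_ms_range = c(100, 600), Y_ms_max = 3000),
    network = list(density = 0.3, window_s = c(0, 3.5)),
    classification = list(n_reps = 10L, n_folds = 10L, n_keep = 60L,
                          k_neighbors = 10L,
                          C_grid = 2^seq(-5, 15, 2),
                          gamma_grid = 2^seq(-15, 3, 2),
                          inner_folds = 5L, tuning = "nested",
                          modalities = c("eeg", "fnirs", "fused"))
  )
  user <- list(paradigm = paradigm, truth = truth,
               preprocessing = preprocessing, nvc = nvc, network = network,
               classification = classification)
  for (sec in names(user)) {
    unknown <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
    if (length(unknown))
      stop("unknown key(s) in config section '", sec, "': ",
           paste(unknown, collapse = ", "))
  }
  # the function-backed sections keep only the overrides (their functions
  # supply defaults); the plain sections are merged with defaults here
  for (sec in c("nvc", "network", "classification")) {
    merged <- defaults[[sec]]
    merged[names(user[[sec]])] <- user[[sec]]
    user[[sec]] <- merged
  }
  structure(c(user, list(seed = as.integer(seed), out = out)),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with any of the [run_config()] sections
#'   (`paradigm`, `truth`, `preprocessing`, `nvc`, `network`,
#'   `classification`, `seed`, `out`).  Unknown sections or keys are
#'   rejected.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("paradigm", "truth", "preprocessing", "nvc", "network",
             "classification", "seed", "out")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config section(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

#' Write a run configuration to YAML
#' @param config A `run_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# stable md5 of an R object via canonical JSON
.config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}
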