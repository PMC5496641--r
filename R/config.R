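# YAML run configuration, seed derivation and run metadata.

chromsig_defaults <- function() {
  list(bin_bp = 10, window_bp = 10000, percentile = 10, k_max = 10,
       stride_bp = 100, top_n = 2500, seed = 1)
}

#' Load and validate a YAML run configuration
#'
#' The config maps channel names to track file paths and optionally
#' overrides the analysis defaults (10 Kb window, 10 bp bins, bandwidth
#' percentile 10, 100 bp scan stride, top 2500 hits).
#'
#' @param path YAML file with a `channels:` map (name -> bedGraph path;
#'   paths are resolved relative to the config file) and optional scalar
#'   parameters `bin_bp`, `window_bp`, `percentile`, `k_max`, `stride_bp`,
#'   `top_n`, `seed`.
#' @return A validated `run_config` list with defaults filled in.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path),
          class = "chromsig_config_error")
  }
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    abort(paste0("cannot parse YAML config: ", conditionMessage(e)),
          class = "chromsig_config_error")
  })
  cfg <- modifyList(chromsig_defaults(), raw[!vapply(raw, is.null, logical(1))])
  for (p in c("bin_bp", "window_bp", "percentile", "k_max", "stride_bp",
              "top_n")) {
    if (!is.numeric(cfg[[p]]) || length(cfg[[p]]) != 1 || cfg[[p]] <= 0) {
      abort(paste0("config parameter '", p, "' must be a positive number"),
            class = "chromsig_config_error")
    }
  }
  if (!is.null(cfg$channels)) {
    paths <- unlist(cfg$channels)
    rel <- !startsWith(paths, "/")
    paths[rel] <- file.path(dirname(path), paths[rel])
    missing <- paths[!file.exists(paths)]
    if (length(missing)) {
      abort(paste0("channel track file(s) not found: ",
                   paste(missing, collapse = ", ")),
            class = "chromsig_config_error")
    }
    cfg$channels <- setNames(paths, names(cfg$channels))
  }
  structure(cfg, class = "run_config")
}

#' Derive a stage-specific sub-seed from a global seed
#'
#' One global seed fans out deterministically to per-stage seeds so stages
#' are independently reproducible.  The result is a positive integer below
#' 2^31.
#'
#' @param seed Global integer seed.
#' @param stage Stage name (any string).
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 9349) %% 2147483587 + 1)
}

#' Write run metadata sufficient to reproduce a run
#'
#' Records the package version, the global seed, the full parameter list
#' and a hash of it as JSON.
#'
#' @param path Output JSON path.
#' @param params Named list of run parameters.
#' @param seed Global seed used.
#' @param extra Optional named list of extra fields (e.g. iteration
#'   counts).
#' @return Invisibly, the metadata list.
#' @export
write_run_metadata <- function(path, params, seed, extra = list()) {
  meta <- c(
    list(
      tool = "chromsig",
      version = as.character(utils::packageVersion("chromsig")),
      seed = seed,
      params = params,
      params_hash = rlang::hash(params)
    ),
    extra
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(meta)
}
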