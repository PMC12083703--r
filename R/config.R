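#' Validated run configuration
#'
#' Gathers the knobs shared by the command-line pipeline stages into a
#' single validated object. Unknown keys are rejected, which catches typos
#' in config files before any stage runs.
#'
#' @param ... Named values among: `labels`, `dict`, `rankings`, `responses`,
#'   `prompts`, `logprobs`, `out` (paths); `k`, `q`, `n_top` (counts); `lambda`, `beta`,
#'   `hfa_threshold`, `match_threshold` (reals); `seed` (integer);
#'   `hfa_rule` (`"all"`, `"any"`, `"majority"`); `normalize` (flag);
#'   `kind` (`"orpo"` or `"dpo"`); `accuracy`, `quality`, `n` (simulator).
#' @return A `run_config` list with defaults filled in.
#' @export
run_config <- function(...) {
  defaults <- list(
    labels = NULL, dict = NULL, rankings = NULL, responses = NULL,
    prompts = NULL, logprobs = NULL, out = NULL,
    k = 10L, q = 10L, n_top = 10L, lambda = 1, beta = 0.25,
    hfa_threshold = 0.6, match_threshold = 0.8, hfa_rule = "all",
    normalize = TRUE, kind = "orpo", accuracy = 0.8, quality = 1,
    n = 100L, seed = 1L
  )
  supplied <- list(...)
  if (length(supplied) > 0 && (is.null(names(supplied)) || any(!nzchar(names(supplied))))) {
    stop("all run_config() arguments must be named", call. = FALSE)
  }
  unknown <- setdiff(names(supplied), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, supplied)
  stopifnot(
    cfg$k >= 1, cfg$q >= 1, cfg$n_top >= 1, cfg$lambda >= 0, cfg$beta >= 0,
    cfg$hfa_threshold >= 0, cfg$hfa_threshold <= 1,
    cfg$match_threshold >= 0, cfg$match_threshold <= 1,
    cfg$accuracy >= 0, cfg$accuracy <= 1,
    cfg$quality >= 0, cfg$quality <= 1, cfg$n >= 1
  )
  if (!cfg$hfa_rule %in% c("all", "any", "majority")) {
    stop("hfa_rule must be one of all, any, majority", call. = FALSE)
  }
  if (!cfg$kind %in% c("orpo", "dpo")) {
    stop("kind must be 'orpo' or 'dpo'", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a key=value text file
#'
#' Plain `key = value` lines; `#` starts a comment. Values are parsed as
#' numbers where possible, otherwise kept as strings. Keys are validated by
#' [run_config()], so unknown keys fail loudly.
#'
#' @param path Config file path.
#' @param overrides Named list applied on top of the file (CLI flags beat
#'   the file, which beats the defaults).
#' @return A [run_config()].
#' @export
read_run_config <- function(path, overrides = list()) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lines[vapply(kv, length, integer(1)) != 2]
  if (length(bad) > 0) {
    stop("malformed config line: '", bad[1], "'", call. = FALSE)
  }
  vals <- lapply(kv, function(p) {
    v <- p[2]
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else if (v %in% c("true", "TRUE")) TRUE else if (v %in% c("false", "FALSE")) FALSE else v
  })
  names(vals) <- vapply(kv, `[[`, character(1), 1)
  vals <- utils::modifyList(vals, overrides)
  do.call(run_config, vals)
}
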