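#' Read a run configuration
#'
#' Loads a YAML configuration with up to three flat sections: `params`
#' (rate constants, defaults applied for omitted fields), `protocol`
#' (dosing schedule) and `sim` (stochastic engine settings). Unknown keys in
#' any section are an error, so a typo cannot silently fall back to a
#' default.
#'
#' @param path Path to a YAML file.
#' @return List with validated `params` ([model_params()]), `protocol`
#'   ([therapy_protocol()]) and `sim` ([sim_config()]).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), c("params", "protocol", "sim"))
  if (length(unknown) > 0)
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  take <- function(section, fun) {
    given <- raw[[section]]
    if (is.null(given)) given <- list()
    allowed <- names(formals(fun))
    bad <- setdiff(names(given), allowed)
    if (length(bad) > 0)
      stop("unknown key(s) in '", section, "': ", paste(bad, collapse = ", "))
    do.call(fun, given)
  }
  list(params = take("params", model_params),
       protocol = take("protocol", therapy_protocol),
       sim = take("sim", sim_config))
}

#' Write a run configuration
#'
#' Serialises parameter/protocol/simulation objects back to YAML with 17
#' significant digits, so a write-read round trip reproduces every numeric
#' field exactly.
#'
#' @param config List with any of `params`, `protocol`, `sim` (as returned
#'   by [load_config()], or built directly).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  out <- list()
  if (!is.null(config$params))
    out$params <- unclass(config$params)
  if (!is.null(config$protocol)) {
    pr <- unclass(config$protocol)
    pr$period_days <- NULL   # derived from f
    out$protocol <- pr
  }
  if (!is.null(config$sim)) {
    sm <- unclass(config$sim)
    if (length(sm$snapshot_times) == 0) sm$snapshot_times <- NULL
    out$sim <- sm
  }
  yaml::write_yaml(out, path, precision = 17L)
  invisible(path)
}

#' Write an experiment run to disk
#'
#' Lays out a run directory deterministically: a JSON manifest recording
#' parameters, protocol, seeds, tolerances and the package version, plus one
#' tab-separated table per trajectory/result, floating point values at 17
#' significant digits (full round-trip precision). Two runs with identical
#' inputs produce byte-identical tables.
#'
#' @param outdir Output directory (created if missing).
#' @param manifest Named list of run metadata; `params`/`protocol` objects
#'   are serialised in full.
#' @param tables Named list of data frames.
#' @return Named character vector of the paths written.
#' @export
write_run <- function(outdir, manifest = list(), tables = list()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest$chemoICB_version <-
    as.character(utils::packageVersion("chemoICB"))
  paths <- c(manifest = file.path(outdir, "manifest.json"))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  for (nm in names(tables)) {
    f <- file.path(outdir, paste0(nm, ".tsv"))
    df <- as.data.frame(tables[[nm]])
    num <- vapply(df, is.numeric, logical(1))
    for (v in names(df)[num]) df[[v]] <- sprintf("%.17g", df[[v]])
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[nm]] <- f
  }
  paths
}

#' Read back a trajectory table written by [write_run()]
#'
#' @param path Path to a `.tsv` trajectory table.
#' @return Data frame with numeric columns restored at full precision.
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("no such table: ", path)
  utils::read.table(path, header = TRUE, sep = "\t")
}
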