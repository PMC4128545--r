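#' Write a results table with a provenance header
#'
#' Writes a data frame as tab-separated values preceded by commented
#' header lines (`# key: value`) recording the package version and any
#' run metadata (resolved configuration, seed, ...), so every artifact
#' carries what is needed to re-run it. Numeric columns are written at
#' full precision (`%.17g`), so a round trip through [read_run_table()]
#' reproduces them bit-exactly. Output is byte-identical across runs with
#' identical inputs unless `timestamp = TRUE`.
#'
#' @param x A data frame.
#' @param path Output path.
#' @param metadata Named list of scalar metadata echoed into the header.
#' @param timestamp Add a timestamp header line? Default `FALSE` so
#'   identical runs produce identical files.
#' @return `path`, invisibly.
#' @export
write_run_table <- function(x, path, metadata = list(), timestamp = FALSE) {
  stopifnot(is.data.frame(x))
  if (length(metadata) && is.null(names(metadata)))
    stop("'metadata' must be a named list")
  hdr <- c(sprintf("# package: phagecommons %s",
                   as.character(packageVersion("phagecommons"))),
           if (timestamp) sprintf("# written: %s",
                                  format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
           vapply(names(metadata), function(nm)
             sprintf("# %s: %s", nm,
                     paste(format(metadata[[nm]], digits = 17),
                           collapse = " ")), character(1)))
  fmt <- x
  for (j in seq_along(fmt))
    if (is.double(fmt[[j]])) fmt[[j]] <- sprintf("%.17g", fmt[[j]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(fmt, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [write_run_table()]
#'
#' @param path File path.
#' @return The data frame, with the parsed header lines attached as a
#'   named character vector attribute `"metadata"`.
#' @export
read_run_table <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^# ([^:]+): (.*)$", hdr))
  meta <- setNames(vapply(kv, `[`, character(1), 3L),
                   vapply(kv, `[`, character(1), 2L))
  out <- read.delim(path, comment.char = "#", sep = "\t",
                    stringsAsFactors = FALSE)
  attr(out, "metadata") <- meta
  out
}

.run_config_keys <- list(
  scenario = "character", params_file = "character",
  t_end = "numeric", dt = "numeric", output_thin = "numeric",
  history_mode = "character", seed = "numeric",
  T_true = "numeric", n = "numeric", R = "numeric", reps = "numeric",
  level = "numeric", out = "character"
)

#' Read and validate a run configuration file
#'
#' Parses a flat `key<TAB>value` configuration (one entry per line,
#' `#` comments allowed) that can drive any of the package's analysis
#' entry points ([run_scenario()], [recovery_experiment()], ...). Unknown
#' keys and malformed numbers are rejected with pointed messages;
#' defaults are resolved for the simulation keys. The resolved
#' configuration can be echoed into output headers via
#' [write_run_table()]'s `metadata`.
#'
#' @param path Path to the config file.
#' @return A validated named list (class `run_config`) of typed values
#'   with simulation defaults filled in.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad))
    stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- vapply(parts, `[`, character(1), 1L)
  vals <- vapply(parts, `[`, character(1), 2L)
  unknown <- setdiff(keys, names(.run_config_keys))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(keys))
    stop("duplicated config key(s): ", paste(keys[duplicated(keys)],
                                             collapse = ", "))
  cfg <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]
    if (.run_config_keys[[k]] == "numeric") {
      v <- suppressWarnings(as.numeric(vals[i]))
      if (is.na(v))
        stop("config key '", k, "' has malformed number: '", vals[i], "'")
      cfg[[k]] <- v
    } else cfg[[k]] <- vals[i]
  }
  defaults <- list(t_end = 1500, dt = 1e-3, history_mode = "hold-initial",
                   level = 0.95)
  for (k in names(defaults))
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (is.null(cfg$output_thin)) cfg$output_thin <- round(1 / cfg$dt)
  if (!cfg$history_mode %in% c("hold-initial", "zero-phage"))
    stop("config key 'history_mode' must be 'hold-initial' or 'zero-phage'")
  if (!is.null(cfg$scenario) && !cfg$scenario %in% .scenarios)
    stop("config key 'scenario' must be one of ",
         paste(.scenarios, collapse = ", "))
  structure(cfg, class = "run_config")
}

#' Write a run configuration file
#'
#' Serializes a config list in the flat `key<TAB>value` format read by
#' [read_run_config()]; a write/read round trip reproduces the resolved
#' configuration.
#'
#' @param config A named list or `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  unknown <- setdiff(names(config), names(.run_config_keys))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  writeLines(vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s\t%s", k,
            if (is.numeric(v)) sprintf("%.17g", v) else as.character(v))
  }, character(1)), path)
  invisible(path)
}
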