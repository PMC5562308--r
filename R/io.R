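# column mapping between the file schema and the internal soil table
OBS_SCHEMA <- c(corg_pct = "corg", temp_k = "temperature",
                time_days = "time")

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

# strict numeric conversion: blanks become NA, anything else that fails to
# parse is an error naming the column and row (no silent coercion)
strict_numeric <- function(x, col) {
  x <- trimws(x)
  x[x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0)
    stop("column '", col, "': non-numeric value(s) in row(s) ",
         paste(bad, collapse = ", "), " (e.g. \"", x[bad[1]], "\")")
  out
}

#' Read an observation table
#'
#' Reads a delimited soil/observation table (comma default, tab detected
#' automatically). The file schema uses columns `sample_id`, `ph`,
#' `corg_pct`, `temp_k` and `time_days` (or `time_years`, converted at
#' 365 d/y), plus optional `e_add_obs`, `total_cu_mg_kg` and `weight`;
#' unknown columns are preserved. On return the covariates carry the
#' internal names used throughout the package: `corg`, `temperature`,
#' `time` (days). Numeric parsing is strict: blanks become `NA`, any other
#' unparseable value is an error naming the column and row.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @return Data frame in internal naming.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  delim <- sniff_delim(path)
  raw <- read.table(path, header = TRUE, sep = delim,
                    colClasses = "character", check.names = TRUE,
                    stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "ph")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (!("time_days" %in% names(raw)) && !("time_years" %in% names(raw)))
    stop("missing required column(s): time_days (or time_years)")

  out <- raw
  for (col in names(out))
    if (col != "sample_id") {
      conv <- tryCatch(strict_numeric(out[[col]], col),
                       error = function(e) e)
      known_numeric <- col %in% c("ph", names(OBS_SCHEMA), "time_years",
                                  "e_add_obs", "total_cu_mg_kg", "weight")
      if (inherits(conv, "error")) {
        if (known_numeric) stop(conv) else next  # unknown column: keep text
      } else out[[col]] <- conv
    }

  for (from in names(OBS_SCHEMA))
    if (from %in% names(out))
      names(out)[names(out) == from] <- OBS_SCHEMA[[from]]
  if (!("time" %in% names(out)))
    out$time <- out$time_years * 365
  if (!("corg" %in% names(out)) && !("corg_pct" %in% names(raw)))
    stop("missing required column(s): corg_pct")
  if (!("temperature" %in% names(out)))
    stop("missing required column(s): temp_k")
  out
}

#' Write an observation table
#'
#' Inverse of [read_observations()]: maps internal column names back to
#' the file schema (`corg` to `corg_pct`, `temperature` to `temp_k`,
#' `time` to `time_days`) and writes full-precision values so a
#' read-write-read cycle is value-identical.
#'
#' @param x Data frame in internal naming.
#' @param path Output file path.
#' @param delim Field delimiter (default comma).
#' @param comment Optional comment line(s) written before the header,
#'   each prefixed with `#`.
#' @return `path`, invisibly.
#' @export
write_observations <- function(x, path, delim = ",", comment = NULL) {
  out <- x
  rev_map <- setNames(names(OBS_SCHEMA), OBS_SCHEMA)
  for (from in names(rev_map))
    if (from %in% names(out))
      names(out)[names(out) == from] <- rev_map[[from]]
  for (col in names(out))
    if (is.numeric(out[[col]]))
      out[[col]] <- ifelse(is.na(out[[col]]), "",
                           sprintf("%.17g", out[[col]]))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  write.table(out, con, sep = delim, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an isotope-measurement table
#'
#' Columns: `sample_id`, `spike_total_mg_kg` (65Cu spike, mg/kg),
#' `ir_meas` (measured 63/65 ratio), optional `ir_nat` (per-soil natural
#' ratio override; blank rows fall back to the 2.2435 default).
#'
#' @param path Path to a CSV/TSV file.
#' @return Data frame with those columns.
#' @export
read_isotope_table <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  delim <- sniff_delim(path)
  raw <- read.table(path, header = TRUE, sep = delim,
                    colClasses = "character", stringsAsFactors = FALSE,
                    comment.char = "#")
  need <- c("sample_id", "spike_total_mg_kg", "ir_meas")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0)
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  for (col in setdiff(names(raw), "sample_id"))
    raw[[col]] <- strict_numeric(raw[[col]], col)
  raw
}

# YAML 1.1 treats bare N, F, y, n ... as booleans -- including as mapping
# keys, which collides with the parameter names N and F. Quote every
# mapping key before parsing so keys always come back as strings.
read_yaml_keys_as_strings <- function(path) {
  lines <- readLines(path)
  lines <- gsub("^(\\s*-?\\s*)([A-Za-z][A-Za-z0-9_]*)(\\s*):",
                '\\1"\\2"\\3:', lines)
  yaml::yaml.load(paste(lines, collapse = "\n"))
}

default_run_config <- function() {
  list(
    params = as.list(aging_params()),
    fit = list(free = c("B", "C", "N", "F", "G"), free_pk = FALSE,
               anchor_weight = 1, multistart = 10, seed = 1),
    simulate = list(n = 100, ph_range = c(2.98, 7.52),
                    corg_range = c(0.41, 23.32),
                    temp_range = c(278, 298),
                    time_range = c(1, 30000),
                    noise_sd = 0.05, seed = 1)
  )
}

#' Read a run configuration
#'
#' YAML configuration with three optional blocks -- `params` (any of the
#' seven model constants), `fit` (`free`, `free_pk`, `anchor_weight`,
#' `multistart`, `seed`) and `simulate` ([generate_soils()] settings plus
#' `noise_sd`, `seed`). Missing entries take the package defaults, so an
#' absent or empty file reproduces the reference parameter set exactly.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Nested list with `params` as an [aging_params()] object.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- read_yaml_keys_as_strings(path)
    if (!is.null(user))
      for (block in intersect(names(user), names(cfg)))
        cfg[[block]] <- modifyList(cfg[[block]], user[[block]])
  }
  cfg$params <- as_aging_params(cfg$params)
  cfg
}

#' Read a model parameter file
#'
#' YAML file with any of the keys `B`, `C`, `N`, `F`, `G`, `K`, `pK0`;
#' missing keys take the reference defaults.
#'
#' @param path Path to a YAML file.
#' @return An [aging_params()] object.
#' @export
read_params_file <- function(path) {
  if (!file.exists(path)) stop("params file not found: ", path)
  as_aging_params(read_yaml_keys_as_strings(path))
}

#' Write a fit report
#'
#' Flat `key = value` text, full precision: fitted and fixed parameters,
#' R2, RMSE, objective, convergence, sizes, seed.
#'
#' @param fit An `aging_fit` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "aging_fit"))
  kv <- c(
    sprintf("package = cuaging %s", as.character(packageVersion("cuaging"))),
    sprintf("free = %s", paste(fit$free, collapse = ",")),
    vapply(PARAM_NAMES, function(nm)
      sprintf("%s = %.17g", nm, fit$params[[nm]]), ""),
    sprintf("r2 = %.17g", fit$r2),
    sprintf("rmse = %.17g", fit$rmse),
    sprintf("objective = %.17g", fit$objective),
    sprintf("converged = %s", fit$converged),
    sprintf("n_iterations = %d", fit$n_iterations),
    sprintf("n_obs = %d", fit$n_obs),
    sprintf("n_anchors = %d", fit$n_anchors),
    sprintf("seed = %d", as.integer(fit$seed))
  )
  writeLines(kv, path)
  invisible(path)
}

log_run <- function(verbose, cmd, seed = NULL, inputs = character()) {
  if (!verbose) return(invisible(NULL))
  message(sprintf("cuaging %s | command: %s",
                  as.character(packageVersion("cuaging")), cmd))
  if (!is.null(seed)) message("  seed: ", seed)
  for (p in inputs)
    if (file.exists(p))
      message(sprintf("  input %s md5=%s", p, unname(tools::md5sum(p))))
  invisible(NULL)
}
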