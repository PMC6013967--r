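# CSV time-series interchange and run configuration.

TS_COLUMNS <- c("time_h", unname(STATE_COLS))

#' Write / read a fermentation time series as CSV
#'
#' The interchange format is plain CSV with unit-bearing column names
#' (`time_h, glu_cmol_L, ..., e2_cmol_L`, optionally the cumulative
#' off-gas columns `h2acc_mol_L`/`co2w_cmol_L`) and `#`-prefixed comment
#' lines carrying metadata (`# key: value`).  `write_timeseries()`
#' serialises the provenance attributes of generated datasets;
#' `read_timeseries()` restores them into attribute `meta`.
#'
#' @param series a trajectory tibble.
#' @param path file path.
#' @param meta named list of additional metadata to put in the header.
#' @return `write_timeseries()`: `path`, invisibly.
#' @export
write_timeseries <- function(series, path, meta = list()) {
  prov <- attr(series, "provenance")
  if (!is.null(prov))
    meta <- modifyList(list(provenance = prov$case, seed = prov$seed,
                            relative_sd = prov$relative_sd,
                            lag_h = prov$lag_h), meta)
  keep <- intersect(c(TS_COLUMNS, unname(AUX_COLS), "q_gas_L_h"),
                    names(series))
  lines <- character(0)
  for (nm in names(meta)) {
    v <- meta[[nm]]
    if (is.null(v) || length(v) != 1 || is.list(v)) next
    lines <- c(lines, sprintf("# %s: %s", nm, format(v, digits = 15)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  utils::write.table(
    format(as.data.frame(series)[keep], digits = 15, trim = TRUE,
           scientific = NA),
    con, sep = ",", quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_timeseries
#' @param clip_negative policy for negative concentrations on read: warn
#'   and clip to zero (`TRUE`, default) or raise an error (`FALSE`).
#' @return `read_timeseries()`: a tibble with attribute `meta` (named
#'   character vector from the comment header) and `unobserved` (states
#'   missing from the file).
#' @export
read_timeseries <- function(path, clip_negative = TRUE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  raw <- readLines(path)
  hdr <- grep("^#", raw, value = TRUE)
  meta <- character(0)
  if (length(hdr)) {
    kv <- regmatches(hdr, regexec("^#\\s*([^:]+):\\s*(.*)$", hdr))
    kv <- kv[vapply(kv, length, 1L) == 3]
    meta <- setNames(vapply(kv, `[`, "", 3),
                     trimws(vapply(kv, `[`, "", 2)))
  }
  df <- utils::read.csv(text = raw, comment.char = "#",
                        check.names = FALSE)
  if (!"time_h" %in% names(df))
    stop("time series file lacks a `time_h` column", call. = FALSE)
  if (any(diff(df$time_h) <= 0))
    stop("non-monotonic `time_h` in time series file", call. = FALSE)
  missing_states <- setdiff(unname(STATE_COLS), names(df))
  conc_cols <- setdiff(intersect(c(TS_COLUMNS, unname(AUX_COLS)),
                                 names(df)), "time_h")
  for (cl in conc_cols) {
    neg <- df[[cl]] < 0
    if (any(neg, na.rm = TRUE)) {
      if (!clip_negative)
        stop(sprintf("negative values in column `%s`", cl), call. = FALSE)
      warning(sprintf("clipping %d negative value(s) in `%s` to zero",
                      sum(neg, na.rm = TRUE), cl), call. = FALSE)
      df[[cl]][neg] <- 0
    }
  }
  out <- tibble::as_tibble(df)
  structure(out, meta = meta, unobserved = missing_states,
            class = c("fh2_dataset", class(out)))
}

CONFIG_DEFAULTS <- list(
  case = "case3",
  t_end = NULL,            # default: the case horizon
  grid_h = 0.25,
  rtol = 1e-8,
  atol = 1e-10,
  q_gas_mode = "n2_plus_product",
  gas_reference = "reactor",
  delta = 0.01,
  probe_params = SENS_PARAMS,
  free_params = character(0),
  weights = NULL,
  relative_sd = 0.05,
  floor_sd = 0,
  seed = 1L,
  lag_h = 0,
  interval = 1.5,
  out_dir = "."
)

#' Load a run configuration
#'
#' Reads a YAML key-value file, validates it against the documented keys
#' and fills in defaults.  Unknown keys and invalid values raise errors
#' naming the offending field.
#'
#' @param path YAML file.
#' @return A validated list of class `fh2_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  validate_config(raw)
}

#' @rdname load_config
#' @param config a (possibly partial) named list of settings.
#' @export
validate_config <- function(config = list()) {
  unknown <- setdiff(names(config), names(CONFIG_DEFAULTS))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s (valid: %s)",
                 paste(unknown, collapse = ", "),
                 paste(names(CONFIG_DEFAULTS), collapse = ", ")),
         call. = FALSE)
  cfg <- modifyList(CONFIG_DEFAULTS, config, keep.null = TRUE)
  # YAML reads vectors back as lists; normalise
  cfg$free_params <- as.character(unlist(cfg$free_params))
  cfg$probe_params <- as.character(unlist(cfg$probe_params))
  if (!cfg$case %in% paste0("case", 1:4))
    stop_domain("case", "must be one of case1..case4")
  for (nm in c("grid_h", "rtol", "atol", "delta", "interval"))
    check_pos(cfg[[nm]], nm)
  for (nm in c("relative_sd", "floor_sd", "lag_h"))
    check_nonneg(cfg[[nm]], nm)
  if (!is.null(cfg$t_end)) check_pos(cfg$t_end, "t_end")
  if (!cfg$q_gas_mode %in% c("n2_plus_product", "n2_only"))
    stop_domain("q_gas_mode", "must be n2_plus_product or n2_only")
  if (!cfg$gas_reference %in% c("reactor", "stp"))
    stop_domain("gas_reference", "must be reactor or stp")
  bad <- setdiff(cfg$probe_params, SENS_PARAMS)
  if (length(bad))
    stop_domain("probe_params", paste("unknown:", paste(bad, collapse = ", ")))
  bad <- setdiff(cfg$free_params, KIN_PARS)
  if (length(bad))
    stop_domain("free_params", paste("unknown:", paste(bad, collapse = ", ")))
  structure(cfg, class = "fh2_config")
}

#' @rdname load_config
#' @param config_obj an `fh2_config`.
#' @export
save_config <- function(config_obj, path) {
  x <- unclass(config_obj)
  x <- x[!vapply(x, is.null, TRUE)]
  yaml::write_yaml(x, path)
  invisible(path)
}
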