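# Schema-validated CSV I/O and the flat run-configuration file. Column names
# carry unit suffixes (uM, s, ppm) to prevent unit drift. All files are
# UTF-8, comma-delimited, dot-decimal, header required.

rate_table_schema <- c(bG1P_uM = "numeric", bG16BP_uM = "numeric",
                       ET_uM = "numeric", v0_uM_per_s = "numeric",
                       replicate = "integer")
progress_schema <- c(time_s = "numeric", value = "numeric",
                     kind = "character")
peak_schema <- c(residue = "integer", resname = "character",
                 state = "character", dH_ppm = "numeric", dN_ppm = "numeric",
                 intensity = "numeric")
zz_schema <- c(t_mix_s = "numeric", I_AA = "numeric", I_BB = "numeric",
               I_AB = "numeric", I_BA = "numeric")
trajectory_schema <- c(time_s = "numeric", species = "character",
                       conc_uM = "numeric")

read_schema_csv <- function(path, schema, optional = character()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- tryCatch(readLines(path, encoding = "UTF-8", warn = FALSE),
                    error = function(e) stop("cannot read ", path, ": ",
                                             conditionMessage(e)))
  if (!length(lines) || all(!nzchar(lines)))
    stop("empty file: ", path)
  if (any(!validUTF8(lines)))
    stop("non-UTF-8 content in ", path, " (first bad line: ",
         which(!validUTF8(lines))[1L], ")")
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  required <- setdiff(names(schema), optional)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  for (col in intersect(names(schema), names(df))) {
    want <- schema[[col]]
    x <- df[[col]]
    if (want %in% c("numeric", "integer")) {
      xn <- suppressWarnings(as.numeric(x))
      bad <- which(is.na(xn) & !is.na(x))
      if (length(bad))
        stop("column '", col, "' in ", path, " is not ", want,
             " (data line ", bad[1L], ")")
      df[[col]] <- if (want == "integer") as.integer(round(xn)) else xn
    } else {
      df[[col]] <- as.character(x)
    }
  }
  df
}

write_schema_csv <- function(df, path, columns) {
  missing <- setdiff(columns, names(df))
  if (length(missing))
    stop("cannot write ", path, ": missing column(s) ",
         paste(missing, collapse = ", "))
  utils::write.csv(df[, columns, drop = FALSE], path, row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write initial-rate tables
#'
#' CSV schema: `bG1P_uM,bG16BP_uM,ET_uM,v0_uM_per_s,replicate` (replicate
#' optional on read, defaulting to 1). Row order is preserved; parse errors
#' name the offending column and line.
#'
#' @param path file path.
#' @return `read_rate_table()`: a validated data frame.
#' @export
read_rate_table <- function(path) {
  df <- read_schema_csv(path, rate_table_schema, optional = "replicate")
  if (is.null(df$replicate)) df$replicate <- 1L
  check_rate_table(df)
  df
}

#' @rdname read_rate_table
#' @param table a rate table data frame.
#' @export
write_rate_table <- function(table, path) {
  check_rate_table(table)
  write_schema_csv(table, path, names(rate_table_schema))
}

check_rate_table <- function(df) {
  need <- c("bG1P_uM", "bG16BP_uM", "ET_uM", "v0_uM_per_s")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("rate table missing column(s): ", paste(missing, collapse = ", "))
  if (!nrow(df)) stop("rate table is empty")
  if (any(df$bG1P_uM < 0 | df$bG16BP_uM < 0))
    stop("concentrations must be >= 0")
  if (any(df$ET_uM <= 0)) stop("ET_uM must be > 0")
  if (any(df$v0_uM_per_s < 0)) stop("v0 must be >= 0")
  invisible(df)
}

#' Read / write progression curves
#'
#' CSV schema: `time_s,value,kind`; `kind` must be constant within a file
#' and one of `absorbance`, `concentration`, `normalised_integral`.
#'
#' @param path file path.
#' @return `read_progress_curve()`: a [progress_curve()].
#' @export
read_progress_curve <- function(path) {
  df <- read_schema_csv(path, progress_schema)
  kinds <- unique(df$kind)
  if (length(kinds) != 1L)
    stop("progress curve file mixes kinds: ", paste(kinds, collapse = ", "))
  progress_curve(df$time_s, df$value, kind = kinds)
}

#' @rdname read_progress_curve
#' @param curve a [progress_curve()].
#' @export
write_progress_curve <- function(curve, path) {
  stopifnot(inherits(curve, "progress_curve"))
  write_schema_csv(as.data.frame(curve), path, names(progress_schema))
}

#' Read / write amide peak lists
#'
#' CSV schema: `residue,resname,state,dH_ppm,dN_ppm,intensity`.
#'
#' @param path file path.
#' @return `read_peak_list()`: a validated peak table.
#' @export
read_peak_list <- function(path) {
  df <- read_schema_csv(path, peak_schema)
  bad <- !df$state %in% c("A", "B", "other")
  if (any(bad))
    stop("invalid state label(s) in ", path, ": ",
         paste(unique(df$state[bad]), collapse = ", "))
  df
}

#' @rdname read_peak_list
#' @param peaks a peak table.
#' @export
write_peak_list <- function(peaks, path) {
  write_schema_csv(peaks, path, names(peak_schema))
}

#' Read / write ZZ-exchange datasets
#'
#' CSV schema: `t_mix_s,I_AA,I_BB,I_AB,I_BA`; intensities must be >= 0.
#'
#' @param path file path.
#' @return `read_zz_dataset()`: a validated data frame of class
#'   `zz_dataset`.
#' @export
read_zz_dataset <- function(path) {
  df <- read_schema_csv(path, zz_schema)
  if (any(df$I_AA < 0 | df$I_BB < 0 | df$I_AB < 0 | df$I_BA < 0))
    stop("intensities must be >= 0")
  class(df) <- c("zz_dataset", "data.frame")
  df
}

#' @rdname read_zz_dataset
#' @param data a ZZ dataset.
#' @export
write_zz_dataset <- function(data, path) {
  write_schema_csv(as.data.frame(data), path, names(zz_schema))
}

#' Write / read a trajectory as tidy CSV
#'
#' Long format `time_s,species,conc_uM`, one row per time point and species.
#'
#' @param traj an [integrate_scheme()] trajectory.
#' @param path file path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  species <- colnames(traj$conc)
  df <- data.frame(
    time_s = rep(traj$times, times = length(species)),
    species = rep(species, each = length(traj$times)),
    conc_uM = as.vector(traj$conc))
  write_schema_csv(df, path, names(trajectory_schema))
}

#' @rdname write_trajectory
#' @return `read_trajectory()`: a data frame `time_s,species,conc_uM`.
#' @export
read_trajectory <- function(path) {
  read_schema_csv(path, trajectory_schema)
}

#' Write a fit report as CSV
#'
#' One row per parameter: `parameter,value,sd`.
#'
#' @param fit a `rate_fit` ([global_fit()]) or `exchange_fit`
#'   ([fit_zz_exchange()]).
#' @param path file path.
#' @export
write_fit_report <- function(fit, path) {
  if (inherits(fit, "rate_fit")) {
    v <- as.numeric(fit$params)
    df <- data.frame(parameter = names(fit$param_sd),
                     value = unname(v[names(fit$param_sd)]),
                     sd = unname(fit$param_sd))
  } else if (inherits(fit, "exchange_fit")) {
    df <- data.frame(parameter = c("k_ex", "pA", "R1", "amplitude"),
                     value = c(fit$k_ex, fit$pA, fit$R1, fit$amplitude),
                     sd = unname(fit$sd[c("k_ex", "pA", "R1", "amplitude")]))
  } else stop("unsupported fit object")
  write_schema_csv(df, path, c("parameter", "value", "sd"))
}

# --- flat run configuration -------------------------------------------------

run_config_keys <- c(
  "seed", "out_dir",
  "variant", "filter_max_bG16BP", "average_replicates",
  "window_frac", "r2_min",
  "rtol", "atol",
  "relative_sd", "absolute_floor",
  "E_T_uM", "bG1P_uM", "agent", "agent_uM",
  "epsilon_NADH", "path_cm")

#' Read / write the flat run-configuration file
#'
#' `key = value` lines (one per key, `#` comments allowed); unknown keys are
#' rejected; values that parse as numbers are numeric, `true`/`false` become
#' logical, everything else stays character. The file round-trips
#' losslessly.
#'
#' @param path file path.
#' @return `read_run_config()`: a named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "=", fixed = TRUE)[[1L]]
    if (length(parts) < 2L)
      stop("malformed config line ", i, ": '", lines[i], "'")
    key <- trimws(parts[1L])
    val <- trimws(paste(parts[-1L], collapse = "="))
    if (!key %in% run_config_keys)
      stop("unknown config key '", key, "' (known: ",
           paste(run_config_keys, collapse = ", "), ")")
    num <- suppressWarnings(as.numeric(val))
    cfg[[key]] <- if (!is.na(num)) num
      else if (val %in% c("true", "false")) val == "true"
      else val
  }
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @param config a named list of configuration values.
#' @export
write_run_config <- function(config, path) {
  bad <- setdiff(names(config), run_config_keys)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  fmt <- vapply(names(config), function(k) {
    v <- config[[k]]
    s <- if (is.logical(v)) tolower(as.character(v))
         else if (is.numeric(v)) format(v, digits = 17)
         else as.character(v)
    paste(k, "=", s)
  }, "")
  writeLines(fmt, path, useBytes = TRUE)
  invisible(path)
}
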