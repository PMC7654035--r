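# Readers/writers for the package's plain-text interchange formats and the
# run-configuration file. CSV dialect is pinned: comma separator, period
# decimal, UTF-8, header required; numerics are written with 17 significant
# digits so finite values round-trip losslessly.

RECORD_COLUMNS <- c("time_h", "od565", "dO2_pct", "lactate_mM", "nitrate_mM",
                    "cmag", "fe_mg_per_gdw", "rpm", "airflow_slpm")
PARTICLE_COLUMNS <- c("condition", "replicate", "timepoint_h", "diameter_nm")
CELL_COLUMNS <- c("condition", "replicate", "timepoint_h", "cell_id",
                  "length_um", "ms_count")

fmt_num <- function(x) {
  if (is.numeric(x)) formatC(x, digits = 17, format = "g") else as.character(x)
}

write_csv_exact <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt_num), stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = ",", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

read_csv_checked <- function(path, required, label) {
  stop_if(!file.exists(path), sprintf("%s file not found: %s", label, path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing <- setdiff(required, names(df))
  stop_if(length(missing) > 0,
          sprintf("%s '%s' is missing column(s): %s", label, path,
                  paste(missing, collapse = ", ")))
  df
}

#' Write / read a fermentation record CSV
#'
#' Canonical schema: `time_h, od565, dO2_pct, lactate_mM, nitrate_mM, cmag,
#' fe_mg_per_gdw, rpm, airflow_slpm` (extra columns are preserved). Reading
#' validates the header, strictly increasing times and rejects duplicate
#' timestamps.
#'
#' @param record a `fermentation_record` (or conforming data.frame).
#' @param path file path.
#' @return `read_record` returns a `fermentation_record`; `write_record`
#'   returns `path` invisibly.
#' @export
write_record <- function(record, path) {
  missing <- setdiff(RECORD_COLUMNS, names(record))
  stop_if(length(missing) > 0,
          sprintf("record is missing column(s): %s", paste(missing, collapse = ", ")))
  write_csv_exact(as.data.frame(record), path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  df <- read_csv_checked(path, RECORD_COLUMNS, "fermentation record")
  stop_if(nrow(df) == 0, "record contains no rows")
  stop_if(anyDuplicated(df$time_h) > 0, "record contains duplicate timestamps")
  stop_if(any(diff(df$time_h) <= 0), "time column must be strictly increasing")
  stop_if(any(!vapply(df[RECORD_COLUMNS[-1]], is.numeric, logical(1)) &
                !vapply(df[RECORD_COLUMNS[-1]], function(x) all(is.na(x)), logical(1))),
          "non-numeric values in record columns (mixed decimal conventions?)")
  for (col in names(df)) if (is.integer(df[[col]])) df[[col]] <- as.double(df[[col]])
  structure(df, class = c("fermentation_record", "data.frame"))
}

#' Write / read particle and cell tables
#'
#' Particle schema: `condition, replicate, timepoint_h, diameter_nm`; cell
#' schema: `condition, replicate, timepoint_h, cell_id, length_um,
#' ms_count`.
#'
#' @param dataset a `particle_dataset` (or a particles data.frame for
#'   `write_particles` when no cell table exists).
#' @param particles_path,cells_path file paths (`cells_path` optional).
#' @return `read_particles` returns a `particle_dataset`.
#' @export
write_particles <- function(dataset, particles_path, cells_path = NULL) {
  parts <- particles_of(dataset)
  write_csv_exact(parts[PARTICLE_COLUMNS], particles_path)
  if (!is.null(cells_path) && inherits(dataset, "particle_dataset"))
    write_csv_exact(dataset$cells[CELL_COLUMNS], cells_path)
  invisible(particles_path)
}

#' @rdname write_particles
#' @export
read_particles <- function(particles_path, cells_path = NULL) {
  parts <- read_csv_checked(particles_path, PARTICLE_COLUMNS, "particle table")
  stop_if(any(parts$diameter_nm <= 0), "non-positive diameters in particle table")
  cells <- if (!is.null(cells_path))
    read_csv_checked(cells_path, CELL_COLUMNS, "cell table")
  else data.frame()
  structure(list(particles = parts, cells = cells), class = "particle_dataset")
}

#' Write / read a SAXS curve as whitespace-separated ASCII
#'
#' Three columns (q \[A^-1\], I, sigma); lines beginning with `#` carry
#' metadata as `# key: value` pairs (`accumulation_time`, `thickness`,
#' `transmission` are parsed when present).
#'
#' @param curve a `saxs_curve`.
#' @param path file path (conventionally `.dat`).
#' @return `read_saxs` returns a `saxs_curve`.
#' @export
write_saxs <- function(curve, path) {
  stopifnot(inherits(curve, "saxs_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# accumulation_time: %s", fmt_num(curve$accumulation_time)),
               sprintf("# thickness: %s", fmt_num(curve$thickness)),
               sprintf("# transmission: %s", fmt_num(curve$transmission)),
               "# columns: q_A^-1 intensity sigma"), con)
  utils::write.table(data.frame(fmt_num(curve$q), fmt_num(curve$intensity),
                                fmt_num(curve$sigma)),
                     con, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_saxs
#' @export
read_saxs <- function(path) {
  stop_if(!file.exists(path), sprintf("SAXS file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  is_meta <- grepl("^\\s*#", lines)
  meta <- list(accumulation_time = 1, thickness = 1, transmission = 1)
  for (ln in lines[is_meta]) {
    m <- regmatches(ln, regexec("^\\s*#\\s*([A-Za-z_]+)\\s*:\\s*([-0-9.eE+]+)", ln))[[1]]
    if (length(m) == 3 && m[2] %in% names(meta)) meta[[m[2]]] <- as.numeric(m[3])
  }
  body <- lines[!is_meta & nzchar(trimws(lines))]
  stop_if(length(body) == 0, "SAXS file contains headers only: empty curve")
  tab <- utils::read.table(text = body)
  stop_if(ncol(tab) < 2, "SAXS file needs at least q and intensity columns")
  sigma <- if (ncol(tab) >= 3) tab[[3]] else rep(0, nrow(tab))
  saxs_curve(tab[[1]], tab[[2]], sigma,
             accumulation_time = meta$accumulation_time,
             thickness = meta$thickness, transmission = meta$transmission)
}

# ---- run configuration ------------------------------------------------

KNOWN_CONFIG_KEYS <- list(
  run = c("preset", "seed", "horizon", "out_dir"),
  controller = c("set_point", "kp", "ki", "sample_interval", "u_split",
                 "rpm_min", "rpm_max", "airflow_min", "airflow_max",
                 "rpm_step", "airflow_step"),
  kinetics = c("regime", "K_lac", "K_O2", "K_fnr", "K_no3", "q_O2",
               "inoculum_od", "lag", "k_iron", "iron0", "k_size", "od_to_dw"),
  reactor = c("volume", "gas_o2_fraction", "n2_sparge", "c_star",
              "kla_a", "kla_alpha", "kla_beta", "kla_k_surface"),
  sensor = c("noise_sd", "detection_floor", "accuracy"),
  sampling = c("interval", "noise"))

#' Read a sectioned key-value run-configuration file
#'
#' TOML-style `[section]` headers with `key = value` lines; `#` comments.
#' Unknown sections or keys are rejected so typos cannot silently fall
#' back to defaults.
#'
#' @param path configuration file.
#' @return nested named list of sections.
#' @export
read_run_config <- function(path) {
  stop_if(!file.exists(path), sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  cfg <- list()
  section <- "run"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      stop_if(!section %in% names(KNOWN_CONFIG_KEYS),
              sprintf("unknown config section [%s]; known: %s", section,
                      paste(names(KNOWN_CONFIG_KEYS), collapse = ", ")))
      next
    }
    kv <- regmatches(ln, regexec("^([A-Za-z_0-9]+)\\s*=\\s*(.*)$", ln))[[1]]
    stop_if(length(kv) != 3, sprintf("cannot parse config line: '%s'", ln))
    key <- kv[2]; val <- trimws(kv[3])
    stop_if(!key %in% KNOWN_CONFIG_KEYS[[section]],
            sprintf("unknown key '%s' in section [%s]; known: %s", key, section,
                    paste(KNOWN_CONFIG_KEYS[[section]], collapse = ", ")))
    val <- gsub('^"|"$', "", val)
    num <- suppressWarnings(as.numeric(val))
    cfg[[section]][[key]] <- if (!is.na(num)) num else val
  }
  cfg
}

#' Named cultivation presets
#'
#' Bundles the condition-specific kinetic parameters, reactor gas phase,
#' controller set point and sensor noise for the three study conditions:
#' `oxic95` (95% dO2, 4 mM nitrate), `microoxic1` (1% dO2, 4 mM nitrate)
#' and `anoxic0` (N2-sparged, 10 mM nitrate, fixed actuation at 100 rpm).
#'
#' @param name preset name.
#' @return list with `params`, `reactor`, `controller` (NULL for the
#'   anoxic fixed-actuation mode), `sensor`, `fixed_actuation`.
#' @export
preset_config <- function(name = c("oxic95", "microoxic1", "anoxic0")) {
  name <- match.arg(name)
  params <- kinetic_params(regime = name)
  if (name == "anoxic0") {
    list(params = params,
         reactor = reactor_config(gas_o2_fraction = 0, n2_sparge = 0.2),
         controller = NULL,
         sensor = sensor_model(noise_sd = 0.1),
         fixed_actuation = c(rpm = 100, airflow = 0))
  } else {
    list(params = params,
         reactor = reactor_config(),
         controller = controller_config(set_point = params$do2_nominal),
         sensor = sensor_model(noise_sd = if (name == "oxic95") 0.5 else 0.2),
         fixed_actuation = NULL)
  }
}
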