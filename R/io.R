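#' Read a PLUMED-style whitespace table
#'
#' Parses a COLVAR-like file: a `#! FIELDS <name>...` header line naming the
#' columns, optional further `#!` comment lines (preserved), and whitespace
#' -separated numeric rows. Ragged rows and a non-monotone `time` column are
#' parse errors reporting the offending line number.
#'
#' @param path file path
#' @param check_time require a strictly increasing `time` column when present
#' @return a data frame (class `colvar_table`) with attributes `fields`,
#'   `comments` and `source`
#' @export
read_colvar <- function(path, check_time = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  is_comment <- startsWith(trimws(lines), "#!")
  hdr_idx <- which(is_comment & grepl("FIELDS", lines))
  if (length(hdr_idx) == 0) stop("malformed header: no '#! FIELDS' line in ",
                                 path)
  hdr <- strsplit(trimws(lines[hdr_idx[1]]), "\\s+")[[1]]
  fields <- hdr[-(1:2)]
  if (length(fields) == 0) stop("malformed header: '#! FIELDS' names no ",
                                "columns in ", path)
  comments <- lines[is_comment & !seq_along(lines) %in% hdr_idx[1]]
  data_idx <- which(!is_comment & nzchar(trimws(lines)))
  vals <- vector("list", length(data_idx))
  for (k in seq_along(data_idx)) {
    i <- data_idx[k]
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) != length(fields))
      stop("ragged row at line ", i, ": expected ", length(fields),
           " columns, found ", length(toks))
    v <- suppressWarnings(as.numeric(toks))
    v[toks %in% c("nan", "NaN", "NA")] <- NA_real_
    if (any(is.na(v) & !toks %in% c("nan", "NaN", "NA")))
      stop("non-numeric value at line ", i)
    vals[[k]] <- v
  }
  m <- if (length(vals)) do.call(rbind, vals) else
    matrix(numeric(0), ncol = length(fields))
  df <- as.data.frame(m)
  names(df) <- fields
  if (check_time && "time" %in% fields && nrow(df) > 1) {
    bad <- which(diff(df$time) <= 0)
    if (length(bad))
      stop("non-monotone time at line ", data_idx[bad[1] + 1])
  }
  structure(df, class = c("colvar_table", "data.frame"),
            fields = fields, comments = comments, source = path)
}

#' Write a PLUMED-style whitespace table
#'
#' Values are printed with 12 significant digits, so a write/read round trip
#' is bit-exact at that precision. Extra `#!` comment lines attached to the
#' table (attribute `comments`) are preserved after the header.
#'
#' @param table data frame of numeric columns
#' @param path output path
#' @param digits significant digits to print
#' @return `path`, invisibly
#' @export
write_colvar <- function(table, path, digits = 12) {
  fields <- names(table)
  lines <- paste("#! FIELDS", paste(fields, collapse = " "))
  comments <- attr(table, "comments")
  if (!is.null(comments)) lines <- c(lines, comments)
  if (nrow(table) > 0) {
    fmt <- function(x) ifelse(is.na(x), "nan",
                              formatC(x, digits = digits, format = "g"))
    body <- apply(as.matrix(table), 1,
                  function(r) paste(fmt(r), collapse = " "))
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read/write a hill list in HILLS-like format
#'
#' Whitespace table with header
#' `#! FIELDS time <cv...> <sigma_cv...> height biasf`, one row per deposited
#' Gaussian.
#'
#' @param path file path
#' @return a [hills_list()]
#' @export
read_hills <- function(path) {
  df <- read_colvar(path)
  fields <- attr(df, "fields")
  sig <- grep("^sigma_", fields, value = TRUE)
  cvn <- sub("^sigma_", "", sig)
  if (length(cvn) == 0 || !all(cvn %in% fields))
    stop("malformed HILLS header: need matching <cv> and sigma_<cv> columns")
  out <- as.data.frame(df)[, c("time", cvn, sig, "height", "biasf")]
  structure(out, class = c("hills", "data.frame"), cv_names = cvn)
}

#' @rdname read_hills
#' @param hills a [hills_list()]
#' @export
write_hills <- function(hills, path) {
  write_colvar(as.data.frame(hills), path)
}

#' Write a free-energy surface grid as plain text
#'
#' Header records the CV names, per-axis edges (min, max, number of cells),
#' the thermal energy and the shift flag; rows hold the cell midpoints, the
#' free energy (`nan` for unvisited cells) and the effective sample count.
#'
#' @param fes an [fes_grid()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fes <- function(fes, path) {
  dims <- vapply(fes$edges, function(e) length(e) - 1L, integer(1))
  grid <- if (length(dims) == 1L) data.frame(fes$mids[[1]]) else
    expand.grid(fes$mids[[1]], fes$mids[[2]], KEEP.OUT.ATTRS = FALSE)
  names(grid) <- fes$cv_names
  grid$free <- as.vector(fes$F)
  grid$n_eff <- if (!is.null(fes$n_eff)) as.vector(fes$n_eff) else NA_real_
  comments <- c(
    vapply(seq_along(dims), function(d) sprintf(
      "#! SET axis_%s %.12g %.12g %d", fes$cv_names[d],
      min(fes$edges[[d]]), max(fes$edges[[d]]), dims[d]), character(1)),
    sprintf("#! SET kT %.12g", fes$kT),
    sprintf("#! SET shifted %d", as.integer(fes$shifted)))
  attr(grid, "comments") <- comments
  write_colvar(grid, path)
}

#' Read a free-energy surface grid written by [write_fes()]
#'
#' @param path file path
#' @return an [fes_grid()]
#' @export
read_fes <- function(path) {
  df <- read_colvar(path, check_time = FALSE)
  comments <- attr(df, "comments")
  ax <- grep("^#! SET axis_", comments, value = TRUE)
  if (length(ax) == 0) stop("not a FES file: no axis definitions in ", path)
  edges <- list()
  for (line in ax) {
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    nm <- sub("^axis_", "", toks[3])
    lo <- as.numeric(toks[4]); hi <- as.numeric(toks[5])
    nb <- as.integer(toks[6])
    edges[[nm]] <- seq(lo, hi, length.out = nb + 1L)
  }
  get_set <- function(key, default) {
    line <- grep(paste0("^#! SET ", key, " "), comments, value = TRUE)
    if (length(line)) as.numeric(strsplit(trimws(line[1]),
                                          "\\s+")[[1]][4]) else default
  }
  kT <- get_set("kT", 1)
  shifted <- as.logical(get_set("shifted", 1))
  dims <- vapply(edges, function(e) length(e) - 1L, integer(1))
  F <- df$free
  n_eff <- df$n_eff
  if (length(dims) == 2L) {
    dim(F) <- unname(dims)
    dim(n_eff) <- unname(dims)
  }
  fes_grid(edges, F, kT = kT, shifted = shifted, n_eff = n_eff)
}

#' Read/write an escape-time table
#'
#' Plain-text table `#! FIELDS run time event` with one row per run
#' (`event` is 1 for an observed escape, 0 for a censored run).
#'
#' @param path file path
#' @param kT thermal energy to attach to the ensemble
#' @param horizon censoring horizon (defaults to the maximum time)
#' @return an [escape_time_set()] (without traces)
#' @export
read_escape_times <- function(path, kT = 1, horizon = NULL) {
  df <- read_colvar(path, check_time = FALSE)
  stopifnot(all(c("run", "time", "event") %in% names(df)))
  if (is.null(horizon)) horizon <- max(df$time)
  escape_time_set(df$time, df$event != 0, horizon = horizon, kT = kT)
}

#' @rdname read_escape_times
#' @param data an [escape_time_set()]
#' @export
write_escape_times <- function(data, path) {
  write_colvar(data.frame(run = data$table$run, time = data$table$time,
                          event = as.integer(data$table$event)), path)
}

config_schema <- list(
  model_system = c("kind", "barrier", "x0", "depth", "rho_min", "rho_barrier",
                   "width_well", "width_barrier", "plateau", "stiffness"),
  cvs = c("cn_r0", "cn_m", "cn_n", "cn_cmax", "wall_k", "wall_rho_s",
          "monitor_threshold"),
  langevin = c("timestep", "friction", "kT", "n_steps", "seed",
               "save_stride"),
  metad = c("height", "stride", "sigma", "bias_factor"),
  fes = c("edges", "transient_fraction", "bound", "unbound"),
  thermo = c("temperature", "rho_s", "v_prot", "v0", "c0", "dg_metad"),
  kinetics = c("n_runs", "horizon", "k0", "gamma", "a", "b", "t_cut",
               "n_boot", "bootstrap_seed", "seed"),
  output = c("dir", "prefix"))

#' Read and validate a pipeline configuration
#'
#' YAML file with sections `model_system`, `cvs`, `langevin`, `metad`,
#' `fes`, `thermo`, `kinetics`, `output`. Unknown sections or keys are
#' rejected; fields left at their defaults are reported via `message()`.
#'
#' @param path YAML file path
#' @param quiet suppress the defaulted-field messages
#' @return a named list of sections (class `run_config`)
#' @export
read_run_config <- function(path, quiet = FALSE) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(config_schema))
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  for (sec in names(cfg)) {
    bad <- setdiff(names(cfg[[sec]]), config_schema[[sec]])
    if (length(bad))
      stop("unknown key(s) in section '", sec, "': ",
           paste(bad, collapse = ", "))
  }
  if (!quiet) {
    for (sec in names(config_schema)) {
      missing <- setdiff(config_schema[[sec]],
                         names(cfg[[sec]]))
      if (sec %in% names(cfg) && length(missing))
        message("config section '", sec, "' defaults: ",
                paste(missing, collapse = ", "))
    }
  }
  structure(cfg, class = "run_config")
}
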