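#' Read a time-course CSV
#'
#' Long-format dialect: columns `time_h, compartment, value` and an
#' optional `sd` column (blank allowed); the unit may be declared in a
#' leading `# unit: <tag>` comment line or forced via `unit`.
#'
#' @param path CSV file path.
#' @param unit expected unit tag; overrides/validates the file header.
#' @return A [time_course()].
#' @export
read_time_course <- function(path, unit = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- readLines(path, n = 10L)
  unit_line <- grep("^#\\s*unit:", header, value = TRUE)
  file_unit <- if (length(unit_line)) {
    trimws(sub("^#\\s*unit:", "", unit_line[1L]))
  } else NULL
  if (!is.null(unit) && !is.null(file_unit) && unit != file_unit) {
    stop("unit mismatch: file declares '", file_unit, "', expected '",
         unit, "'", call. = FALSE)
  }
  use_unit <- if (!is.null(unit)) unit else
    if (!is.null(file_unit)) file_unit else "fraction"
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  need <- c("time_h", "compartment", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(df$time_h) | !is.finite(df$value))
  if (length(bad)) {
    stop("malformed row(s) at data line(s) ",
         paste(bad, collapse = ", "), " of ", path, call. = FALSE)
  }
  times <- sort(unique(df$time_h))
  comps <- unique(df$compartment)
  vals <- matrix(NA_real_, length(times), length(comps),
                 dimnames = list(NULL, comps))
  vals[cbind(match(df$time_h, times), match(df$compartment, comps))] <-
    df$value
  if (any(is.na(vals))) {
    stop("time course is not complete: every compartment needs a value ",
         "at every time", call. = FALSE)
  }
  sd <- NULL
  if ("sd" %in% names(df) && any(is.finite(df$sd))) {
    sd <- matrix(NA_real_, length(times), length(comps),
                 dimnames = list(NULL, comps))
    sd[cbind(match(df$time_h, times), match(df$compartment, comps))] <-
      df$sd
  }
  time_course(times, vals, sd = sd, unit = use_unit)
}

#' Write a time-course CSV
#'
#' @param tc a [time_course()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_time_course <- function(tc, path) {
  stopifnot(inherits(tc, "time_course"))
  df <- as.data.frame(tc)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# unit: ", tc$unit), con)
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = NA),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a transfer-rate table (CSV or JSON)
#'
#' CSV columns `donor, receptor, rate_per_h`; JSON as an array of objects
#' with the same keys. Duplicate edges are an error.
#'
#' @param path file path (`.json` files are parsed as JSON).
#' @return A [transfer_rates()] object.
#' @export
read_rates <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  }
  need <- c("donor", "receptor", "rate_per_h")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  transfer_rates(df$donor, df$receptor, df$rate_per_h)
}

#' Write a transfer-rate table
#'
#' @param rates a [transfer_rates()] object.
#' @param path output path (`.json` writes JSON, else CSV).
#' @return `path`, invisibly.
#' @export
write_rates <- function(rates, path) {
  stopifnot(inherits(rates, "transfer_rates"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(rates), path, digits = NA,
                         auto_unbox = TRUE)
  } else {
    df <- as.data.frame(rates)
    df$rate_per_h <- format(df$rate_per_h, digits = 17, trim = TRUE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read cell-death model parameters from JSON
#'
#' Keys mirror the printed parameter table: `q0`, `k1_e3`, `k2_e5`, and
#' either `p_e3` (class I) or `p0_e3` and `pstar_e3` (class II).
#'
#' @param path JSON file path.
#' @return A `survival_params` object (class I or II inferred from keys).
#' @export
read_params <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- jsonlite::fromJSON(path)
  need <- c("q0", "k1_e3", "k2_e5")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("missing key(s) in ", path, ": ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if ("p_e3" %in% names(x)) {
    survival_params_I(x$q0, x$k1_e3, x$k2_e5, x$p_e3)
  } else if (all(c("p0_e3", "pstar_e3") %in% names(x))) {
    survival_params_II(x$q0, x$k1_e3, x$k2_e5, x$p0_e3, x$pstar_e3)
  } else {
    stop("params file needs either p_e3 or p0_e3 + pstar_e3",
         call. = FALSE)
  }
}

#' Write cell-death model parameters to JSON
#'
#' @param params a `survival_params` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "survival_params"))
  x <- list(q0 = params$q0, k1_e3 = params$k1, k2_e5 = params$k2)
  if (params$model == "I") {
    x$p_e3 <- params$p
  } else {
    x$p0_e3 <- params$p0
    x$pstar_e3 <- params$pstar
  }
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a spectrum histogram CSV
#'
#' Columns `e_low_kev, e_high_kev, fluence`. The peak voltage defaults to
#' the highest bin edge rounded up to the nearest kV.
#'
#' @param path CSV file path.
#' @param kvp peak tube voltage; `NULL` infers it from the bins.
#' @return A [spectrum_histogram()].
#' @export
read_spectrum <- function(path, kvp = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  need <- c("e_low_kev", "e_high_kev", "fluence")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing column(s) in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (is.null(kvp)) kvp <- ceiling(max(df$e_high_kev))
  spectrum_histogram(df$e_low_kev, df$e_high_kev, df$fluence, kvp)
}

#' Read an energy-deposit event CSV
#'
#' Radial dialect: leading comment `# n_primaries: N`, columns
#' `primary_id, r_nm, edep_ev`. Cartesian dialect: columns
#' `x_nm, y_nm, z_nm, edep_ev`, reduced to radii about `center`.
#'
#' @param path CSV file path.
#' @param center numeric length-3 nanoparticle center (nm) for Cartesian
#'   files.
#' @return List with `events` (radial data frame) and `n_primaries`.
#' @export
read_events <- function(path, center = c(0, 0, 0)) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- readLines(path, n = 5L)
  np_line <- grep("^#\\s*n_primaries:", header, value = TRUE)
  if (!length(np_line)) {
    stop("events file must declare '# n_primaries: N'", call. = FALSE)
  }
  n_primaries <- as.numeric(trimws(sub("^#\\s*n_primaries:", "",
                                       np_line[1L])))
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  if (all(c("x_nm", "y_nm", "z_nm") %in% names(df))) {
    df$r_nm <- sqrt((df$x_nm - center[1L])^2 + (df$y_nm - center[2L])^2 +
                      (df$z_nm - center[3L])^2)
  }
  if (!all(c("r_nm", "edep_ev") %in% names(df))) {
    stop("events file needs r_nm/edep_ev or x_nm/y_nm/z_nm/edep_ev",
         call. = FALSE)
  }
  if (!"primary_id" %in% names(df)) df$primary_id <- seq_len(nrow(df))
  list(events = df[, c("primary_id", "r_nm", "edep_ev")],
       n_primaries = n_primaries)
}

#' Read a radial profile CSV
#'
#' Inverse of [write_profile()] for energy profiles: rebuilds the shell
#' grid from the boundary columns and the primary count from the header
#' comment.
#'
#' @param path CSV file path.
#' @return A `radial_profile`.
#' @export
read_profile <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- readLines(path, n = 5L)
  np_line <- grep("^#\\s*n_primaries:", header, value = TRUE)
  if (!length(np_line)) {
    stop("profile file must declare '# n_primaries: N'", call. = FALSE)
  }
  n_primaries <- as.numeric(trimws(sub("^#\\s*n_primaries:", "",
                                       np_line[1L])))
  df <- utils::read.csv(path, comment.char = "#",
                        stringsAsFactors = FALSE)
  need <- c("shell_index", "r_inner_nm", "r_outer_nm", "value")
  if (!all(need %in% names(df))) {
    stop("profile file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df <- df[order(df$shell_index), , drop = FALSE]
  d <- df$r_outer_nm[1L] - df$r_inner_nm[1L]
  grid <- build_shell_grid(df$r_inner_nm[1L], d, nrow(df))
  structure(list(grid = grid, energy_ev_per_primary = df$value,
                 n_primaries = n_primaries, n_events = NA_integer_,
                 discarded = c(inside_np = NA_integer_,
                               beyond_grid = NA_integer_),
                 discarded_energy_ev = NA_real_),
            class = "radial_profile")
}

#' Write a radial profile or DER profile CSV
#'
#' Columns `shell_index` (0-based), `r_inner_nm`, `r_outer_nm`, `value`;
#' profile metadata (`n_primaries`, discarded counts, or the DER
#' validity) is written as leading comment lines.
#'
#' @param x a `radial_profile` or `der_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(x, path) {
  g <- x$grid
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(x, "radial_profile")) {
    writeLines(c(paste0("# n_primaries: ", x$n_primaries),
                 paste0("# discarded_inside_np: ",
                        x$discarded[["inside_np"]]),
                 paste0("# discarded_beyond_grid: ",
                        x$discarded[["beyond_grid"]])), con)
    value <- x$energy_ev_per_primary
  } else if (inherits(x, "der_profile")) {
    writeLines(paste0("# invalid_shells: ", sum(!x$valid)), con)
    value <- x$ratio
  } else {
    stop("'x' must be a radial_profile or der_profile", call. = FALSE)
  }
  df <- data.frame(shell_index = 0:(g$n - 1L),
                   r_inner_nm = g$boundaries[-(g$n + 1L)],
                   r_outer_nm = g$boundaries[-1L],
                   value = format(value, digits = 17, trim = TRUE))
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
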