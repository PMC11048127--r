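#' Read a one-port Touchstone (.s1p) file
#'
#' Parses the Touchstone 1.1 text format produced by VNA software:
#' `!` comments, one `#` option line declaring the frequency unit
#' (Hz/kHz/MHz/GHz), parameter type, data format and reference
#' impedance, then one row per frequency. The RI (real/imaginary),
#' MA (magnitude/angle in degrees) and DB (dB magnitude/angle)
#' dialects are all supported. Missing option fields take the
#' Touchstone defaults (`# GHZ S MA R 50`).
#'
#' @param path Path to a `.s1p` file.
#' @return An [s11_sweep()].
#' @examples
#' sw <- synth_s11(vna_grid(), 1.28e9, 80)
#' p <- tempfile(fileext = ".s1p")
#' write_touchstone(sw, p)
#' sw2 <- read_touchstone(p)
#' @export
read_touchstone <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("!.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  opt <- lines[startsWith(lines, "#")]
  data_lines <- lines[!startsWith(lines, "#")]
  unit <- "GHZ"; fmt <- "MA"; z0 <- 50; par <- "S"
  if (length(opt) > 0) {
    tok <- toupper(strsplit(trimws(sub("^#", "", opt[1L])), "\\s+")[[1L]])
    tok <- tok[nzchar(tok)]
    i <- 1L
    while (i <= length(tok)) {
      t <- tok[i]
      if (t %in% c("HZ", "KHZ", "MHZ", "GHZ")) unit <- t
      else if (t %in% c("S", "Y", "Z", "G", "H")) par <- t
      else if (t %in% c("RI", "MA", "DB")) fmt <- t
      else if (t == "R" && i < length(tok)) {
        z0 <- as.numeric(tok[i + 1L]); i <- i + 1L
      }
      i <- i + 1L
    }
  }
  if (par != "S") abort("only S-parameter Touchstone files are supported.")
  if (length(data_lines) == 0) abort("empty data section in Touchstone file.")
  rows <- lapply(strsplit(data_lines, "\\s+"), as.numeric)
  ncols <- lengths(rows)
  if (any(ncols != 3L)) {
    abort(paste(
      "expected a one-port file (3 numbers per row); got rows with",
      max(ncols), "columns (a multi-port file?)"
    ))
  }
  m <- do.call(rbind, rows)
  if (anyNA(m)) abort("non-numeric data in Touchstone file.")
  scale <- switch(unit, HZ = 1, KHZ = 1e3, MHZ = 1e6, GHZ = 1e9)
  freq <- m[, 1L] * scale
  if (any(diff(freq) <= 0)) {
    abort("non-monotone frequency column in Touchstone file.")
  }
  s11 <- switch(fmt,
    RI = complex(real = m[, 2L], imaginary = m[, 3L]),
    MA = complex(modulus = m[, 2L], argument = m[, 3L] * pi / 180),
    DB = complex(modulus = 10^(m[, 2L] / 20), argument = m[, 3L] * pi / 180)
  )
  s11_sweep(freq, s11, z0 = z0)
}

#' Write a one-port sweep as a Touchstone (.s1p) file
#'
#' @param sweep An [s11_sweep()].
#' @param path Output path.
#' @param unit Frequency unit for the file: `"GHz"`, `"MHz"`, `"kHz"`
#'   or `"Hz"`.
#' @param format Data format: `"RI"`, `"MA"` or `"DB"`.
#' @return `path`, invisibly.
#' @export
write_touchstone <- function(sweep, path, unit = "GHz", format = "RI") {
  format <- toupper(format)
  u <- toupper(unit)
  if (!u %in% c("HZ", "KHZ", "MHZ", "GHZ")) abort("unknown frequency unit.")
  if (!format %in% c("RI", "MA", "DB")) abort("unknown data format.")
  scale <- switch(u, HZ = 1, KHZ = 1e3, MHZ = 1e6, GHZ = 1e9)
  z0 <- attr(sweep, "z0") %||% 50
  f <- sweep$frequency_hz / scale
  s <- sweep$s11
  ab <- switch(format,
    RI = cbind(Re(s), Im(s)),
    MA = cbind(Mod(s), Arg(s) * 180 / pi),
    DB = cbind(20 * log10(pmax(Mod(s), 1e-300)), Arg(s) * 180 / pi)
  )
  header <- c(
    "! one-port reflection sweep written by evapsense",
    sprintf("# %s S %s R %g", u, format, z0)
  )
  body <- sprintf("%.17g %.17g %.17g", f, ab[, 1L], ab[, 2L])
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read and write measurement tables as CSV
#'
#' Measurement tables pair cell concentrations with endpoint resonant
#' frequencies per replicate. The CSV schema is
#' `concentration_cells_per_mL,f_res_GHz,replicate` (header mandatory,
#' `.` decimal separator); column matching on read is case-insensitive.
#'
#' @param path CSV path.
#' @return `read_measurement_csv()`: a tibble with columns
#'   `concentration_cells_per_ml`, `f_res_ghz`, `replicate`.
#' @examples
#' tbl <- simulate_endpoint_dataset(endpoint_sim_config(seed = 1))
#' p <- tempfile(fileext = ".csv")
#' write_measurement_csv(tbl, p)
#' read_measurement_csv(p)
#' @export
read_measurement_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  names(df) <- tolower(names(df))
  need <- c("concentration_cells_per_ml", "f_res_ghz")
  if (!all(need %in% names(df))) {
    abort(paste("CSV must contain columns concentration_cells_per_mL",
                "and f_res_GHz."))
  }
  if (!"replicate" %in% names(df)) df$replicate <- 1L
  as_tibble(df[, c("concentration_cells_per_ml", "f_res_ghz", "replicate")])
}

#' @rdname read_measurement_csv
#' @param table A measurement table tibble.
#' @export
write_measurement_csv <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- tibble(
    concentration_cells_per_mL = table$concentration_cells_per_ml,
    f_res_GHz = table$f_res_ghz,
    replicate = table$replicate %||% 1L
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Read and write permittivity tables as CSV
#'
#' Schema: `frequency_Hz,eps_real,eps_imag`.
#'
#' @param path CSV path.
#' @return A tibble with columns `frequency_hz`, `eps_real`,
#'   `eps_imag`.
#' @export
read_permittivity_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  names(df) <- tolower(names(df))
  need <- c("frequency_hz", "eps_real", "eps_imag")
  if (!all(need %in% names(df))) {
    abort("CSV must contain columns frequency_Hz, eps_real, eps_imag.")
  }
  as_tibble(df[, need])
}

#' @rdname read_permittivity_csv
#' @param table A permittivity table tibble.
#' @export
write_permittivity_csv <- function(table, path) {
  out <- tibble(
    frequency_Hz = table$frequency_hz,
    eps_real = table$eps_real,
    eps_imag = table$eps_imag
  )
  readr::write_csv(out, path)
  invisible(path)
}
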