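# SPR trace / isotherm containers and their CSV dialects.
#
# Sensorgram CSV: '#key=value' header lines (injection_start_s,
# injection_end_s, label) followed by "time_s,response_RU".
# Isotherm CSV: optional '#ligand=...' header, then
# "concentration_M,Req_RU".

#' Construct a sensorgram
#'
#' An SPR response-vs-time trace with its analyte injection window.
#'
#' @param time_s strictly increasing time points (s).
#' @param response_RU response at each time point (resonance units).
#' @param injection_start_s,injection_end_s injection window (s); must lie
#'   within the time range, start < end.
#' @param label free-text analyte/surface label.
#' @return Object of class `sensorgram`.
#' @export
sensorgram <- function(time_s, response_RU, injection_start_s,
                       injection_end_s, label = "") {
  time_s <- as.numeric(time_s)
  response_RU <- as.numeric(response_RU)
  stopifnot(length(time_s) == length(response_RU), length(time_s) >= 2L)
  if (any(diff(time_s) <= 0)) stop("time must be strictly increasing")
  if (!all(is.finite(time_s)) || !all(is.finite(response_RU))) {
    stop("sensorgram values must be finite")
  }
  if (is.na(injection_start_s) || is.na(injection_end_s)) {
    stop("injection window metadata is required")
  }
  if (injection_start_s >= injection_end_s) {
    stop("injection_start_s must precede injection_end_s")
  }
  if (injection_start_s < time_s[1] || injection_end_s > time_s[length(time_s)]) {
    stop("injection window must lie within the recorded time range")
  }
  structure(list(time_s = time_s, response_RU = response_RU,
                 injection_start_s = injection_start_s,
                 injection_end_s = injection_end_s, label = label),
            class = "sensorgram")
}

#' @export
print.sensorgram <- function(x, ...) {
  cat(sprintf("<sensorgram> '%s': %d points, %.4g-%.4g s, injection %.4g-%.4g s, max %.4g RU\n",
              x$label, length(x$time_s), x$time_s[1],
              x$time_s[length(x$time_s)], x$injection_start_s,
              x$injection_end_s, max(x$response_RU)))
  invisible(x)
}

#' Construct an equilibrium binding isotherm
#'
#' Equilibrium response (Req, RU) versus analyte concentration (M).
#'
#' @param concentration_M positive, unique analyte concentrations (M).
#' @param Req_RU equilibrium responses (RU).
#' @param ligand analyte label.
#' @return Object of class `isotherm`.
#' @export
isotherm <- function(concentration_M, Req_RU, ligand = "") {
  concentration_M <- as.numeric(concentration_M)
  Req_RU <- as.numeric(Req_RU)
  stopifnot(length(concentration_M) == length(Req_RU))
  if (any(concentration_M <= 0)) stop("concentrations must be positive")
  dup <- duplicated(concentration_M)
  if (any(dup)) {
    stop("duplicated concentrations: ",
         paste(signif(unique(concentration_M[dup]), 6), collapse = ", "))
  }
  ord <- order(concentration_M)
  structure(list(concentration_M = concentration_M[ord],
                 Req_RU = Req_RU[ord], ligand = ligand),
            class = "isotherm")
}

#' @export
print.isotherm <- function(x, ...) {
  cat(sprintf("<isotherm> '%s': %d concentrations, %.3g-%.3g M, Req up to %.4g RU\n",
              x$ligand, length(x$concentration_M), min(x$concentration_M),
              max(x$concentration_M), max(x$Req_RU)))
  invisible(x)
}

.read_hash_header <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    h <- sub("^#\\s*", "", h)
    if (grepl("=", h, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", h))
      kv[[key]] <- trimws(sub("^[^=]*=", "", h))
    }
  }
  kv
}

.read_two_col_csv <- function(path, col1, col2) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  kv <- .read_hash_header(lines)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(body)) stop("no data rows in ", path)
  df <- read.csv(text = paste(body, collapse = "\n"),
                 stringsAsFactors = FALSE)
  if (!all(c(col1, col2) %in% names(df))) {
    stop(sprintf("expected columns '%s,%s' in %s", col1, col2, path))
  }
  if (!is.numeric(df[[col1]]) || !is.numeric(df[[col2]]) ||
      anyNA(df[[col1]]) || anyNA(df[[col2]])) {
    stop("non-numeric or missing values in ", path)
  }
  list(df = df, meta = kv)
}

#' Read a sensorgram CSV
#'
#' @param path CSV with columns `time_s,response_RU` and `#key=value`
#'   header lines carrying `injection_start_s`, `injection_end_s` and
#'   optionally `label`.
#' @return A [sensorgram()].
#' @export
read_sensorgram_csv <- function(path) {
  parsed <- .read_two_col_csv(path, "time_s", "response_RU")
  meta <- parsed$meta
  if (is.null(meta$injection_start_s) || is.null(meta$injection_end_s)) {
    stop("sensorgram CSV lacks injection_start_s/injection_end_s metadata: ",
         path)
  }
  sensorgram(parsed$df$time_s, parsed$df$response_RU,
             as.numeric(meta$injection_start_s),
             as.numeric(meta$injection_end_s),
             label = if (is.null(meta$label)) "" else meta$label)
}

#' Write a sensorgram CSV
#' @param s a [sensorgram()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sensorgram_csv <- function(s, path) {
  stopifnot(inherits(s, "sensorgram"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#injection_start_s=%.10g", s$injection_start_s),
               sprintf("#injection_end_s=%.10g", s$injection_end_s),
               sprintf("#label=%s", s$label),
               "time_s,response_RU"), con)
  writeLines(sprintf("%.10g,%.10g", s$time_s, s$response_RU), con)
  invisible(path)
}

#' Read an isotherm CSV
#' @param path CSV with columns `concentration_M,Req_RU` and an optional
#'   `#ligand=...` header line.
#' @return An [isotherm()].
#' @export
read_isotherm_csv <- function(path) {
  parsed <- .read_two_col_csv(path, "concentration_M", "Req_RU")
  lig <- parsed$meta$ligand
  isotherm(parsed$df$concentration_M, parsed$df$Req_RU,
           ligand = if (is.null(lig)) "" else lig)
}

#' Write an isotherm CSV
#' @param iso an [isotherm()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_isotherm_csv <- function(iso, path) {
  stopifnot(inherits(iso, "isotherm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("#ligand=%s", iso$ligand),
               "concentration_M,Req_RU"), con)
  writeLines(sprintf("%.10g,%.10g", iso$concentration_M, iso$Req_RU), con)
  invisible(path)
}
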