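# Flat key-value configuration files and CSV/JSON writers for responses,
# spectra, signals and fit results.

#' Read a flat key-value configuration file
#'
#' One `key = value` pair per line; blank lines and lines starting with `#`
#' are ignored. Values that parse as numbers become numeric, `true`/`false`
#' become logical, everything else stays character. Comma-separated values
#' become vectors.
#'
#' @param path Path to the configuration file.
#' @return Named list of parsed values.
#' @export
#' @examples
#' tmp <- tempfile()
#' writeLines(c("alpha = 0.3", "taus = 0.05, 0.5, 5", "mode = shared"), tmp)
#' read_config(tmp)
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0)
      stop("malformed config line ", i, " (missing '='): \"", ln, "\"")
    key <- trimws(substr(ln, 1, eq - 1))
    if (!nzchar(key))
      stop("malformed config line ", i, " (empty key): \"", ln, "\"")
    raw <- trimws(strsplit(trimws(substr(ln, eq + 1, nchar(ln))),
                           ",", fixed = TRUE)[[1]])
    num <- suppressWarnings(as.numeric(raw))
    val <- if (!anyNA(num)) num
           else if (all(tolower(raw) %in% c("true", "false")))
             tolower(raw) == "true"
           else raw
    out[[key]] <- val
  }
  out
}

#' Write a complex frequency response as CSV
#'
#' Columns `freq_hz,re,im`.
#'
#' @param freqs Frequencies in Hz.
#' @param response Complex response, same length.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_response_csv <- function(freqs, response, path) {
  if (length(freqs) != length(response))
    stop("`freqs` and `response` must have the same length")
  write.csv(data.frame(freq_hz = freqs, re = Re(response),
                       im = Im(response)),
            path, row.names = FALSE)
  invisible(path)
}

#' Write a PSD as CSV
#'
#' Columns `freq_hz,power`. Accepts a [psd_estimate()] or explicit vectors.
#'
#' @param psd A [psd_estimate()], or numeric power vector.
#' @param path Output path.
#' @param freqs Frequencies in Hz (ignored when `psd` is a
#'   [psd_estimate()]).
#' @return The path, invisibly.
#' @export
write_psd_csv <- function(psd, path, freqs = NULL) {
  if (inherits(psd, "psd_estimate")) {
    freqs <- psd$freqs
    psd <- psd$power
  }
  if (is.null(freqs) || length(freqs) != length(psd))
    stop("`freqs` and `psd` must have the same length")
  write.csv(data.frame(freq_hz = freqs, power = psd), path,
            row.names = FALSE)
  invisible(path)
}

#' Write a sampled signal as CSV
#'
#' Columns `t_s,value` (or `t_s,v_mV` when `voltage = TRUE`).
#'
#' @param sig A [sampled_signal()].
#' @param path Output path.
#' @param voltage Use the voltage column name (default `FALSE`).
#' @return The path, invisibly.
#' @export
write_signal_csv <- function(sig, path, voltage = FALSE) {
  stopifnot(inherits(sig, "sampled_signal"))
  df <- data.frame(t_s = sig$t, value = sig$values)
  if (voltage) names(df)[2] <- "v_mV"
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a spike train as CSV
#'
#' Single column `spike_time_s`.
#'
#' @param spikes A [spike_train()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_spikes_csv <- function(spikes, path) {
  stopifnot(inherits(spikes, "spike_train"))
  write.csv(data.frame(spike_time_s = spikes$times), path,
            row.names = FALSE)
  invisible(path)
}

#' Serialize a constant-phase fit result as JSON
#'
#' @param fit A [fit_gains_constant_phase()] result.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "phase_fit"))
  jsonlite::write_json(
    list(taus = fit$taus, A_values = fit$A_values, alpha = fit$alpha,
         band = fit$band, mode = fit$mode, residual = fit$residual,
         sse = fit$sse, iterations = fit$iterations,
         converged = fit$converged),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
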