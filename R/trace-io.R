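#' Write / read a dual-channel trace CSV
#'
#' The on-disk format is a plain CSV with header `t_s,s1_m,s2_m`, preceded
#' by `# meta:` comment lines carrying the run condition
#' (`head_m`, `amplitude_m`, `label`). Numbers are written with 17
#' significant digits, so `write_trace()` followed by [read_trace()]
#' reproduces the arrays bit for bit.
#'
#' @param trace A [dual_trace()].
#' @param path File path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()`
#'   returns a [dual_trace()].
#' @export
write_trace <- function(trace, path) {
  assert_dual_trace(trace)
  meta <- c(
    sprintf("# meta: head_m=%.17g", attr(trace, "head")),
    sprintf("# meta: amplitude_m=%.17g", attr(trace, "amplitude")),
    sprintf("# meta: label=%s", attr(trace, "label") %||% ""))
  body <- sprintf("%.17g,%.17g,%.17g", trace$times, trace$s1, trace$s2)
  writeLines(c(meta, "t_s,s1_m,s2_m", body), path)
  invisible(path)
}

#' @rdname write_trace
#' @param monotone_tol Passed to [dual_trace()] validation.
#' @export
read_trace <- function(path, monotone_tol = 1e-9) {
  lines <- readLines(path)
  is_meta <- grepl("^#", lines)
  meta_lines <- lines[is_meta]
  content <- lines[!is_meta]
  if (length(content) < 2L) {
    abort_format_error(sprintf("'%s': no data rows", path))
  }
  header <- trimws(content[1])
  if (header != "t_s,s1_m,s2_m") {
    abort_format_error(sprintf(
      "'%s': expected header 't_s,s1_m,s2_m', found '%s'", path, header))
  }
  df <- utils::read.csv(text = content, header = TRUE,
                        colClasses = "numeric")
  meta <- parse_meta_lines(meta_lines)
  if (length(meta_lines) == 0L) {
    warning("no '# meta:' lines found; trace metadata left empty",
            call. = FALSE)
  }
  dt <- diff(df$t_s)
  if (any(dt <= 0)) {
    abort_format_error(sprintf("'%s': time column is not strictly increasing", path))
  }
  tryCatch(
    dual_trace(df$t_s, df$s1_m, df$s2_m,
               head = meta$head_m %||% NA_real_,
               amplitude = meta$amplitude_m %||% NA_real_,
               label = meta$label %||% "",
               monotone_tol = monotone_tol),
    cuttleflow_invalid_input = function(e) {
      abort_format_error(sprintf("'%s': %s", path, conditionMessage(e)))
    })
}

parse_meta_lines <- function(lines) {
  meta <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*meta:\\s*([A-Za-z0-9_]+)=(.*)$", ln))[[1]]
    if (length(m) == 3L) {
      key <- m[2]; val <- m[3]
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (key == "label") val else if (!is.na(num)) num else val
    }
  }
  meta
}

#' Write / read a capillary-rise trace CSV
#'
#' Columns `t_s,z_m,zdot_m_s`, full float precision.
#'
#' @param trace A `rise_trace`.
#' @param path File path.
#' @return `read_rise_trace()` returns a `rise_trace`.
#' @export
write_rise_trace <- function(trace, path) {
  assert_rise_trace(trace)
  body <- sprintf("%.17g,%.17g,%.17g", trace$times, trace$heights, trace$speeds)
  writeLines(c("t_s,z_m,zdot_m_s", body), path)
  invisible(path)
}

#' @rdname write_rise_trace
#' @export
read_rise_trace <- function(path) {
  df <- utils::read.csv(path, colClasses = "numeric")
  if (!identical(names(df), c("t_s", "z_m", "zdot_m_s"))) {
    abort_format_error(sprintf("'%s': expected columns t_s,z_m,zdot_m_s", path))
  }
  tr <- new_rise_trace(df$t_s, df$z_m, df$zdot_m_s)
  assert_rise_trace(tr)
  tr
}

#' Run manifest for reproducibility
#'
#' Records the command line, configuration snapshot, seeds and md5 digests
#' of input/output files of a pipeline run, so any stochastic result can
#' be replayed exactly.
#'
#' @param command Character, the invoked command or function call.
#' @param config A named list snapshot of the configuration used.
#' @param seeds Integer vector of every seed the run consumed.
#' @param inputs,outputs Character vectors of file paths to digest.
#' @param path If non-`NULL`, the manifest is also written there as JSON.
#' @return A `run_manifest` list (invisibly if written to `path`).
#' @export
run_manifest <- function(command, config = list(), seeds = integer(),
                         inputs = character(), outputs = character(),
                         path = NULL) {
  digest_files <- function(paths) {
    if (length(paths) == 0L) return(list())
    sums <- tools::md5sum(paths)
    as.list(sums)
  }
  manifest <- structure(
    list(command = command,
         config = config,
         seeds = as.integer(seeds),
         input_digests = digest_files(inputs),
         output_digests = digest_files(outputs),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest")
  if (!is.null(path)) {
    jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    return(invisible(manifest))
  }
  manifest
}
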