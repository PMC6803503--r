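#' Write / read a trace as CSV
#'
#' The on-disk schema is `time_ms,V_mV,n,h,c,M`, written with full
#' round-trip precision so a written-then-read trace is value-identical
#' and reruns are byte-identical.
#'
#' @param trace A `"pc_trace"`.
#' @param path Output file.
#' @return `write_trace` returns `path` invisibly; `read_trace` returns a
#'   `"pc_trace"`.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time_ms = sprintf("%.17g", trace$t),
                   V_mV = sprintf("%.17g", trace$V),
                   n = sprintf("%.17g", trace$n),
                   h = sprintf("%.17g", trace$h),
                   c = sprintf("%.17g", trace$c),
                   M = sprintf("%.17g", trace$M))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- read.csv(path)
  need <- c("time_ms", "V_mV", "n", "h", "c", "M")
  if (!all(need %in% names(df)))
    stop("not a trace CSV (expected header time_ms,V_mV,n,h,c,M)")
  tr <- data.frame(t = df$time_ms, V = df$V_mV, n = df$n, h = df$h,
                   c = df$c, M = df$M)
  attr(tr, "backend") <- "file"
  class(tr) <- c("pc_trace", "data.frame")
  tr
}

#' Write / read a key-value configuration file
#'
#' Plain `key = value` lines covering the membrane parameters; unknown
#' keys are rejected on read.
#'
#' @param params A [purkinje_params()].
#' @param path File path.
#' @return `read_params` returns a [purkinje_params()].
#' @export
write_params <- function(params, path) {
  writeLines(sprintf("%s = %.17g", names(unclass(params)), unclass(params)),
             path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  kv <- strsplit(ln, "=")
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2)))
  allowed <- names(unclass(purkinje_params()))
  if (!all(keys %in% allowed))
    stop("unknown parameter key(s): ",
         paste(setdiff(keys, allowed), collapse = ", "))
  do.call(purkinje_params, as.list(stats::setNames(vals, keys)))
}

# minimal JSON emitter for flat report lists (numbers, strings, plain
# vectors, nested named lists)
to_json <- function(x, indent = 0) {
  pad <- strrep(" ", indent)
  if (is.list(x)) {
    items <- vapply(names(x), function(nm)
      sprintf("%s  \"%s\": %s", pad, nm, to_json(x[[nm]], indent + 2)),
      character(1))
    return(sprintf("{\n%s\n%s}", paste(items, collapse = ",\n"), pad))
  }
  fmt1 <- function(v) {
    if (is.character(v)) sprintf("\"%s\"", v)
    else if (is.logical(v)) tolower(as.character(v))
    else sprintf("%.17g", v)
  }
  if (length(x) == 1) fmt1(x)
  else sprintf("[%s]", paste(vapply(x, fmt1, character(1)), collapse = ", "))
}

write_report_json <- function(x, path) {
  writeLines(to_json(x), path)
  invisible(path)
}
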