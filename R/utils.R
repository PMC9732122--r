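#' @keywords internal
#' @importFrom stats predict
"_PACKAGE"

# Condition helper: all package errors carry a subclass "dzd_<class>" so
# callers can handle specific failure modes programmatically.
dzd_stop <- function(class, msg, ..., data = NULL) {
  cond <- structure(
    class = c(paste0("dzd_", class), "dzd_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1), data = data)
  )
  stop(cond)
}

dzd_warn <- function(class, msg, ...) {
  warning(warningCondition(sprintf(msg, ...),
                           class = c(paste0("dzd_", class), "dzd_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Composite trapezoid on an irregular grid.
trapz_int <- function(x, y) {
  if (length(x) < 2L) return(0)
  sum(diff(x) * (y[-length(y)] + y[-1L]) / 2)
}

assert_num <- function(x, name, lower = -Inf, upper = Inf,
                       strict_lower = FALSE, len = 1L) {
  if (!is.numeric(x) || (!is.null(len) && length(x) != len) || anyNA(x)) {
    dzd_stop("config_error", "'%s' must be numeric (length %d) without NA",
             name, len %||% length(x))
  }
  bad <- if (strict_lower) any(x <= lower) else any(x < lower)
  if (bad || any(x > upper)) {
    dzd_stop("config_error", "'%s' must be in %s%g, %g]",
             name, if (strict_lower) "(" else "[", lower, upper)
  }
  invisible(x)
}

# Deterministic per-instrument RNG streams: a single master seed plus a fixed
# per-stream offset so adding noise to one instrument never shifts another's.
stream_seed <- function(seed, stream) {
  offsets <- c(od = 11L, frrf = 23L, o2 = 37L, ara = 47L, c14 = 59L)
  if (!stream %in% names(offsets)) {
    dzd_stop("config_error", "unknown RNG stream '%s'", stream)
  }
  (as.integer(seed) + offsets[[stream]]) %% .Machine$integer.max
}

# Multiplicative Gaussian noise with coefficient of variation `cv`,
# truncated at zero (readouts are non-negative physical quantities).
apply_noise <- function(x, cv, seed, stream) {
  if (cv == 0) return(x)
  if (cv < 0) dzd_stop("config_error", "noise_cv must be >= 0, got %g", cv)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(stream_seed(seed, stream))
  pmax(0, x * (1 + stats::rnorm(length(x), 0, cv)))
}

read_dzd_csv <- function(path, required) {
  if (!file.exists(path)) {
    dzd_stop("parse_error", "input file not found: %s", path)
  }
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) dzd_stop("parse_error", "cannot parse %s: %s",
                                 path, conditionMessage(e))
  )
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    dzd_stop("parse_error", "%s: missing column(s) %s",
             path, paste(miss, collapse = ", "))
  }
  df
}

write_dzd_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
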