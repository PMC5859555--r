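#' @keywords internal
"_PACKAGE"

# Lightweight stderr logger. Levels: 0 silent, 1 warn, 2 info, 3 debug.
# Controlled by options(svfusion.verbose = <level>), default 1.
svf_log <- function(level, ...) {
  if (getOption("svfusion.verbose", 1L) >= level) {
    message("[svfusion] ", ...)
  }
  invisible(NULL)
}

# Deterministic 31-bit seed derivation from a master seed and stream indices.
# Keeps every derived seed strictly below 2^31 so set.seed() is safe.
derive_seed <- function(master, ...) {
  idx <- c(...)
  h <- as.numeric(master) %% 2147483647
  for (k in idx) {
    h <- (h * 48271 + as.numeric(k) + 1) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_data <- function(...) {
  stop(structure(class = c("svf_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_usage <- function(...) {
  stop(structure(class = c("svf_usage_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
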