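.LOG_LEVELS <- c(DEBUG = 10L, INFO = 20L, WARN = 30L, ERROR = 40L)

.log_threshold <- function() {
  lvl <- getOption("trilayer.loglevel", "INFO")
  .LOG_LEVELS[[match.arg(lvl, names(.LOG_LEVELS))]]
}

#' Timestamped logging to standard error
#'
#' All pipeline stages report through this logger. The minimum emitted level
#' is controlled by \code{options(trilayer.loglevel = "DEBUG"|"INFO"|"WARN"|
#' "ERROR")}; the default is \code{"INFO"}.
#'
#' @param level one of DEBUG, INFO, WARN, ERROR
#' @param fmt sprintf-style format string
#' @param ... values interpolated into \code{fmt}
#' @return invisibly, the formatted message (emitted to stderr if at or above
#'   the configured level).
#' @export
tlLog <- function(level = c("INFO", "DEBUG", "WARN", "ERROR"), fmt, ...) {
  level <- match.arg(level)
  msg <- sprintf("[%s] %-5s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 level, sprintf(fmt, ...))
  if (.LOG_LEVELS[[level]] >= .log_threshold()) message(msg)
  invisible(msg)
}
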