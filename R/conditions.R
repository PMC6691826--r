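# Classified error conditions so front-ends can map failures to exit codes
# (usage -> 2, data validation -> 3, numerical failure -> 4).

wlogsy_stop <- function(class, ...) {
  stop(structure(class = c(class, "wlogsy_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_usage <- function(...) wlogsy_stop("wlogsy_usage_error", ...)
stop_data <- function(...) wlogsy_stop("wlogsy_data_error", ...)
stop_numeric <- function(...) wlogsy_stop("wlogsy_numeric_error", ...)

exit_code_for <- function(cond) {
  if (inherits(cond, "wlogsy_usage_error")) 2L
  else if (inherits(cond, "wlogsy_data_error")) 3L
  else if (inherits(cond, "wlogsy_numeric_error")) 4L
  else 1L
}
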