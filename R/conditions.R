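# Condition helpers. Validation failures get their own condition class so the
# command-line layer can map them to exit code 2 while unexpected errors
# stay exit code 1.

stop_validation <- function(..., call. = FALSE) {
  msg <- paste0(...)
  cnd <- structure(
    class = c("zooprior_validation_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cnd)
}

# Collect-then-fail: validators gather every violation before stopping so a
# bad file is reported in full, not one error at a time.
fail_if_any <- function(problems, header) {
  problems <- problems[nzchar(problems)]
  if (length(problems) == 0L) return(invisible(NULL))
  stop_validation(header, ":\n", paste0("  - ", problems, collapse = "\n"))
}

warn_soft <- function(msg, strict = FALSE) {
  if (isTRUE(strict)) stop_validation(msg) else warning(msg, call. = FALSE)
  invisible(NULL)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)
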