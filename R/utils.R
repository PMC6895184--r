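# classed conditions so callers can distinguish parse/domain/precondition
# failures from programming errors
stop_uvvis <- function(msg, class) {
  stop(structure(class = c(class, "uvvisdb_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

warn_uvvis <- function(msg, class) {
  warning(structure(class = c(class, "uvvisdb_warning", "warning", "condition"),
                    list(message = msg, call = sys.call(-1))))
}

# NA is the package-wide null marker; the deposit's "NULL" strings, JSON
# nulls and absent keys all map onto it on load
is_null_marker <- function(x) {
  is.null(x) || length(x) == 0L || (length(x) == 1L && (is.na(x) || identical(x, "NULL")))
}

scalar_or_na <- function(x, as = "character") {
  if (is_null_marker(x)) {
    return(switch(as, character = NA_character_, numeric = NA_real_, integer = NA_integer_))
  }
  switch(as,
         character = as.character(x[[1]]),
         numeric = as.numeric(x[[1]]),
         integer = as.integer(x[[1]]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
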