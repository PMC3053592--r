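#' @keywords internal
"_PACKAGE"

# Canonical unordered gene-pair key. \x1f (unit separator) cannot occur in
# sane identifiers, so pasted keys are collision-free.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\x1f")
}

stop_chromex <- function(..., class = "chromex_error") {
  stop(errorCondition(paste0(...), class = c(class, "chromex_error")))
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x > 0 && x == as.integer(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
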