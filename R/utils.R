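# internal helpers shared across modules

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0L) b else a
}

fail <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# empty-string / NA -> NA_character_
na_chr <- function(x) {
  x <- as.character(x)
  x[!nzchar(x) | is.na(x)] <- NA_character_
  x
}

# order() on character columns must not depend on the user's locale:
# site builds and indices promise byte-deterministic output.
c_order <- function(...) {
  cols <- lapply(list(...), function(x) {
    if (is.character(x)) factor(x, levels = sort(unique(x), method = "radix")) else x
  })
  do.call(order, cols)
}

c_sort <- function(x) sort(x, method = "radix")

stopifnot_scalar_chr <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    fail("%s must be a single non-NA string", what)
  }
}
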