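# Internal helpers shared across modules.

# Canonical unordered-pair representation: lexicographically sorted endpoints.
canonicalize_pairs <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  swap <- b < a
  tmp <- a[swap]
  a[swap] <- b[swap]
  b[swap] <- tmp
  data.frame(a = a, b = b, stringsAsFactors = FALSE)
}

pair_key <- function(a, b) {
  p <- canonicalize_pairs(a, b)
  paste(p$a, p$b, sep = "|")
}

key_to_pairs <- function(keys) {
  if (length(keys) == 0L) {
    return(data.frame(a = character(0), b = character(0), stringsAsFactors = FALSE))
  }
  parts <- strsplit(keys, "|", fixed = TRUE)
  data.frame(
    a = vapply(parts, `[[`, character(1), 1L),
    b = vapply(parts, `[[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_rtc <- function(...) stop(..., call. = FALSE)
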