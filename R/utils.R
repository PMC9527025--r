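# Shared internal helpers.

DNA_BASES <- c("A", "C", "G", "T")

# Round half away from zero (Table-style display rounding; base round() is
# round-half-even and would print 0.25% as 0.2).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Canonical unordered pair key for joining pair tables.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

# Coerce a sequence given as a single string or a character vector of
# single characters into an upper-case character vector, with U -> T.
seq_chars <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) {
    x <- strsplit(x, "", fixed = TRUE)[[1]]
  }
  x <- toupper(as.character(x))
  x[x == "U"] <- "T"
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
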