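# internal helpers shared across modules

# Round half away from zero, matching printed pie-chart style percentages
# (base round() rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

# Guess the field separator of a delimited text file from its first line.
sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
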