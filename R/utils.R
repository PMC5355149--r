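# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_rng_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old_seed <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old_seed, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Uniform draw from {lo, ..., hi}, immune to sample()'s length-1 expansion.
sample_int_range <- function(lo, hi) {
  if (lo == hi) return(as.integer(lo))
  sample(seq.int(lo, hi), 1L)
}

# Read text from a path or treat a string containing newlines as literal content.
# Keeps module readers usable both on files and on in-memory fixtures.
read_text_input <- function(x) {
  stopifnot(is.character(x), length(x) >= 1L)
  if (length(x) > 1L) return(paste(x, collapse = "\n"))
  if (!grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(paste(readLines(x, warn = FALSE, encoding = "UTF-8"), collapse = "\n"))
  }
  x
}

# XML-escape for hand-built GEXF attribute values.
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

# Format numbers for deterministic text output (no scientific notation drift).
fmt_num <- function(x, digits = 10) {
  formatC(x, format = "g", digits = digits)
}
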