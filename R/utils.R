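# internal utilities shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# ";"-separated attribute fields -> list of token vectors
split_tokens <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(v) {
    v <- trimws(v)
    v[nzchar(v)]
  })
}

join_tokens <- function(x) vapply(x, paste, character(1), collapse = ";")

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA", eol = "\n",
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""), ...)
}

# matrix with rownames -> data.frame with an explicit id column (for writers)
matrix_to_df <- function(m, id_col) {
  out <- data.frame(rownames(m), as.data.frame(m, check.names = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[1] <- id_col
  out
}
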