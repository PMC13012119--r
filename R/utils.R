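#' @importFrom vctrs vec_proxy_compare
NULL

# Strict TSV reader shared by every text-table input: UTF-8, '#' comments,
# required header columns, informative errors.
read_tsv_strict <- function(path, required, col_types = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                        col_types = col_types, progress = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s: missing required column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0) abort(sprintf("%s: no records", path))
  as_tibble(df)
}

# Write a data file atomically: stage next to the target, then rename, so a
# failed run never leaves a partially written output.
write_atomic <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) abort(sprintf("could not write %s", path))
  invisible(path)
}

write_tsv_atomic <- function(df, path) {
  write_atomic(function(p) readr::write_tsv(df, p, progress = FALSE), path)
}

write_json_atomic <- function(x, path) {
  write_atomic(function(p) {
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, path)
}

logsumexp <- function(x) {
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}
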