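# Internal helpers shared across modules.

assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s]", name, min, max))
  }
  invisible(x)
}

# Ordered taxonomic ranks, shallowest first. `superkingdom` is not part of
# the lineage columns; bins carry kingdom -> species.
tax_ranks <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus", "species")
}

# Atomic write: emit to a temp file in the destination directory, then rename.
write_atomically <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  file.rename(tmp, path)
  invisible(path)
}
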