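## Shared tabular I/O helpers.  All stage boundaries are RFC-4180 CSV with
## headers; reals are serialised at full precision (17 significant digits)
## so that case classification and joins are stable across write/read.

write_table_csv <- function(df, path) {
  stopifnot(is.data.frame(df))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  # serialise doubles with 17 significant digits so every value
  # round-trips bit-exactly (required for stable case classification
  # across write/read)
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- NA_character_
      out[[j]] <- v
    }
  }
  data.table::fwrite(out, path, sep = ",", quote = "auto", eol = "\n")
  invisible(path)
}

read_table_csv <- function(path, required_cols = NULL) {
  if (!file.exists(path)) {
    stop("required input file not found: ", path, call. = FALSE)
  }
  dt <- data.table::fread(path, sep = ",", header = TRUE, data.table = FALSE)
  if (!is.null(required_cols)) {
    missing <- setdiff(required_cols, names(dt))
    if (length(missing)) {
      stop("file ", path, " is missing columns: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  dt
}

# fwrite's full-precision float handling: data.table writes doubles with
# enough digits to round-trip exactly (R >= 4 uses shortest-round-trip
# representation), so no explicit format step is needed.

`%||%` <- function(a, b) if (is.null(a)) b else a

# let data.table's [ dispatch work inside this package without a full
# import of its namespace
.datatable.aware <- TRUE
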