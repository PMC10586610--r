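# Internal helpers shared across modules.

# Round half away from zero (for non-negative x: half-up). base::round()
# rounds half to even, which is not what bench SOPs mean by "round".
round_half_up <- function(x) {
  floor(x + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

# Sniff the field separator of a delimited text file: tab wins over comma so
# that TSV written by write_table() round-trips through the CSV readers.
sniff_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) return(",")
  if (grepl("\t", first, fixed = TRUE)) "\t" else ","
}

read_delim_checked <- function(path, required, stage) {
  if (!file.exists(path)) {
    stop_stage(stage, "input file not found: ", path)
  }
  df <- read.delim(path, sep = sniff_sep(path), header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop_stage(stage, "missing required column(s): ",
               paste(missing, collapse = ", "), " in ", path)
  }
  df
}

# Serialize numeric columns at full (17 significant digit) precision so that
# write -> read round-trips reproduce doubles bit-exactly.
format_full_precision <- function(df) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  df
}
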