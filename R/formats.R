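# Shared helpers for the `#`-commented CSV dialects used by the five
# site data records. All writers format numbers deterministically (fixed
# 5-decimal floats, "NA" for missing) so that write -> read -> write is
# byte-identical.

TOOL_PROVENANCE <- "canopygcc v0.1.0"

fmt_num <- function(x, digits = 5) {
  out <- ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
  # normalise negative zero
  sub("^-0\\.0+$", paste0("0.", strrep("0", digits)), out)
}

fmt_int <- function(x) {
  ifelse(is.na(x), "NA", format(as.integer(x), scientific = FALSE, trim = TRUE))
}

fmt_chr <- function(x) {
  ifelse(is.na(x) | x == "", "NA", x)
}

fmt_date <- function(x) {
  ifelse(is.na(x), "NA", format(x, "%Y-%m-%d"))
}

na_chr <- function(x) {
  x[x == "NA"] <- NA_character_
  x
}

na_num <- function(x) as.numeric(ifelse(x == "NA", NA, x))

na_int <- function(x) as.integer(ifelse(x == "NA", NA, x))

na_date <- function(x) as.Date(ifelse(x == "NA", NA, x), format = "%Y-%m-%d")

# Read a file with a leading block of `#` lines, a column-header line and
# comma-separated data rows. Returns the header lines, the column names and
# a character matrix of the row fields.
read_hash_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_hash <- grepl("^#", lines)
  n_hdr <- if (any(!is_hash)) which(!is_hash)[1] - 1L else length(lines)
  header <- lines[seq_len(n_hdr)]
  body <- lines[-seq_len(n_hdr)]
  body <- body[nzchar(body)]
  if (length(body) < 1) {
    stop("no column header line found in ", path, call. = FALSE)
  }
  cols <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  rows <- body[-1]
  cells <- if (length(rows)) {
    do.call(rbind, strsplit(rows, ",", fixed = TRUE))
  } else {
    matrix(character(0), nrow = 0, ncol = length(cols))
  }
  if (ncol(cells) != length(cols) && nrow(cells) > 0) {
    stop("column count mismatch in ", path, call. = FALSE)
  }
  list(header = header, cols = cols, cells = cells, data_lines = rows)
}

# Pull "# Key: value" out of a header block; "" if absent.
hdr_value <- function(header, key) {
  pat <- paste0("^#\\s*", key, ":\\s*")
  hit <- grep(pat, header, value = TRUE)
  if (!length(hit)) return("")
  trimws(sub(pat, "", hit[1]))
}

hdr_num <- function(header, key) {
  v <- hdr_value(header, key)
  if (v %in% c("", "NA")) NA_real_ else as.numeric(v)
}

require_cols <- function(got, want, path) {
  missing <- setdiff(want, got)
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
}
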