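# CSV and plain-text model-config interfaces.

#' Read a rectangular numeric dataset from CSV
#'
#' Comma-separated, mandatory header row, '.' decimal, UTF-8. Columns are kept
#' as read; non-numeric cells in columns used by a model are an error at
#' design-build time, and rows with missing values in used columns are dropped
#' listwise (with a logged count) when the design is built.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_variable_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dat <- utils::read.csv(path, header = TRUE, fileEncoding = "UTF-8")
  if (nrow(dat) < 1L) stop("empty dataset: ", path)
  dat
}

#' Parse a term string
#'
#' Grammar: `"x"` (raw), `"x:y"` (product), `"x^2"` (power). Centering is not
#' part of the term string; it is supplied by a [center_scheme()], e.g.
#' `--center humidity=85` on the command line.
#'
#' @param s term string.
#' @return a `"term_spec"`.
#' @export
parse_term <- function(s) {
  s <- trimws(s)
  if (grepl(":", s, fixed = TRUE)) {
    parts <- trimws(strsplit(s, ":", fixed = TRUE)[[1]])
    if (length(parts) != 2L) stop("a product term has exactly two components: ", s)
    return(term_product(parts[1], parts[2]))
  }
  if (grepl("^", s, fixed = TRUE)) {
    parts <- trimws(strsplit(s, "^", fixed = TRUE)[[1]])
    if (length(parts) != 2L) stop("malformed power term: ", s)
    k <- suppressWarnings(as.integer(parts[2]))
    if (is.na(k)) stop("malformed power exponent: ", s)
    return(term_power(parts[1], k))
  }
  term_raw(s)
}

#' Parse centering-scheme strings
#'
#' Each entry is `var=mean` or `var=<number>`, e.g.
#' `parse_center_scheme(c("temp=mean", "humidity=85"))`.
#'
#' @param entries character vector (possibly comma-separated).
#' @return a [center_scheme()].
#' @export
parse_center_scheme <- function(entries) {
  if (length(entries) == 0L) return(center_scheme())
  entries <- trimws(unlist(strsplit(entries, ",", fixed = TRUE)))
  entries <- entries[nzchar(entries)]
  sch <- list()
  for (e in entries) {
    kv <- strsplit(e, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("malformed centering entry (want var=mean or var=<number>): ", e)
    val <- trimws(kv[2])
    sch[[trimws(kv[1])]] <- if (identical(val, "mean")) "mean" else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num)) stop("malformed centering constant: ", e)
      num
    }
  }
  do.call(center_scheme, sch)
}

#' Read a model configuration file
#'
#' Plain-text key-value format, one key per line:
#' \preformatted{
#' response: bars
#' terms: temp humidity temp:humidity
#' center: temp=mean humidity=85
#' intercept: true
#' }
#' `terms` are whitespace-separated [parse_term()] strings; `center` entries
#' are optional, as is `intercept` (default true).
#'
#' @param path file path.
#' @return list with `spec` (a [model_spec()]) and `scheme` (a [center_scheme()]).
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("malformed config line: ", ln)
    kv[[m[2]]] <- m[3]
  }
  if (is.null(kv$response)) stop("config is missing 'response'")
  if (is.null(kv$terms)) stop("config is missing 'terms'")
  terms <- lapply(strsplit(trimws(kv$terms), "\\s+")[[1]], parse_term)
  scheme <- if (!is.null(kv$center)) {
    parse_center_scheme(strsplit(trimws(kv$center), "\\s+")[[1]])
  } else center_scheme()
  intercept <- if (!is.null(kv$intercept)) {
    tolower(kv$intercept) %in% c("true", "yes", "1")
  } else TRUE
  list(spec = model_spec(kv$response, terms, intercept), scheme = scheme)
}
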