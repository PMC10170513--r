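#' COLVAR-style and HILLS-style columnar text files
#'
#' Whitespace-delimited columnar text with a `#! FIELDS ...` header
#' line, the de-facto dialect for CV time series and deposited-hill
#' lists. Values are written with 17 significant digits so that
#' `read(write(x))` round-trips exactly.
#'
#' @name metad_io
NULL

write_fields_file <- function(df, path, extra_header = character()) {
  header <- paste("#! FIELDS", paste(names(df), collapse = " "))
  body <- do.call(paste, c(lapply(df, function(col) {
    if (is.logical(col)) as.integer(col) else sprintf("%.17g", col)
  }), list(sep = " ")))
  writeLines(c(header, extra_header, body), path)
  invisible(path)
}

read_fields_file <- function(path) {
  lines <- readLines(path)
  hi <- grep("^#! FIELDS", lines)[1]
  if (is.na(hi)) stop("not a FIELDS-header columnar file: ", path, call. = FALSE)
  fields <- strsplit(sub("^#! FIELDS\\s+", "", lines[hi]), "\\s+")[[1]]
  sets <- grep("^#! SET", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0L) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(fields)), fields))
  } else {
    df <- read.table(text = body, col.names = fields)
  }
  attr(df, "set_lines") <- sets
  df
}

#' Write a CV time series (COLVAR dialect)
#'
#' @param traj a `metad_trajectory` (or a data frame whose first column
#'   is `time`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_colvar <- function(traj, path) {
  df <- if (inherits(traj, "metad_trajectory")) traj$records else traj
  write_fields_file(df, path)
}

#' Read a CV time series (COLVAR dialect)
#'
#' @param path input file.
#' @return data frame with the columns named in the FIELDS header;
#'   a column named `unbound` is mapped back to logical.
#' @export
read_colvar <- function(path) {
  df <- read_fields_file(path)
  attr(df, "set_lines") <- NULL
  if ("unbound" %in% names(df)) df$unbound <- df$unbound != 0
  df
}

#' Write a hill list (HILLS dialect)
#'
#' Columns `time center_1..n sigma_1..n height biasf`.
#'
#' @param h a [hills()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_hills <- function(h, path) {
  stopifnot(inherits(h, "hills"))
  df <- as.data.frame(h)
  df$biasf <- rep(attr(h, "biasf"), nrow(df))
  ncv <- attr(h, "ncv")
  extra <- c(
    sprintf("#! SET ncv %d", ncv),
    sprintf("#! SET periodic_%d %s %s", seq_len(ncv),
            ifelse(attr(h, "periodic"), "1", "0"),
            ifelse(attr(h, "periodic"),
                   sprintf("%.17g", attr(h, "period")), "NA")))
  write_fields_file(df, path, extra_header = extra)
}

#' Read a hill list (HILLS dialect)
#'
#' @param path input file.
#' @return a [hills()] object.
#' @export
read_hills <- function(path) {
  df <- read_fields_file(path)
  sets <- attr(df, "set_lines")
  cn <- names(df)
  centers <- as.matrix(df[grep("^center_", cn)])
  ncv <- ncol(centers)
  periodic <- rep(FALSE, ncv); period <- rep(NA_real_, ncv)
  for (i in seq_len(ncv)) {
    m <- grep(sprintf("^#! SET periodic_%d ", i), sets, value = TRUE)
    if (length(m) == 1L) {
      parts <- strsplit(m, "\\s+")[[1]]
      periodic[i] <- parts[4] == "1"
      if (periodic[i]) period[i] <- as.numeric(parts[5])
    }
  }
  biasf <- if ("biasf" %in% cn && nrow(df) > 0) df$biasf[1] else NA_real_
  hills(centers, as.matrix(df[grep("^sigma_", cn)]), df$height, df$time,
        periodic = periodic, period = period, biasf = biasf)
}
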