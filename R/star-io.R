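#' @include AllClasses.R
NULL

#' Write a metadata table as a STAR-style text file
#'
#' One `data_` block with a `loop_` of named columns (`_<name> #<k>`),
#' whitespace-separated rows. All columns of the data frame are written,
#' so user columns survive a round trip untouched.
#'
#' @param table a data.frame.
#' @param path output path.
#' @param blockName data block name.
#' @return invisibly, the path.
#' @export
writeStarTable <- function(table, path, blockName = "images") {
  stopifnot(is.data.frame(table))
  lines <- c(paste0("data_", blockName), "", "loop_",
             sprintf("_%s #%d", names(table), seq_along(table)))
  fmt <- vapply(table, function(col) {
    if (is.numeric(col)) format(col, digits = 17, trim = TRUE,
                                scientific = FALSE)
    else as.character(col)
  }, character(nrow(table)))
  fmt <- matrix(fmt, nrow = nrow(table))
  fmt[is.na(as.matrix(table))] <- "NA"
  lines <- c(lines, apply(fmt, 1, paste, collapse = "  "))
  writeLines(lines, path)
  invisible(path)
}

#' Read a STAR-style metadata table
#'
#' Parses a single `data_` block with one `loop_`; column types are
#' inferred. Optionally validates that required columns are present.
#'
#' @param path file path.
#' @param requiredColumns character vector of columns that must exist.
#' @return data.frame.
#' @export
readStarTable <- function(path, requiredColumns = character()) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  loopAt <- grep("^\\s*loop_\\s*$", lines)
  if (!length(loopAt)) stop("no loop_ block found in ", path)
  i <- loopAt[1] + 1
  cols <- character()
  while (i <= length(lines) && grepl("^\\s*_", lines[i])) {
    nm <- sub("^\\s*_([^ #\t]+).*$", "\\1", lines[i])
    cols <- c(cols, nm)
    i <- i + 1
  }
  if (!length(cols)) stop("loop_ block has no column definitions")
  body <- lines[i:length(lines)]
  body <- body[nzchar(trimws(body))]
  body <- body[!grepl("^\\s*data_", body)]
  rows <- strsplit(trimws(body), "\\s+")
  bad <- which(lengths(rows) != length(cols))
  if (length(bad))
    stop("row ", bad[1], " has ", lengths(rows)[bad[1]], " fields; expected ",
         length(cols))
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- cols
  df[] <- lapply(df, function(x) utils::type.convert(x, as.is = TRUE))
  missing <- setdiff(requiredColumns, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  df
}

#' Write an image stack's ground-truth metadata
#' @param stack an [ImageStack-class].
#' @param path output path.
#' @export
writeMeta <- function(stack, path) writeStarTable(imageMeta(stack), path)

#' Read ground-truth metadata and validate stage requirements
#'
#' @param path STAR-style table path.
#' @param stage optional pipeline stage name; "ctf" additionally requires
#'   a defocus column.
#' @return data.frame.
#' @export
readMeta <- function(path, stage = NULL) {
  req <- c("imageId", "pdId")
  if (!is.null(stage) && stage == "ctf") req <- c(req, "defocusUM")
  df <- readStarTable(path, requiredColumns = req)
  if (!is.null(stage) && stage == "ctf" && anyNA(df$defocusUM))
    stop("stage '", stage, "' requires a defocus for every image")
  df
}
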