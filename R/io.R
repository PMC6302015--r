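#' Isotherm, dialysis-well and melt-curve file I/O
#'
#' Plain TSV readers/writers for the tabular formats the pipeline consumes:
#' isotherms (`injection`, `dv_uL`, `molar_ratio`, `heat`), dialysis wells
#' (`protein_side_total_uM`, `buffer_side_total_uM`, `protein_uM`) and melt
#' curves (`temperature_C`, `value`, with the observable kind in a
#' `# kind=` header line).
#'
#' @param x Object to write.
#' @param path File path.
#' @return Readers return the parsed object; writers return `path`
#'   invisibly.
#' @name ionbind_io
NULL

#' @rdname ionbind_io
#' @export
write_isotherm_tsv <- function(x, path) {
  utils::write.table(x[, c("injection", "dv_uL", "molar_ratio", "heat")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname ionbind_io
#' @export
read_isotherm_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#")
  need <- c("injection", "dv_uL", "molar_ratio", "heat")
  if (!all(need %in% names(df)))
    stop("isotherm TSV must have columns: ", paste(need, collapse = ", "))
  structure(df, class = c("isotherm", "data.frame"))
}

#' @rdname ionbind_io
#' @export
write_wells_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname ionbind_io
#' @export
read_wells_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#")
  need <- c("protein_side_total_uM", "buffer_side_total_uM", "protein_uM")
  if (!all(need %in% names(df)))
    stop("wells TSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname ionbind_io
#' @export
write_melt_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# kind=", attr(x, "kind")), con)
  utils::write.table(data.frame(temperature_C = x$temperature, value = x$value),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname ionbind_io
#' @export
read_melt_tsv <- function(path) {
  first <- readLines(path, n = 1)
  kind <- if (grepl("^# *kind=", first))
    sub("^# *kind=", "", trimws(first)) else "ratio"
  df <- utils::read.delim(path, comment.char = "#")
  melt_curve(df$temperature_C, df$value, kind = kind)
}

#' @rdname ionbind_io
#' @export
write_spectrum_tsv <- function(x, path) {
  utils::write.table(data.frame(wavelength_nm = x$wavelengths,
                                intensity = x$intensities),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname ionbind_io
#' @export
read_spectrum_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#")
  list(wavelengths = df$wavelength_nm, intensities = df$intensity)
}

# strip S3 classes recursively so jsonlite serialises plain lists
as_plain <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(unclass(x)))
  if (is.list(x)) return(lapply(unclass(x), as_plain))
  x
}

#' Write an analysis result as a JSON envelope
#'
#' Serialises a fit/result object together with a provenance block
#' (package version, result class, seed, extra parameters and input file
#' checksums) so that runs are reproducible and self-describing.
#'
#' @param x Result object (any of the package's fit/result classes).
#' @param path Output JSON file.
#' @param seed Seed used for the computation, if any.
#' @param parameters Named list of parameters to record.
#' @param inputs Character vector of input file paths to checksum.
#' @return `path`, invisibly.
#' @export
write_result_json <- function(x, path, seed = NULL, parameters = NULL,
                              inputs = NULL) {
  prov <- list(package = "ionbind",
               version = as.character(utils::packageVersion("ionbind")),
               result_class = class(x)[1],
               seed = seed,
               parameters = parameters)
  if (!is.null(inputs) && length(inputs))
    prov$input_md5 <- as.list(tools::md5sum(inputs))
  jsonlite::write_json(list(provenance = prov, result = as_plain(x)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", force = TRUE)
  invisible(path)
}
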