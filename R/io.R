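#' Read and write the package's tabular formats
#'
#' Plain TSV/CSV readers and writers for the pipeline's tables:
#' differential-expression tables (`id`, `timepoint`, `log2fc`, `adj_p`),
#' prediction tables (`mirna`, `gene`, `source`, `score`), qPCR tables
#' (`condition`, `analyte`, `day`, `replicate`, `pct_control`) and
#' observation series (`species`, `condition`, `day`, `value`). The
#' delimiter is inferred from the file extension (`.csv` -> comma,
#' otherwise tab).
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return Readers return a validated data frame; writers return `path`
#'   invisibly.
#' @name chondromir-io
NULL

.delim <- function(path) if (grepl("\\.csv$", path)) "," else "\t"

.write_table <- function(x, path) {
  utils::write.table(x, path, sep = .delim(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.read_table <- function(path, required) {
  x <- utils::read.table(path, sep = .delim(path), header = TRUE,
                         stringsAsFactors = FALSE)
  miss <- setdiff(required, names(x))
  if (length(miss)) stop("file ", path, " lacks column(s): ",
                         paste(miss, collapse = ", "))
  x
}

#' @rdname chondromir-io
#' @export
write_de_table <- function(x, path) .write_table(.check_de(x), path)

#' @rdname chondromir-io
#' @export
read_de_table <- function(path)
  .check_de(.read_table(path, c("id", "timepoint", "log2fc", "adj_p")))

#' @rdname chondromir-io
#' @export
write_predictions <- function(x, path) .write_table(x, path)

#' @rdname chondromir-io
#' @export
read_predictions <- function(path)
  .read_table(path, c("mirna", "gene", "source", "score"))

#' @rdname chondromir-io
#' @export
write_qpcr <- function(x, path) .write_table(x, path)

#' @rdname chondromir-io
#' @export
read_qpcr <- function(path)
  .read_table(path, c("condition", "analyte", "day", "replicate",
                      "pct_control"))

#' @rdname chondromir-io
#' @export
write_observations <- function(x, path) .write_table(.check_observations(x),
                                                     path)

#' @rdname chondromir-io
#' @export
read_observations <- function(path)
  .check_observations(.read_table(path, c("species", "condition", "day",
                                          "value")))

#' Write a trajectory as a TSV table
#'
#' @param trajectory A `kinetic_trajectory`.
#' @param path Output path; columns are `time` then one column per species.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "kinetic_trajectory"))
  .write_table(data.frame(time = trajectory$time, trajectory$states,
                          check.names = FALSE), path)
}

#' Read or write gene sets in GMT format
#'
#' One pathway per line: id, description, then member genes, tab-separated.
#'
#' @param sets Named list of character vectors.
#' @param path File path.
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  stats::setNames(sets, vapply(parts, `[[`, "", 1))
}

#' Write a JSON screen or assessment report
#'
#' @param report A list (e.g. screen summary or `fit_assessment`).
#' @param path Output path.
#' @export
write_json_report <- function(report, path) {
  if (inherits(report, "fit_assessment")) report <- unclass(report)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
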