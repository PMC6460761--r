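#' Read a posterior-draw table
#'
#' Reads a delimited text table of retained MCMC draws (one column per
#' parameter, one row per draw, header row of parameter names). The
#' delimiter is auto-detected among tab, comma and semicolon on read;
#' written tables are always TSV.
#'
#' An optional sidecar configuration (JSON; a named list mapping column
#' name to a list with fields \code{parameter}, \code{population} and
#' optionally \code{units}) relabels the columns; unmapped columns keep
#' their header name as the parameter token.
#'
#' @param path table file path.
#' @param sidecar optional path to the JSON column map.
#' @return Named list of [PosteriorDraws-class] objects, one per column.
#' @export
readPosteriorTable <- function(path, sidecar = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else if (grepl(",", header)) ","
         else if (grepl(";", header)) ";" else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE)
  map <- if (!is.null(sidecar)) jsonlite::fromJSON(sidecar,
                                                   simplifyVector = FALSE)
         else list()
  out <- lapply(names(tab), function(col) {
    m <- map[[col]]
    posteriorDraws(tab[[col]],
                   parameter = if (!is.null(m$parameter)) m$parameter
                               else col,
                   population = if (!is.null(m$population)) m$population
                                else NA_character_,
                   units = if (!is.null(m$units)) m$units else "")
  })
  stats::setNames(out, names(tab))
}

#' Write posterior draws as a TSV table
#'
#' @param draws_list named list of [PosteriorDraws-class] objects of equal
#'   length (or a single object).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDrawsTable <- function(draws_list, path) {
  if (methods::is(draws_list, "PosteriorDraws"))
    draws_list <- stats::setNames(list(draws_list),
                                  draws_list@parameter)
  cols <- lapply(draws_list, drawsVector)
  if (length(unique(lengths(cols))) != 1L)
    stop("all draw vectors must have the same length")
  tab <- as.data.frame(cols, check.names = FALSE, optional = TRUE)
  names(tab) <- names(draws_list)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a per-individual trait table (CSV)
#'
#' Expects columns \code{individual_id}, \code{population}, \code{sex},
#' then one column per trait or covariate.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
readTraitTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = ",",
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("individual_id", "population", "sex")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("trait table missing columns: ",
         paste(missing_cols, collapse = ", "))
  tab
}

#' Write a trait table as CSV
#' @param tab data.frame from [genTraits()] or equivalent.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeTraitTable <- function(tab, path) {
  utils::write.table(tab, path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a population map (two-column TSV: sample_id, population)
#' @param path TSV path (header optional; detected by the literal header
#'   \code{sample_id}).
#' @return Named character vector, sample_id -> population.
#' @export
readPopulationMap <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("^sample_id\\b", first)
  tab <- utils::read.table(path, header = has_header, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("population map needs two columns")
  if (!nrow(tab)) stop("population map is empty")
  stats::setNames(as.character(tab[[2]]), as.character(tab[[1]]))
}

#' Write a population map (two-column TSV)
#' @param popmap named character vector, sample_id -> population.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePopulationMap <- function(popmap, path) {
  utils::write.table(data.frame(sample_id = names(popmap),
                                population = unname(popmap)),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read one locus alignment from a FASTA file
#'
#' @param path FASTA path; record names are the sample ids.
#' @param locus_name locus label; defaults to the file name without
#'   extension.
#' @return A [HaplotypeAlignment-class] object.
#' @export
readLocusFasta <- function(path, locus_name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(locus_name))
    locus_name <- sub("\\.[^.]*$", "", basename(path))
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  haplotypeAlignment(seqs, locus_name)
}

#' Write one locus alignment to FASTA
#' @param aln a [HaplotypeAlignment-class] object.
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
writeLocusFasta <- function(aln, path) {
  Biostrings::writeXStringSet(aln@sequences, path)
  invisible(path)
}

writeJson <- function(x, path) {
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, na = "null"), path)
  invisible(path)
}
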