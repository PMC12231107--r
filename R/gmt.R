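#' Read a GMT gene-set collection
#'
#' GMT is tab-delimited: set name, description, then member genes.
#'
#' @param path File path.
#' @return Named list of character vectors of gene ids.
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    stopIfNot(length(parts) >= 3,
              sprintf("malformed GMT line %d: need name, description, members", i))
    sets[[parts[1]]] <- parts[-(1:2)]
  }
  sets
}

#' Write a GMT gene-set collection
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional named descriptions; defaults to \code{"na"}.
#' @return The path, invisibly.
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
  stopIfNot(!is.null(names(sets)) && all(nzchar(names(sets))),
            "sets must be named")
  lines <- vapply(names(sets), function(id) {
    desc <- if (!is.null(descriptions) && !is.null(descriptions[[id]]))
      descriptions[[id]] else "na"
    paste(c(id, desc, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
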