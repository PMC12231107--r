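#' Derive a reproducible RNG substream seed
#'
#' Hashes a master seed together with a stage name and entity identifiers into
#' a 32-bit seed, so each generator draws from an independent substream keyed
#' by \code{(stage, entity)}. Adding strains or samples therefore never
#' reshuffles the random numbers of existing ones.
#'
#' @param master Integer master seed.
#' @param ... Character or numeric key components (stage name, entity id, ...).
#' @return An integer usable with \code{\link{set.seed}}.
#' @export
#' @examples
#' substreamSeed(1L, "growth", "G0001")
substreamSeed <- function(master, ...) {
  stopifnot(length(master) == 1L, is.finite(master))
  key <- paste(c(format(master, scientific = FALSE),
                 vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                        character(1))), collapse = "/")
  ## polynomial rolling hash mod (2^31 - 1); doubles stay exact below 2^53.
  ## The master seed is hashed as part of the key (not added afterwards) so
  ## that neighbouring masters yield unrelated substreams.
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Evaluate code under a temporary RNG substream
#'
#' Sets the seed from \code{\link{substreamSeed}}, evaluates \code{expr}, and
#' restores the caller's RNG state.
#'
#' @param master Integer master seed.
#' @param ... Key components passed to \code{\link{substreamSeed}}.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
withSubstream <- function(master, ..., expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substreamSeed(master, ...))
  expr
}

## Deterministic TSV writer: fixed field order, no quoting surprises, "." decimal.
writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA", eol = "\n")
  invisible(path)
}

readTsv <- function(path, ...) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

## x log2 x with the 0 log 0 = 0 convention, vectorised.
plogp <- function(x) ifelse(x > 0, x * log2(x), 0)

stopIfNot <- function(cond, msg, class = "chemnetError") {
  if (!isTRUE(cond)) stop(errorCondition(msg, class = c(class, "error")))
  invisible(TRUE)
}
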