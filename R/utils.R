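# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the RNG locally and restores the caller's state afterwards, so
#' fixture generation never perturbs user-level randomness.
#' @noRd
withLocalSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

omStop <- function(...) stop(..., call. = FALSE)

isUrl <- function(x) grepl("^https?://", x)

#' Fetch a path-or-URL to a readable local file
#' @noRd
resolveSource <- function(source) {
  if (!isUrl(source)) {
    if (!file.exists(source)) {
      omStop("cannot read ontology source: ", source)
    }
    return(source)
  }
  dest <- tempfile(fileext = paste0(".", tools::file_ext(source)))
  resp <- httr::GET(source, httr::write_disk(dest, overwrite = TRUE))
  if (httr::http_error(resp)) {
    omStop("failed to fetch ", source, " (HTTP ", httr::status_code(resp), ")")
  }
  dest
}
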