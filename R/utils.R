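# Run `expr` under a fixed RNG state without disturbing the caller's
# random stream.
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Serialise a ground-truth ledger
#'
#' Every synthetic-data generator returns a `truth` ledger that, together
#' with the seed, fully determines the dataset. This writes it as JSON so
#' a generated dataset can always be shipped with its ground truth.
#'
#' @param truth The `truth` element of a generator result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_ledger <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
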