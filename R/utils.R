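# internal helpers shared across the package

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Stable fingerprint of a signature scheme
#'
#' Hashes the canonical representation (sorted score names, each with step,
#' direction and sorted members) so that a score matrix can be matched to the
#' exact gene sets it was computed under. Used to refuse prediction on scores
#' produced under a different scheme.
#'
#' @param scheme A `signature_scheme` object.
#' @return A character scalar hash.
#' @export
scheme_fingerprint <- function(scheme) {
  stopifnot(inherits(scheme, "signature_scheme"))
  canon <- lapply(scheme$scores[sort(names(scheme$scores))], function(sc) {
    set_canon <- function(s) {
      if (is.null(s)) return(NULL)
      list(step = s$step, direction = s$direction, members = sort(s$members))
    }
    list(positive = set_canon(sc$positive), negative = set_canon(sc$negative))
  })
  rlang::hash(canon)
}

# abort with a user-facing message, no call in the condition
fail <- function(...) stop(sprintf(...), call. = FALSE)

# deterministic table writer: tab-separated, no quoting, fixed ordering is the
# caller's responsibility
write_tsv_plain <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_plain <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
}
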