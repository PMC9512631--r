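# Internal helpers shared across modules.

#' Derive an independent RNG stream seed from a global seed
#'
#' Each generator hashes its own stream label so that adding a new generator
#' never perturbs the draws of an existing one.
#'
#' @param seed integer global seed.
#' @param stream character label of the stream.
#' @return an integer seed below 2^31.
#' @keywords internal
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) %% 65521 + 1) * 32749 + h) %% 2147483647L
}

# Evaluate expr with a locally-set RNG state; the caller's RNG is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Normalize an annotation description string for matching
#'
#' Lower-cases, maps Greek letters to their spelled-out forms (beta, alpha,
#' kappa), replaces hyphens and slashes by spaces and squeezes whitespace, so
#' that "TGF-β signaling pathway" and "TGF beta signaling pathway" compare
#' equal. All phrase/keyword matching in the ontology and pathway modules
#' operates on this normalized form.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
norm_text <- function(x) {
  x <- tolower(x)
  x <- gsub("β", "beta", x, fixed = TRUE)
  x <- gsub("α", "alpha", x, fixed = TRUE)
  x <- gsub("κ", "kappa", x, fixed = TRUE)
  x <- gsub("kappa b", "kappab", x, fixed = TRUE)
  x <- gsub("[-/]", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# Squeeze internal whitespace only (used when deduplicating descriptions).
squeeze_ws <- function(x) trimws(gsub("\\s+", " ", x))

tcx_log <- function(...) {
  if (isTRUE(getOption("tcx.verbose", TRUE))) message(...)
}

# Write a data.frame as strict TSV (UTF-8, header, no quoting). Numeric
# columns are rendered with 17 significant digits so that read_tsv() returns
# bit-identical doubles.
write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}
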