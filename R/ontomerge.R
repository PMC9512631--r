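# Composite functional database: alias resolution, per-gene union of unique
# ontological descriptions across sources, term counting, keyword grouping.

#' Resolve gene symbols through an alias table
#'
#' Maps each symbol (case-insensitively) to its canonical form. Resolution
#' is idempotent: canonical symbols map to themselves. Unknown symbols pass
#' through unchanged (upper-cased) with a logged warning. An alias mapping
#' to two different canonicals, or an alias chain (a canonical that is
#' itself an alias of something else), is an error.
#'
#' @param symbols character vector.
#' @param alias_table data.frame with columns `alias`, `canonical`.
#' @return character vector of canonical symbols (upper-case).
#' @export
resolve_aliases <- function(symbols, alias_table) {
  al <- toupper(alias_table$alias)
  can <- toupper(alias_table$canonical)
  map <- tapply(can, al, unique)
  conflicts <- names(map)[lengths(map) > 1]
  if (length(conflicts) > 0)
    stop("alias(es) mapping to multiple canonical symbols: ",
         paste(vapply(conflicts, function(a)
           sprintf("%s -> {%s}", a, paste(map[[a]], collapse = ", ")),
           character(1)), collapse = "; "))
  map <- unlist(map)
  chained <- map[map %in% names(map) & map != names(map)]
  chained <- chained[map[chained] != chained]
  if (length(chained) > 0)
    stop("alias chain detected: canonical symbol(s) ",
         paste(unique(chained), collapse = ", "), " are themselves aliases")
  s <- toupper(symbols)
  hit <- s %in% names(map)
  if (any(!hit))
    tcx_log(sprintf("resolve_aliases: %d unknown symbol(s) passed through",
                    sum(!hit)))
  s[hit] <- unname(map[s[hit]])
  s
}

#' Build the composite annotation database
#'
#' Resolves aliases, pools all sources and forms, per gene, the
#' case-insensitive union of unique ontological descriptions (whitespace
#' normalized). The result is independent of source order; descriptions are
#' stored sorted by their normalized form for determinism.
#'
#' @param sources list of data.frames with columns `symbol`, `description`.
#' @param alias_table optional alias table for [resolve_aliases()].
#' @return data.frame `gene`, `description` (unique pairs), of class
#'   `tcx_composite`.
#' @export
build_composite <- function(sources, alias_table = NULL) {
  if (length(sources) == 0) stop("need at least one annotation source")
  pooled <- do.call(rbind, lapply(sources, function(s)
    data.frame(symbol = s$symbol, description = s$description,
               stringsAsFactors = FALSE)))
  gene <- if (is.null(alias_table)) toupper(pooled$symbol)
          else resolve_aliases(pooled$symbol, alias_table)
  desc <- squeeze_ws(pooled$description)
  key <- paste(gene, tolower(desc), sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(gene = gene[first], description = desc[first],
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene, tolower(out$description)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("tcx_composite", "data.frame")
  out
}

#' Count ontological term occurrences
#'
#' A "term" is a whole description string after whitespace normalization
#' (matched case-insensitively); its count is the number of genes whose
#' unique description set contains it. Summed over terms, the counts equal
#' the summed sizes of the per-gene unique description sets.
#'
#' @param composite a `tcx_composite` table.
#' @return data.frame `term`, `count`, sorted by decreasing count then term.
#' @export
count_terms <- function(composite) {
  if (nrow(composite) == 0)
    return(data.frame(term = character(), count = integer(),
                      stringsAsFactors = FALSE))
  term_norm <- tolower(composite$description)
  display <- composite$description[!duplicated(term_norm)]
  names(display) <- term_norm[!duplicated(term_norm)]
  tab <- table(term_norm)
  out <- data.frame(term = unname(display[names(tab)]),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out[order(-out$count, out$term), , drop = FALSE]
}

#' Default functional-group keyword sets
#'
#' Editable keyword configuration for the recurring functional categories of
#' the latent period (MAPK signalling, inflammation/immune response, cell
#' cycle/proliferation, transcription, synaptic events, calcium signalling,
#' apoptosis, mitochondrial processes, glial activation/differentiation).
#' The keyword lists are an explicitly heuristic starting point.
#'
#' @return named list of keyword character vectors.
#' @export
default_functional_groups <- function() {
  list(
    "MAPK signaling" = c("MAPK", "MAP kinase", "ERK", "JNK", "p38"),
    "inflammation/immune" = c("inflammation", "inflammatory response",
                              "immune response", "cytokine", "chemokine"),
    "cell cycle/proliferation" = c("cell cycle", "proliferation", "mitosis"),
    "transcription" = c("transcription"),
    "synaptic" = c("synaptic", "synapse", "neurotransmitter"),
    "calcium signaling" = c("calcium"),
    "apoptosis" = c("apoptosis", "apoptotic", "programmed cell death"),
    "mitochondrial" = c("mitochondri"),
    "glial activation/differentiation" = c("glial", "astrocyte", "microglia"))
}

#' Keyword-defined functional gene groups
#'
#' A gene belongs to a group iff at least one of the group's keywords occurs
#' (case-insensitive substring) in at least one of its unique descriptions.
#' A gene may belong to many groups. Empty keyword lists are an error.
#'
#' @param composite a `tcx_composite` table.
#' @param groups named list of keyword character vectors; see
#'   [default_functional_groups()].
#' @return data.frame `group`, `gene` with attribute `keywords`.
#' @export
keyword_group <- function(composite, groups = default_functional_groups()) {
  if (length(groups) == 0 || is.null(names(groups)))
    stop("`groups` must be a non-empty named list")
  if (any(lengths(groups) == 0))
    stop("empty keyword list for group(s): ",
         paste(names(groups)[lengths(groups) == 0], collapse = ", "))
  dlow <- tolower(composite$description)
  out <- list()
  for (gname in names(groups)) {
    kws <- tolower(groups[[gname]])
    hit <- Reduce(`|`, lapply(kws, function(k) grepl(k, dlow, fixed = TRUE)))
    members <- sort(unique(composite$gene[hit]))
    if (length(members) > 0)
      out[[length(out) + 1L]] <- data.frame(group = gname, gene = members,
                                            stringsAsFactors = FALSE)
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(group = character(), gene = character(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "keywords") <- groups
  res
}
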