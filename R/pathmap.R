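# Pathway mapping: reduction of MAPK signalling into 13 component pathways,
# co-annotation array plots, regulator polarity, enzyme-class groupings.

#' The 13 component MAPK-related pathways
#'
#' Fixed vocabulary and plot order (1 = ERK1/2 ... 13 = PI3K/AKT), arranged by
#' family: Classical (ERK1/2, Growth Factor, Ras/Rab), SAPK (p38,
#' Rho/Cdc42/Rac, JNK, p53, TGF-beta, TNF-alpha), Other (NF-kappaB, Wnt,
#' JAK/STAT, PI3K/AKT).
#'
#' @format character vector of length 13.
#' @export
MAPK_PATHWAYS <- c("ERK1/2", "Growth Factor", "Ras/Rab",
                   "p38", "Rho/Cdc42/Rac", "JNK", "p53", "TGF-beta", "TNF-alpha",
                   "NF-kappaB", "Wnt", "JAK/STAT", "PI3K/AKT")

#' Family membership of the 13 pathways
#'
#' Named character vector mapping each pathway to its family
#' (Classical, SAPK or Other). The three families partition the 13 pathways
#' as 3 + 6 + 4.
#'
#' @format named character vector of length 13.
#' @export
MAPK_FAMILIES <- c(
  "ERK1/2" = "Classical", "Growth Factor" = "Classical", "Ras/Rab" = "Classical",
  "p38" = "SAPK", "Rho/Cdc42/Rac" = "SAPK", "JNK" = "SAPK",
  "p53" = "SAPK", "TGF-beta" = "SAPK", "TNF-alpha" = "SAPK",
  "NF-kappaB" = "Other", "Wnt" = "Other", "JAK/STAT" = "Other",
  "PI3K/AKT" = "Other")

#' Default phrase-to-pathway lexicon
#'
#' Maps ontology description phrases (matched case-insensitively as
#' substrings after [norm_text()] normalization, so hyphen/slash and Greek
#' spelling variants compare equal) to the 13 component pathways. Shipped as
#' an editable table: the mapping is a documented heuristic covering the
#' phrase families that recur in gene-ontology and pathway databases, not a
#' claim about any particular database snapshot.
#'
#' @return data.frame with columns `phrase`, `pathway`.
#' @export
default_pathway_lexicon <- function() {
  lex <- rbind(
    c("classical MAPK", "ERK1/2"),
    c("ERK cascade", "ERK1/2"),
    c("ERK1/2 signaling", "ERK1/2"),
    c("extracellular signal regulated kinase", "ERK1/2"),
    c("growth factor signaling", "Growth Factor"),
    c("nerve growth factor pathway", "Growth Factor"),
    c("PDGF signaling pathway", "Growth Factor"),
    c("PDGFR-alpha signaling pathway", "Growth Factor"),
    c("epidermal growth factor receptor signaling pathway", "Growth Factor"),
    c("Ras protein signal transduction", "Ras/Rab"),
    c("Rab protein signal transduction", "Ras/Rab"),
    c("Ras/Rab signaling", "Ras/Rab"),
    c("p38 MAPK", "p38"),
    c("Rho protein signal transduction", "Rho/Cdc42/Rac"),
    c("Cdc42 protein signal transduction", "Rho/Cdc42/Rac"),
    c("Rac protein signal transduction", "Rho/Cdc42/Rac"),
    c("JNK cascade", "JNK"),
    c("stress-activated protein kinase signaling", "JNK"),
    c("p53 signaling pathway", "p53"),
    c("p53 pathway", "p53"),
    c("TGF-beta signaling pathway", "TGF-beta"),
    c("TGF-beta receptor signaling pathway", "TGF-beta"),
    c("transforming growth factor beta", "TGF-beta"),
    c("TNF-alpha signaling", "TNF-alpha"),
    c("tumor necrosis factor", "TNF-alpha"),
    c("JAK-STAT cascade", "JAK/STAT"),
    c("JAK/STAT signaling", "JAK/STAT"),
    c("Wnt receptor signaling pathway", "Wnt"),
    c("Wnt signaling pathway", "Wnt"),
    c("NF-kappaB cascade", "NF-kappaB"),
    c("I-kappaB kinase/NF-kappaB cascade", "NF-kappaB"),
    c("NF-kappaB signaling", "NF-kappaB"),
    c("phosphoinositide 3-kinase", "PI3K/AKT"),
    c("PI3K/AKT signaling", "PI3K/AKT"),
    c("AKT signaling pathway", "PI3K/AKT"))
  data.frame(phrase = lex[, 1], pathway = lex[, 2], stringsAsFactors = FALSE)
}

check_lexicon <- function(lexicon) {
  stopifnot(is.data.frame(lexicon), all(c("phrase", "pathway") %in% names(lexicon)))
  unknown <- setdiff(unique(lexicon$pathway), MAPK_PATHWAYS)
  if (length(unknown) > 0)
    stop("lexicon maps phrase(s) to unknown pathway(s): ",
         paste(unknown, collapse = ", "))
  lexicon
}

# Which pathways match a single normalized description string.
match_pathways <- function(desc_norm, lexicon) {
  phr <- norm_text(lexicon$phrase)
  hit <- vapply(phr, function(p) grepl(p, desc_norm, fixed = TRUE), logical(1))
  unique(lexicon$pathway[hit])
}

#' Assign each gene its pathway set
#'
#' Scans the deduplicated description set of every gene in a composite
#' annotation table for lexicon phrases and returns the long gene-pathway
#' table. A gene associated with regulation and/or transduction of a pathway
#' (e.g. "positive regulation of JNK cascade") belongs to that pathway's set.
#'
#' @param composite composite annotation table from [build_composite()]
#'   (data.frame with `gene`, `description`).
#' @param lexicon phrase-to-pathway table; see [default_pathway_lexicon()].
#' @return data.frame `gene`, `pathway` (unique pairs). Genes whose
#'   descriptions match no phrase are reported in the `unannotated`
#'   attribute, mirroring the exclusion of pathway-unannotated genes from
#'   pathway-level analyses.
#' @export
assign_pathways <- function(composite, lexicon = default_pathway_lexicon()) {
  lexicon <- check_lexicon(lexicon)
  genes <- unique(composite$gene)
  dn <- norm_text(composite$description)
  out <- lapply(genes, function(g) {
    ds <- dn[composite$gene == g]
    pws <- unique(unlist(lapply(ds, match_pathways, lexicon = lexicon)))
    if (length(pws) == 0) return(NULL)
    data.frame(gene = g, pathway = pws, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(gene = character(), pathway = character(),
                                      stringsAsFactors = FALSE)
  res <- res[order(res$gene, match(res$pathway, MAPK_PATHWAYS)), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "unannotated") <- setdiff(genes, res$gene)
  res
}

#' Pathway sets as a named list
#'
#' @param assignments long `gene`/`pathway` table from [assign_pathways()].
#' @return named list mapping gene to its character vector of pathways.
#' @export
pathway_sets <- function(assignments) {
  split(assignments$pathway, assignments$gene)
}

#' Retain pathways backed by at least one uniquely-annotated DE gene
#'
#' A pathway is retained if at least one differentially expressed gene is
#' annotated with exactly that single pathway. This is the selection
#' criterion that justified the 13-pathway reduction.
#'
#' @param assignments long `gene`/`pathway` table.
#' @param de_genes character vector of differentially expressed genes.
#' @return character vector of retained pathway names (in canonical order).
#' @export
unique_gene_criterion <- function(assignments, de_genes) {
  sets <- pathway_sets(assignments[assignments$gene %in% toupper(de_genes), ,
                                   drop = FALSE])
  singles <- unlist(sets[lengths(sets) == 1], use.names = FALSE)
  MAPK_PATHWAYS[MAPK_PATHWAYS %in% singles]
}

#' Partition pathway-annotated genes into single- and multiple-pathway groups
#'
#' @param assignments long `gene`/`pathway` table.
#' @param genes optional restriction (e.g. the DE genes of one age group).
#' @return list with `single`, `multiple` (gene vectors), `n_annotated`,
#'   `pct_multiple` (percentage of annotated genes carrying >= 2 pathways).
#' @export
partition_single_multiple <- function(assignments, genes = NULL) {
  if (!is.null(genes))
    assignments <- assignments[assignments$gene %in% toupper(genes), , drop = FALSE]
  sets <- pathway_sets(assignments)
  single <- sort(names(sets)[lengths(sets) == 1])
  multiple <- sort(names(sets)[lengths(sets) >= 2])
  n <- length(single) + length(multiple)
  list(single = single, multiple = multiple, n_annotated = n,
       pct_multiple = if (n > 0) 100 * length(multiple) / n else 0)
}

#' Count single-pathway genes per MAPK family
#'
#' @param single_genes character vector of single-pathway-annotated genes.
#' @param assignments long `gene`/`pathway` table.
#' @return named integer vector with counts for Classical, SAPK and Other.
#' @export
family_summary <- function(single_genes, assignments) {
  sets <- pathway_sets(assignments[assignments$gene %in% toupper(single_genes), ,
                                   drop = FALSE])
  if (any(lengths(sets) != 1))
    stop("family_summary expects single-pathway genes only")
  fam <- MAPK_FAMILIES[unlist(sets, use.names = FALSE)]
  out <- c(Classical = 0L, SAPK = 0L, Other = 0L)
  tab <- table(fam)
  out[names(tab)] <- as.integer(tab)
  out
}

#' Pathway co-annotation array-plot matrix
#'
#' Builds the 13 x 13 pair-count matrix used to visualise co-annotation of
#' multiple-pathway genes: a gene annotated with n pathways increments
#' exactly choose(n, 2) cells — in the upper triangle if upregulated, in the
#' lower if downregulated. The diagonal is unused. Matrices are additive
#' over genes, so per-age/per-time strata can be summed.
#'
#' @param assignments long `gene`/`pathway` table.
#' @param directions named character vector, gene -> "up" or "down", naming
#'   exactly the genes to plot (each must carry >= 2 pathways).
#' @return 13 x 13 integer matrix with pathway dimnames.
#' @export
array_plot_matrix <- function(assignments, directions) {
  stopifnot(!is.null(names(directions)), all(directions %in% c("up", "down")))
  genes <- toupper(names(directions))
  sets <- pathway_sets(assignments[assignments$gene %in% genes, , drop = FALSE])
  mat <- matrix(0L, 13, 13, dimnames = list(MAPK_PATHWAYS, MAPK_PATHWAYS))
  for (g in genes) {
    pws <- sets[[g]]
    if (is.null(pws) || length(pws) < 2)
      stop("gene ", g, " has fewer than 2 pathway annotations")
    idx <- sort(match(pws, MAPK_PATHWAYS))
    pairs <- utils::combn(idx, 2)
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      if (directions[[g]] == "up") mat[i, j] <- mat[i, j] + 1L
      else mat[j, i] <- mat[j, i] + 1L
    }
  }
  mat
}

#' Split multiple-pathway genes by annotation breadth
#'
#' The array plots are displayed separately for genes annotated with up to
#' four pathways and genes annotated with five or more, because a broadly
#' annotated gene alone fills many squares.
#'
#' @param assignments long `gene`/`pathway` table.
#' @param genes genes to split (must be pathway-annotated).
#' @param cut breadth threshold (default 4).
#' @return list with elements `le` (n <= cut) and `ge` (n > cut).
#' @export
split_by_breadth <- function(assignments, genes, cut = 4) {
  sets <- pathway_sets(assignments[assignments$gene %in% toupper(genes), ,
                                   drop = FALSE])
  n <- lengths(sets)
  list(le = names(n)[n <= cut], ge = names(n)[n > cut])
}

# Parse one normalized description as a regulation phrase.
# Returns list(polarity, tail) or NULL if not a regulation phrase.
parse_regulation <- function(desc_norm) {
  m <- regmatches(desc_norm,
                  regexec("^(positive |negative )?regulation of (.+)$", desc_norm))[[1]]
  if (length(m) == 0) return(NULL)
  pol <- trimws(m[2])
  list(polarity = if (pol == "") "general" else pol, tail = m[3])
}

#' Classify pathway regulators and their polarity
#'
#' Scans descriptions for regulation phrases ("positive regulation of X",
#' "negative regulation of X", bare "regulation of X") whose object maps to
#' one of the 13 pathways. A gene annotated as both a positive and a
#' negative regulator of the same pathway is classed as a "general"
#' regulator of that pathway, as is a gene with only an unsigned regulation
#' phrase. Genes regulating two or more distinct pathways are flagged
#' multi-pathway regulators.
#'
#' @param composite composite annotation table (`gene`, `description`).
#' @param lexicon phrase-to-pathway table.
#' @return data.frame `gene`, `pathway`, `polarity` ("positive", "negative"
#'   or "general") with attribute `multi_pathway` (genes regulating >= 2
#'   pathways). Regulation phrases whose object matches no pathway are
#'   counted in attribute `n_unparsed` and otherwise ignored.
#' @export
classify_regulators <- function(composite, lexicon = default_pathway_lexicon()) {
  lexicon <- check_lexicon(lexicon)
  dn <- norm_text(composite$description)
  recs <- list()
  n_unparsed <- 0L
  for (i in seq_along(dn)) {
    reg <- parse_regulation(dn[i])
    if (is.null(reg)) next
    pws <- match_pathways(reg$tail, lexicon)
    if (length(pws) == 0) { n_unparsed <- n_unparsed + 1L; next }
    for (pw in pws)
      recs[[length(recs) + 1L]] <- data.frame(
        gene = composite$gene[i], pathway = pw, polarity = reg$polarity,
        stringsAsFactors = FALSE)
  }
  if (n_unparsed > 0)
    tcx_log(sprintf("classify_regulators: %d regulation phrase(s) matched no pathway; ignored",
                    n_unparsed))
  df <- if (length(recs) > 0) do.call(rbind, recs) else
    data.frame(gene = character(), pathway = character(), polarity = character(),
               stringsAsFactors = FALSE)
  # collapse per gene x pathway: positive + negative (or unsigned) -> general
  key <- paste(df$gene, df$pathway, sep = "\r")
  out <- lapply(unique(key), function(k) {
    rows <- df[key == k, , drop = FALSE]
    pol <- unique(rows$polarity)
    p <- if ("positive" %in% pol && "negative" %in% pol) "general"
         else if (identical(pol, "positive")) "positive"
         else if (identical(pol, "negative")) "negative"
         else if ("positive" %in% pol) "positive"
         else if ("negative" %in% pol) "negative"
         else "general"
    # an unsigned phrase alongside a single signed one keeps the signed polarity,
    # except that signed-both always collapses to general (handled above)
    data.frame(gene = rows$gene[1], pathway = rows$pathway[1], polarity = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(data.frame(gene = character(),
                                               pathway = character(),
                                               polarity = character(),
                                               stringsAsFactors = FALSE))))
  res <- res[order(res$gene, match(res$pathway, MAPK_PATHWAYS)), , drop = FALSE]
  rownames(res) <- NULL
  tab <- table(res$gene)
  attr(res, "multi_pathway") <- sort(names(tab)[tab >= 2])
  attr(res, "n_unparsed") <- n_unparsed
  res
}

#' Default enzyme-class keyword lexicon
#'
#' Keyword families (normalized-substring matched) for the kinase,
#' phosphatase, dual-specificity-phosphatase and MAPKKK-associated flags.
#'
#' @return named list of character keyword vectors.
#' @export
default_enzyme_lexicon <- function() {
  list(
    kinase = c("protein kinase activity", "kinase activity",
               "protein serine/threonine kinase"),
    phosphatase = c("phosphatase"),
    dual_specificity = c("dual specificity phosphatase",
                         "dual specificity protein phosphatase"),
    mapkkk = c("MAP kinase kinase kinase", "MAPKKK", "MAP kinase phosphatase"))
}

#' Classify kinase/phosphatase enzyme annotations
#'
#' Flags each gene for kinase activity, phosphatase activity,
#' dual-specificity phosphatase (which implies phosphatase) and MAPKKK
#' association, and records polarity of regulation-of-kinase /
#' regulation-of-phosphatase phrases analogously to [classify_regulators()].
#'
#' @param composite composite annotation table (`gene`, `description`).
#' @param lexicon keyword lexicon; see [default_enzyme_lexicon()].
#' @return data.frame with columns `gene`, `kinase`, `phosphatase`,
#'   `dual_specificity`, `mapkkk`, `reg_kinase`, `reg_phosphatase` (the last
#'   two in \{"none","positive","negative","general"\}).
#' @export
classify_enzymes <- function(composite, lexicon = default_enzyme_lexicon()) {
  genes <- unique(composite$gene)
  dn <- norm_text(composite$description)
  has_kw <- function(ds, kws) {
    any(vapply(norm_text(kws), function(k)
      any(grepl(k, ds, fixed = TRUE)), logical(1)))
  }
  reg_pol <- function(ds, what) {
    pols <- character(0)
    for (d in ds) {
      reg <- parse_regulation(d)
      if (is.null(reg)) next
      if (grepl(what, reg$tail, fixed = TRUE)) pols <- c(pols, reg$polarity)
    }
    if (length(pols) == 0) return("none")
    u <- unique(pols)
    if ("positive" %in% u && "negative" %in% u) "general"
    else if (identical(u, "positive")) "positive"
    else if (identical(u, "negative")) "negative"
    else if ("positive" %in% u) "positive"
    else if ("negative" %in% u) "negative"
    else "general"
  }
  rows <- lapply(genes, function(g) {
    ds <- dn[composite$gene == g]
    dual <- has_kw(ds, lexicon$dual_specificity)
    data.frame(gene = g,
               kinase = has_kw(ds, lexicon$kinase),
               phosphatase = dual || has_kw(ds, lexicon$phosphatase),
               dual_specificity = dual,
               mapkkk = has_kw(ds, lexicon$mapkkk),
               reg_kinase = reg_pol(ds, "kinase activity"),
               reg_phosphatase = reg_pol(ds, "phosphatase activity"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Pathway-by-age count table
#'
#' Tabulates, per pathway and age group, the number of annotated DE genes
#' and the number annotated with that single pathway only.
#'
#' @param assignments long `gene`/`pathway` table.
#' @param de_sets named list, age label -> character vector of DE genes.
#' @return data.frame `pathway`, then `<age>_all` and `<age>_single` columns.
#' @export
pathway_table <- function(assignments, de_sets) {
  out <- data.frame(pathway = MAPK_PATHWAYS, stringsAsFactors = FALSE)
  for (age in names(de_sets)) {
    sub <- assignments[assignments$gene %in% toupper(de_sets[[age]]), , drop = FALSE]
    sets <- pathway_sets(sub)
    all_n <- vapply(MAPK_PATHWAYS, function(pw)
      sum(vapply(sets, function(s) pw %in% s, logical(1))), integer(1))
    single_n <- vapply(MAPK_PATHWAYS, function(pw)
      sum(vapply(sets, function(s) identical(s, pw), logical(1))), integer(1))
    out[[paste0(age, "_all")]] <- all_n
    out[[paste0(age, "_single")]] <- single_n
  }
  out
}
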