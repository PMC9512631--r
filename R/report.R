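# Reporting: interpolated time-course curves, figures, and the end-to-end
# pipeline orchestrator.

#' Second-order interpolation of a fold-change time course
#'
#' Piecewise quadratic through consecutive point triples, used purely for
#' visual smoothing of time-course plots (it plays no role in statistics).
#' The curve passes exactly through every input point; with exactly two
#' points it reduces to linear interpolation.
#'
#' @param time_h strictly increasing (after sorting; duplicates are an
#'   error) numeric time points, >= 2 of them.
#' @param fc fold-change values at those times.
#' @param n_out number of output points spanning the time range.
#' @param at optional explicit evaluation times overriding `n_out`.
#' @return data.frame `time_h`, `fc`.
#' @export
interpolate_curve <- function(time_h, fc, n_out = 50, at = NULL) {
  if (length(time_h) < 2) stop("need >= 2 points")
  if (anyDuplicated(time_h)) stop("duplicate time points")
  ord <- order(time_h)
  tt <- time_h[ord]; yy <- fc[ord]
  xs <- if (is.null(at)) seq(min(tt), max(tt), length.out = n_out) else at
  m <- length(tt)
  lagrange3 <- function(x, t3, y3) {
    y3[1] * (x - t3[2]) * (x - t3[3]) / ((t3[1] - t3[2]) * (t3[1] - t3[3])) +
    y3[2] * (x - t3[1]) * (x - t3[3]) / ((t3[2] - t3[1]) * (t3[2] - t3[3])) +
    y3[3] * (x - t3[1]) * (x - t3[2]) / ((t3[3] - t3[1]) * (t3[3] - t3[2]))
  }
  ys <- vapply(xs, function(x) {
    if (m == 2) {
      yy[1] + (yy[2] - yy[1]) * (x - tt[1]) / (tt[2] - tt[1])
    } else {
      j <- findInterval(x, tt, all.inside = TRUE)  # segment [tt_j, tt_j+1]
      k <- max(1L, min(j - 1L, m - 2L))            # triple k..k+2 covering it
      lagrange3(x, tt[k:(k + 2)], yy[k:(k + 2)])
    }
  }, numeric(1))
  data.frame(time_h = xs, fc = ys)
}

#' Plot interpolated time courses on log axes
#'
#' Log-scaled time axis (to discriminate 1 h from 6 h) and log-scaled fold
#' axis; one interpolated line per gene. Genes present in both age groups
#' are drawn gray, first-age-only blue, second-age-only red.
#'
#' @param de selected DE rows (`gene`, `age`, `time_h`, `fc`).
#' @param membership named character vector gene -> "shared", "a_only" or
#'   "b_only"; defaults to "shared" for all.
#' @param main plot title.
#' @return invisibly, the list of interpolated curves.
#' @export
plot_time_courses <- function(de, membership = NULL, main = "") {
  cols <- c(shared = "gray40", a_only = "blue", b_only = "red")
  genes <- unique(de$gene)
  if (is.null(membership))
    membership <- stats::setNames(rep("shared", length(genes)), genes)
  curves <- list()
  rng_y <- range(de$fc)
  graphics::plot(range(de$time_h), rng_y, type = "n", log = "xy",
                 xlab = "time after KA-SE (h)", ylab = "fold change",
                 main = main)
  graphics::abline(h = 1, lty = 3, col = "gray70")
  for (g in genes) {
    sub <- de[de$gene == g, , drop = FALSE]
    if (nrow(sub) < 2) {
      graphics::points(sub$time_h, sub$fc, pch = 16,
                       col = cols[[membership[[g]]]])
      next
    }
    cu <- interpolate_curve(sub$time_h, sub$fc, n_out = 80)
    cu$fc[cu$fc <= 0] <- min(sub$fc) * 0.5  # guard for the log axis only
    graphics::lines(cu$time_h, cu$fc, col = cols[[membership[[g]]]])
    graphics::points(sub$time_h, sub$fc, pch = 16, cex = 0.6, col = "black")
    curves[[g]] <- cu
  }
  invisible(curves)
}

#' Render an array-plot matrix as a heat map
#'
#' Upper triangle: upregulated pair counts (oranges); lower triangle:
#' downregulated (blues); family boundaries (Classical | SAPK | Other)
#' drawn as boxes.
#'
#' @param mat 13 x 13 matrix from [array_plot_matrix()].
#' @param main plot title.
#' @export
plot_array_heat <- function(mat, main = "") {
  n <- nrow(mat)
  graphics::image(seq_len(n), seq_len(n), t(mat[n:1, ]),
                  col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "", main = main)
  graphics::axis(1, at = seq_len(n), labels = seq_len(n), las = 1, cex.axis = 0.7)
  graphics::axis(2, at = seq_len(n), labels = rev(seq_len(n)), las = 1,
                 cex.axis = 0.7)
  for (b in c(0, 3, 9, 13) + 0.5) {
    graphics::abline(v = b, col = "gray30")
    graphics::abline(h = n - b + 1, col = "gray30")
  }
  invisible(mat)
}

#' Default pipeline configuration
#'
#' Nested list mirroring the design/effect/corpus specifications plus the
#' selection thresholds. The defaults run a reduced-size but structurally
#' faithful study (the full 60-profile factorial layout with a smaller gene
#' panel) so the end-to-end pipeline stays fast.
#'
#' @param n_genes,n_de study size knobs.
#' @return nested configuration list.
#' @export
default_config <- function(n_genes = 1200, n_de = 80) {
  list(
    design = list(age_groups = c("P15", "P30"),
                  treatments = c("PBS", "KA"),
                  time_points_h = c(1, 6, 24, 72, 240),
                  replicates_per_cell = 3,
                  n_genes = n_genes),
    effects = list(n_de = n_de, noise_sd = 0.3,
                   baseline_log2_mean = 6, baseline_log2_sd = 1.5),
    corpus = list(n_sources = 3, alias_rate = 0.3),
    rule = list(fc_up = 2, fc_down = 0.5, p_max = 0.05, q_max = 0.05,
                use_q = TRUE, min_present = 2, presence = "either_group"),
    n_permutations = "exhaustive",
    qpcr = list(n_genes = 12, n_control = 3, n_treated = 3,
                ct_noise_sd = 0.2))
}

#' Read a pipeline configuration from YAML
#'
#' Missing fields fall back to [default_config()] values.
#'
#' @param path YAML file.
#' @return nested configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- default_config()
  merge_lists <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge_lists(a[[nm]], b[[nm]]) else b[[nm]]
    }
    a
  }
  merge_lists(base, user)
}

#' Run the whole pipeline end to end
#'
#' Generates (or loads) a study, runs differential expression per age and
#' time point, selects significant genes, builds the composite annotation
#' database for them, maps pathways (table, array plots, regulators,
#' enzymes), simulates and analyses a qPCR panel, and writes every tabular
#' output plus a run log to `out_dir`. Given the same configuration and
#' seed the tabular outputs are byte-identical; figure rendering never
#' alters them.
#'
#' @param config nested list from [default_config()]/[read_config()], or a
#'   path to a YAML file.
#' @param seed integer master seed.
#' @param out_dir output directory.
#' @param study optional pre-built `tcx_study` + truth list (as returned by
#'   [generate_study()]); when `NULL` one is generated from `config`.
#' @param figures also render PNG figures (default off).
#' @return invisible list of the main in-memory results.
#' @export
run_pipeline <- function(config = default_config(), seed = 1, out_dir,
                         study = NULL, figures = FALSE) {
  if (is.character(config)) config <- read_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "setup"
  result <- tryCatch({
    stage <- "synth"
    design <- do.call(design_spec, config$design)
    effects <- do.call(effect_spec, config$effects)
    if (is.null(study)) study <- generate_study(design, effects, seed = seed)
    truth <- study$truth
    study <- study$study
    write_study(study, out_dir)
    write_tsv(truth, file.path(out_dir, "truth_de.tsv"))

    stage <- "diffexpr"
    rule <- do.call(selection_rule, config$rule)
    de <- run_de(study, rule, n_permutations = config$n_permutations,
                 seed = seed)
    write_tsv(de, file.path(out_dir, "de.tsv"))
    sel <- select_significant(de, rule)
    ages <- names(sel$selected)
    write_tsv(sel$detail, file.path(out_dir, "selected.tsv"))
    venn <- if (length(ages) >= 2)
      summarize_sets(sel$selected[[1]], sel$selected[[2]],
                     label_a = ages[1], label_b = ages[2]) else NULL
    if (!is.null(venn)) {
      write_tsv(data.frame(quantity = c(ages[1], ages[2], "shared", "union",
                                        paste0(ages[1], "_only"),
                                        paste0(ages[2], "_only")),
                           n = c(venn$n_a, venn$n_b, venn$n_shared,
                                 venn$n_union, venn$n_a_only, venn$n_b_only)),
                file.path(out_dir, "venn.tsv"))
    }
    write_tsv(count_directions(de[de$significant, , drop = FALSE]),
              file.path(out_dir, "direction_counts.tsv"))

    stage <- "ontology"
    de_genes <- sort(unique(unlist(sel$selected)))
    corpus_spec <- do.call(annotation_corpus_spec, config$corpus)
    all_genes <- rownames(study$signals)
    corpus <- generate_annotation_corpus(
      corpus_spec, if (length(de_genes) > 0) de_genes else all_genes[1],
      seed = seed)
    composite <- build_composite(corpus$sources, corpus$aliases)
    write_tsv(stats::aggregate(description ~ gene, composite,
                               FUN = paste, collapse = " | "),
              file.path(out_dir, "composite.tsv"))
    write_tsv(count_terms(composite), file.path(out_dir, "term_counts.tsv"))
    write_tsv(keyword_group(composite), file.path(out_dir, "groups.tsv"))

    stage <- "pathways"
    assignments <- assign_pathways(composite)
    write_tsv(assignments, file.path(out_dir, "pathway_sets.tsv"))
    writeLines(attr(assignments, "unannotated"),
               file.path(out_dir, "unannotated_genes.txt"))
    ptab <- pathway_table(assignments, sel$selected)
    write_tsv(ptab, file.path(out_dir, "pathway_table.tsv"))
    for (age in ages) {
      for (tp in sort(unique(de$time_h))) {
        sig_rows <- de[de$age == age & de$time_h == tp & de$significant, ,
                       drop = FALSE]
        part <- partition_single_multiple(assignments, sig_rows$gene)
        multi <- sig_rows[sig_rows$gene %in% part$multiple, , drop = FALSE]
        if (nrow(multi) == 0) next
        mat <- array_plot_matrix(assignments,
                                 stats::setNames(multi$direction, multi$gene))
        write_tsv(data.frame(pathway = rownames(mat), mat, check.names = FALSE),
                  file.path(out_dir, sprintf("arrayplot_%s_%gh.tsv", age, tp)))
      }
    }
    regulators <- classify_regulators(composite)
    write_tsv(regulators, file.path(out_dir, "regulators.tsv"))
    enzymes <- classify_enzymes(composite)
    write_tsv(enzymes, file.path(out_dir, "enzymes.tsv"))

    stage <- "qpcr"
    qcfg <- config$qpcr
    panel <- utils::head(if (length(de_genes) > 0) de_genes else all_genes,
                         qcfg$n_genes)
    true_folds <- with_seed(derive_seed(seed, "qpcr_folds"),
                            2^stats::runif(length(panel), -2, 4))
    # anchor injected qPCR folds to the array's observed folds where possible
    last_age <- ages[length(ages)]
    fc_lookup <- de[de$age == last_age & de$time_h == 24, , drop = FALSE]
    hit <- match(panel, fc_lookup$gene)
    true_folds[!is.na(hit)] <- fc_lookup$fc[hit[!is.na(hit)]]
    ctab <- generate_ct_table(panel, true_folds,
                              n_control = qcfg$n_control,
                              n_treated = qcfg$n_treated,
                              ct_noise_sd = qcfg$ct_noise_sd, seed = seed)
    write_tsv(ctab, file.path(out_dir, "ct.tsv"))
    qp <- ddct_fold(ctab)
    write_tsv(qp, file.path(out_dir, "qpcr_folds.tsv"))
    conc <- concordance(fc_lookup, qp)
    write_tsv(conc$report, file.path(out_dir, "concordance.tsv"))
    write_tsv(data.frame(count = names(unlist(conc$counts)),
                         n = unlist(conc$counts)),
              file.path(out_dir, "concordance_counts.tsv"))

    stage <- "figures"
    if (figures) {
      grDevices::png(file.path(out_dir, "time_courses.png"), 900, 700)
      shared <- if (!is.null(venn)) venn$shared else character(0)
      det <- sel$detail
      memb <- stats::setNames(
        ifelse(unique(det$gene) %in% shared, "shared",
               ifelse(unique(det$gene) %in% sel$selected[[1]], "a_only",
                      "b_only")), unique(det$gene))
      try(plot_time_courses(det, memb, main = "selected genes"), silent = TRUE)
      grDevices::dev.off()
    }

    stage <- "log"
    writeLines(c(
      sprintf("tcx version: %s", as.character(utils::packageVersion("tcx"))),
      sprintf("seed: %d", seed),
      sprintf("genes: %d  samples: %d", nrow(study$signals), ncol(study$signals)),
      sprintf("thresholds: fc_up=%g fc_down=%g p<%g q<%g", rule$fc_up,
              rule$fc_down, rule$p_max, rule$q_max),
      sprintf("permutations: %s", paste(config$n_permutations, collapse = ""))),
      file.path(out_dir, "run_log.txt"))

    list(study = study, truth = truth, de = de, selection = sel, venn = venn,
         composite = composite, assignments = assignments,
         pathway_table = ptab, regulators = regulators, enzymes = enzymes,
         qpcr = qp, concordance = conc)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
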