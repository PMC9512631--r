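# qRT-PCR: delta-delta-Ct fold changes with unpaired t-tests, and the
# microarray-vs-qPCR concordance accounting.

#' Delta-delta-Ct relative quantification
#'
#' Normalizes each gene's cycle threshold to the housekeeping Ct of the same
#' sample (dCt), compares treated against control group means (ddCt =
#' mean dCt treated − mean dCt control) and reports the relative fold as
#' 2^(−ddCt). Group comparison uses a two-sided unpaired Student's t-test
#' on the per-sample dCt values. The computation is invariant to adding a
#' constant to every Ct of a sample, because the housekeeping normalization
#' cancels it.
#'
#' @param ct long data.frame with columns `sample`, `gene`, `ct`,
#'   `is_housekeeping`, `group`.
#' @param group_control,group_treated the two group labels present in
#'   `ct$group`.
#' @param housekeeping `"mean"` (default: arithmetic mean Ct of all flagged
#'   housekeeping genes per sample) or the name of a single housekeeping
#'   gene.
#' @param p_max significance threshold applied to the reported flag.
#' @return data.frame `gene`, `dct_control`, `dct_treated`, `ddct`, `fold`,
#'   `p`, `significant`.
#' @export
ddct_fold <- function(ct, group_control = "control", group_treated = "treated",
                      housekeeping = "mean", p_max = 0.05) {
  need <- c("sample", "gene", "ct", "is_housekeeping", "group")
  miss <- setdiff(need, names(ct))
  if (length(miss) > 0) stop("Ct table lacks columns: ", paste(miss, collapse = ", "))
  ct$gene <- toupper(ct$gene)
  if (!all(c(group_control, group_treated) %in% ct$group))
    stop("missing group(s): ",
         paste(setdiff(c(group_control, group_treated), unique(ct$group)),
               collapse = ", "))
  if (any(!is.finite(ct$ct))) stop("non-finite Ct value(s)")

  hk_rows <- if (identical(housekeeping, "mean")) {
    ct[ct$is_housekeeping, , drop = FALSE]
  } else {
    ct[ct$gene == toupper(housekeeping) & ct$is_housekeeping, , drop = FALSE]
  }
  samples <- unique(ct$sample)
  no_hk <- setdiff(samples, unique(hk_rows$sample))
  if (length(no_hk) > 0)
    stop("missing housekeeping Ct for sample(s): ", paste(no_hk, collapse = ", "))
  hk <- tapply(hk_rows$ct, hk_rows$sample, mean)

  ct$dct <- ct$ct - unname(hk[ct$sample])
  out <- lapply(unique(ct$gene), function(g) {
    sub <- ct[ct$gene == g, , drop = FALSE]
    dct_c <- sub$dct[sub$group == group_control]
    dct_t <- sub$dct[sub$group == group_treated]
    if (length(dct_c) == 0 || length(dct_t) == 0) return(NULL)
    ddct <- mean(dct_t) - mean(dct_c)
    p <- if (length(dct_c) >= 2 && length(dct_t) >= 2 &&
             (stats::var(dct_c) > 0 || stats::var(dct_t) > 0)) {
      stats::t.test(dct_t, dct_c, var.equal = TRUE)$p.value
    } else if (isTRUE(all.equal(mean(dct_t), mean(dct_c)))) 1 else {
      .Machine$double.xmin
    }
    data.frame(gene = g, dct_control = mean(dct_c), dct_treated = mean(dct_t),
               ddct = ddct, fold = 2^(-ddct), p = p, significant = p < p_max,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Microarray-vs-qPCR concordance accounting
#'
#' Applies the nested filters used to validate array calls against qPCR:
#' genes shared between the two platforms, of those the array-significant
#' ones, of those the ones whose qPCR fold agrees in trend with the array
#' direction, of those the qPCR-significant ones, and of those the ones
#' beyond the fold threshold.
#'
#' @param array_de data.frame with columns `gene`, `direction`
#'   ("up"/"down"/"none"), `significant` — e.g. one age/time slice of
#'   [run_de()] output.
#' @param qpcr output of [ddct_fold()].
#' @param fold_threshold qPCR fold-change magnitude for the last filter
#'   (default 2: fold > 2 or < 1/2).
#' @return list with `report` (per shared gene: directions, agreement and
#'   significance flags, qPCR fold) and `counts` (`n_shared`,
#'   `n_array_significant`, `n_same_trend`, `n_qpcr_significant`,
#'   `n_beyond_fold`).
#' @export
concordance <- function(array_de, qpcr, fold_threshold = 2) {
  shared <- intersect(toupper(array_de$gene), toupper(qpcr$gene))
  a <- array_de[match(shared, toupper(array_de$gene)), , drop = FALSE]
  qp <- qpcr[match(shared, toupper(qpcr$gene)), , drop = FALSE]
  qdir <- ifelse(qp$fold > 1, "up", ifelse(qp$fold < 1, "down", "none"))
  report <- data.frame(
    gene = shared,
    array_direction = a$direction,
    array_significant = a$significant,
    qpcr_direction = qdir,
    qpcr_fold = qp$fold,
    qpcr_significant = qp$significant,
    same_trend = a$direction != "none" & qdir != "none" & a$direction == qdir,
    stringsAsFactors = FALSE)
  sig <- report$array_significant
  trend <- sig & report$same_trend
  qsig <- trend & report$qpcr_significant
  beyond <- qsig & (report$qpcr_fold > fold_threshold |
                      report$qpcr_fold < 1 / fold_threshold)
  list(report = report,
       counts = list(n_shared = length(shared),
                     n_array_significant = sum(sig),
                     n_same_trend = sum(trend),
                     n_qpcr_significant = sum(qsig),
                     n_beyond_fold = sum(beyond)))
}
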