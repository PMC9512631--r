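# Differential expression: presence filtering, normalization, fold change,
# unpaired t-tests, SAM-style permutation q-values, joint selection rule and
# set accounting.

#' Selection rule for differential expression
#'
#' Defaults are the rat-study thresholds: fold change > 2 (or < 0.5 for
#' downregulation), p < 0.05 and q < 0.05, with a gene called significant
#' for an age group if all criteria hold jointly at >= 1 time point, and a
#' presence rule requiring a Present call in at least two of three
#' replicates in either the control or the treated group. [human_selection_rule()]
#' gives the human-study variant (fold 1.5, t-test only, Present in all
#' samples).
#'
#' @param fc_up,fc_down fold-change thresholds (up > 1 > down > 0).
#' @param p_max,q_max significance thresholds in (0, 1].
#' @param use_q apply the q-value criterion (FALSE for the human variant).
#' @param min_present minimum Present calls per group for the
#'   "either group" presence rule.
#' @param presence `"either_group"` or `"all_samples"`.
#' @return a `tcx_rule` list.
#' @export
selection_rule <- function(fc_up = 2, fc_down = 0.5, p_max = 0.05,
                           q_max = 0.05, use_q = TRUE, min_present = 2,
                           presence = c("either_group", "all_samples")) {
  presence <- match.arg(presence)
  if (!(fc_up > 1 && 1 > fc_down && fc_down > 0))
    stop("need fc_up > 1 > fc_down > 0")
  if (p_max <= 0 || p_max > 1 || q_max <= 0 || q_max > 1)
    stop("p/q thresholds must lie in (0, 1]")
  structure(list(fc_up = fc_up, fc_down = fc_down, p_max = p_max,
                 q_max = q_max, use_q = use_q, min_present = min_present,
                 presence = presence),
            class = "tcx_rule")
}

#' @rdname selection_rule
#' @export
human_selection_rule <- function() {
  selection_rule(fc_up = 1.5, fc_down = 1 / 1.5, p_max = 0.05, q_max = 1,
                 use_q = FALSE, presence = "all_samples")
}

#' Presence filter on detection calls
#'
#' Retains genes whose detection calls meet the presence rule for a
#' contrast: under `"either_group"`, at least `min_present` Present calls in
#' the treated or in the control group; under `"all_samples"`, a Present
#' call in every sample of both groups. Gene order is preserved.
#'
#' @param study a `tcx_study`.
#' @param treated,control sample-ID vectors of the two groups.
#' @param rule a [selection_rule()].
#' @return character vector of retained genes.
#' @export
presence_filter <- function(study, treated, control, rule = selection_rule()) {
  stopifnot(all(c(treated, control) %in% colnames(study$calls)))
  ct <- study$calls[, treated, drop = FALSE] == "P"
  cc <- study$calls[, control, drop = FALSE] == "P"
  if (rule$presence == "either_group") {
    if (length(treated) < rule$min_present || length(control) < rule$min_present)
      stop(sprintf("replicate count below the presence minimum (%d)",
                   rule$min_present))
    keep <- rowSums(ct) >= rule$min_present | rowSums(cc) >= rule$min_present
  } else {
    keep <- rowSums(ct) == length(treated) & rowSums(cc) == length(control)
  }
  rownames(study$signals)[keep]
}

#' Normalize a study by per-sample median scaling
#'
#' Divides every sample's signals by that sample's median, so the per-sample
#' median of normalized signals is exactly 1. The method is
#' scale-equivariant: multiplying one sample's raw signals by a constant
#' leaves its normalized values unchanged. Statistics downstream are taken
#' on log2 normalized values; fold changes on the linear scale.
#'
#' @param study a `tcx_study`.
#' @param method only `"median"` is implemented.
#' @return the study with normalized signals (attribute `normalized` set).
#' @export
normalize_study <- function(study, method = "median") {
  method <- match.arg(method, "median")
  if (nrow(study$signals) > 1) {
    v <- apply(study$signals, 2, stats::var)
    if (any(v == 0))
      stop("zero-variance sample(s): ",
           paste(colnames(study$signals)[v == 0], collapse = ", "))
  }
  med <- apply(study$signals, 2, stats::median)
  study$signals <- sweep(study$signals, 2, med, "/")
  attr(study, "normalized") <- TRUE
  study
}

#' Per-gene fold change between two sample groups
#'
#' Ratio of group means on the linear (normalized) signal scale.
#' Downregulation is reported as fc < 1, never as a negative reciprocal, so
#' fc(treated, control) * fc(control, treated) = 1 holds exactly.
#'
#' @param study a (normalized) `tcx_study`.
#' @param treated,control disjoint non-empty sample-ID vectors.
#' @param genes optional gene subset.
#' @return named numeric vector of fold changes.
#' @export
fold_change <- function(study, treated, control, genes = NULL) {
  if (length(treated) == 0 || length(control) == 0)
    stop("both groups must be non-empty")
  if (length(intersect(treated, control)) > 0)
    stop("groups overlap: ", paste(intersect(treated, control), collapse = ", "))
  x <- study$signals
  if (!is.null(genes)) x <- x[toupper(genes), , drop = FALSE]
  rowMeans(x[, treated, drop = FALSE]) / rowMeans(x[, control, drop = FALSE])
}

#' Per-gene unpaired t-test p-values
#'
#' Two-sided Student's t-test (pooled variance) on log2 normalized signals,
#' vectorized over genes. When the pooled variance of a gene is zero the
#' probability is defined as 1 if the group means are equal and the smallest
#' representable positive value otherwise (logged).
#'
#' @param study a (normalized) `tcx_study`.
#' @param treated,control sample-ID vectors, >= 2 samples each.
#' @param genes optional gene subset.
#' @return named numeric vector of p-values.
#' @export
ttest_p <- function(study, treated, control, genes = NULL) {
  if (length(treated) < 2 || length(control) < 2)
    stop("need >= 2 samples per group")
  x <- log2(study$signals)
  if (!is.null(genes)) x <- x[toupper(genes), , drop = FALSE]
  xt <- x[, treated, drop = FALSE]; xc <- x[, control, drop = FALSE]
  n1 <- length(treated); n2 <- length(control)
  m1 <- rowMeans(xt); m2 <- rowMeans(xc)
  ss <- rowSums((xt - m1)^2) + rowSums((xc - m2)^2)
  df <- n1 + n2 - 2
  se <- sqrt(ss / df * (1 / n1 + 1 / n2))
  p <- numeric(nrow(x)); names(p) <- rownames(x)
  ok <- se > 0
  p[ok] <- 2 * stats::pt(-abs((m1[ok] - m2[ok]) / se[ok]), df)
  if (any(!ok)) {
    tcx_log(sprintf("ttest_p: %d gene(s) with zero pooled variance", sum(!ok)))
    p[!ok] <- ifelse(m1[!ok] == m2[!ok], 1, .Machine$double.xmin)
  }
  p
}

# Label permutations: each column of the returned index matrix gives the
# sample positions (within c(treated, control)) assigned to the treated arm.
perm_assignments <- function(n1, n2, n_permutations, seed) {
  total <- choose(n1 + n2, n1)
  if (identical(n_permutations, "exhaustive") || total <= n_permutations) {
    if (total > 1e5)
      stop("exhaustive permutation set too large (", total, ")")
    return(utils::combn(n1 + n2, n1))
  }
  # sample distinct assignments, always keeping the observed labelling
  with_seed(derive_seed(seed, "perm"), {
    seen <- new.env(hash = TRUE)
    out <- list(seq_len(n1))
    assign(paste(seq_len(n1), collapse = ","), TRUE, envir = seen)
    while (length(out) < n_permutations) {
      cand <- sort(sample(n1 + n2, n1))
      key <- paste(cand, collapse = ",")
      if (!exists(key, envir = seen)) {
        assign(key, TRUE, envir = seen)
        out[[length(out) + 1L]] <- cand
      }
    }
    matrix(unlist(out), nrow = n1)
  })
}

sam_scores <- function(X, idx_t, idx_c, s0) {
  n1 <- length(idx_t); n2 <- length(idx_c)
  xt <- X[, idx_t, drop = FALSE]; xc <- X[, idx_c, drop = FALSE]
  m1 <- rowMeans(xt); m2 <- rowMeans(xc)
  ss <- rowSums((xt - m1)^2) + rowSums((xc - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  list(d = (m1 - m2) / (s + s0), s = s)
}

# SAM's fudge factor: the percentile of the gene-wise standard errors that
# minimizes the coefficient of variation of the spread of d across bins of
# s; falls back to median(s) when the search degenerates.
choose_s0 <- function(X, idx_t, idx_c) {
  sc <- sam_scores(X, idx_t, idx_c, s0 = 0)
  s <- sc$s
  if (all(s == 0)) return(stats::median(s))
  cands <- unique(stats::quantile(s, seq(0, 1, by = 0.05), names = FALSE))
  n_bins <- max(2L, min(100L, floor(length(s) / 20)))
  bins <- cut(rank(s, ties.method = "first"), breaks = n_bins, labels = FALSE)
  cv <- vapply(cands, function(s0) {
    d <- sam_scores(X, idx_t, idx_c, s0)$d
    mads <- tapply(d, bins, stats::mad)
    mads <- mads[is.finite(mads)]
    if (length(mads) < 2 || mean(mads) == 0) return(Inf)
    stats::sd(mads) / mean(mads)
  }, numeric(1))
  if (all(!is.finite(cv))) return(stats::median(s))
  cands[which.min(cv)]
}

#' SAM-style permutation q-values
#'
#' Implements the significance-analysis-of-microarrays skeleton: a moderated
#' score d = (mean difference) / (s + s0) with the fudge factor s0 chosen to
#' minimize the coefficient of variation of d's spread across bins of s;
#' label permutations (exhaustive when feasible, otherwise distinct sampled
#' assignments including the observed one); the false-discovery rate at each
#' gene's |d| estimated as pi0 times the median permuted count of scores at
#' or beyond that threshold (inclusive on both tails, a conservative
#' tie-break) over the observed count; pi0 by the standard interquartile
#' estimate from the permuted scores; and monotonicity enforced so that a
#' larger |d| never receives a larger q.
#'
#' @param study a (normalized) `tcx_study`.
#' @param treated,control sample-ID vectors.
#' @param genes optional gene subset.
#' @param n_permutations `"exhaustive"` (default; all distinct label
#'   assignments) or an integer. When the requested number exceeds the
#'   number of distinct assignments, all of them are used (logged).
#' @param seed integer seed (only used when permutations are sampled).
#' @return data.frame `gene`, `d`, `q` with attributes `s0`, `pi0`,
#'   `n_permutations`.
#' @export
qvalue_sam <- function(study, treated, control, genes = NULL,
                       n_permutations = "exhaustive", seed = 1) {
  X <- log2(study$signals)
  if (!is.null(genes)) X <- X[toupper(genes), , drop = FALSE]
  X <- X[, c(treated, control), drop = FALSE]
  n1 <- length(treated); n2 <- length(control)
  if (!identical(n_permutations, "exhaustive") &&
      n_permutations >= choose(n1 + n2, n1))
    tcx_log(sprintf("requested %s permutations but only %d distinct exist; using all",
                    n_permutations, choose(n1 + n2, n1)))
  idx_t <- seq_len(n1); idx_c <- n1 + seq_len(n2)
  s0 <- choose_s0(X, idx_t, idx_c)
  d <- sam_scores(X, idx_t, idx_c, s0)$d
  ad <- abs(d)
  m <- length(d)

  perms <- perm_assignments(n1, n2, n_permutations, seed)
  B <- ncol(perms)
  all_idx <- seq_len(n1 + n2)
  # counts of permuted |d*| >= each observed |d| (inclusive both tails)
  cnt <- matrix(0L, nrow = m, ncol = B)
  dperm_all <- numeric(0)
  for (b in seq_len(B)) {
    it <- perms[, b]; ic <- setdiff(all_idx, it)
    db <- sam_scores(X, it, ic, s0)$d
    sv <- sort(abs(db))
    cnt[, b] <- m - findInterval(ad, sv, left.open = TRUE)
    dperm_all <- c(dperm_all, db)
  }
  qq <- stats::quantile(dperm_all, c(0.25, 0.75), names = FALSE)
  pi0 <- min(1, sum(d > qq[1] & d < qq[2]) / (0.5 * m))
  sv_obs <- sort(ad)
  R <- m - findInterval(ad, sv_obs, left.open = TRUE)
  medV <- apply(cnt, 1, stats::median)
  q <- pmin(1, pi0 * medV / R)
  # monotone non-increasing in |d|
  ord <- order(ad, decreasing = TRUE)
  q[ord] <- cummax(q[ord])

  out <- data.frame(gene = rownames(X), d = d, q = q, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "s0") <- s0
  attr(out, "pi0") <- pi0
  attr(out, "n_permutations") <- B
  out
}

de_direction <- function(fc, p, q, rule) {
  sig <- p < rule$p_max & (!rule$use_q | q < rule$q_max)
  ifelse(sig & fc > rule$fc_up, "up",
         ifelse(sig & fc < rule$fc_down, "down", "none"))
}

#' Run the full differential-expression stage for a rat-mode study
#'
#' For every age group and time point, contrasts the treated against the
#' control arm: presence filter, per-sample median normalization (computed
#' once on the full study), fold change, t-test p, permutation q. Rows are
#' emitted only for genes passing the presence filter of their contrast.
#'
#' @param study a `tcx_study` in rat mode.
#' @param rule a [selection_rule()].
#' @param n_permutations passed to [qvalue_sam()].
#' @param seed integer seed.
#' @return data.frame `gene`, `age`, `time_h`, `fc`, `p`, `q`, `direction`,
#'   `significant` (per-row joint criterion).
#' @export
run_de <- function(study, rule = selection_rule(),
                   n_permutations = "exhaustive", seed = 1) {
  stopifnot(study$mode == "rat")
  norm <- normalize_study(study)
  treatments <- unique(study$design$treatment)
  ctrl_arm <- treatments[1]; trt_arm <- treatments[2]
  out <- list()
  for (age in unique(study$design$age)) {
    for (tp in sort(unique(study$design$time_h))) {
      treated <- select_samples(study, age = age, treatment = trt_arm,
                                time_h = tp)
      control <- select_samples(study, age = age, treatment = ctrl_arm,
                                time_h = tp)
      genes <- presence_filter(study, treated, control, rule)
      if (length(genes) == 0) next
      fc <- fold_change(norm, treated, control, genes = genes)
      p <- ttest_p(norm, treated, control, genes = genes)
      qv <- qvalue_sam(norm, treated, control, genes = genes,
                       n_permutations = n_permutations, seed = seed)
      q <- stats::setNames(qv$q, qv$gene)[genes]
      dir <- de_direction(fc, p, q, rule)
      out[[length(out) + 1L]] <- data.frame(
        gene = genes, age = age, time_h = tp, fc = unname(fc),
        p = unname(p), q = unname(q), direction = unname(dir),
        significant = unname(dir != "none"), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run the human case-control differential-expression variant
#'
#' Contrasts each case tissue group against the controls with the human
#' rule: Present in all samples, fold 1.5, t-test only (no q criterion).
#'
#' @param study a `tcx_study` in human mode.
#' @param rule a [selection_rule()]; default [human_selection_rule()].
#' @return data.frame `gene`, `contrast`, `fc`, `p`, `direction`,
#'   `significant`.
#' @export
run_de_human <- function(study, rule = human_selection_rule()) {
  stopifnot(study$mode == "human")
  norm <- normalize_study(study)
  control <- select_samples(study, condition = "control")
  out <- list()
  for (tis in unique(study$design$tissue[study$design$condition == "MTLE"])) {
    treated <- select_samples(study, condition = "MTLE", tissue = tis)
    genes <- presence_filter(study, treated, control, rule)
    if (length(genes) == 0) next
    fc <- fold_change(norm, treated, control, genes = genes)
    p <- ttest_p(norm, treated, control, genes = genes)
    dir <- de_direction(fc, p, rep(0, length(fc)), rule)
    out[[length(out) + 1L]] <- data.frame(
      gene = genes, contrast = paste0("MTLE_", tis, "_vs_control"),
      fc = unname(fc), p = unname(p), direction = unname(dir),
      significant = unname(dir != "none"), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate per-time-point results into per-age significance
#'
#' A gene is significant for an age group iff the joint rule (fold change,
#' p, and q when enabled) holds at >= 1 time point. Directions are kept per
#' time point.
#'
#' @param de output of [run_de()].
#' @param rule the [selection_rule()] used.
#' @param times expected time points; defaults to those present. A time
#'   point expected but absent from `de` is an error.
#' @return list with `selected` (named list age -> significant gene vector)
#'   and `detail` (the per-row table restricted to significant genes).
#' @export
select_significant <- function(de, rule = selection_rule(), times = NULL) {
  if (is.null(times)) times <- sort(unique(de$time_h))
  miss <- setdiff(times, unique(de$time_h))
  if (length(miss) > 0)
    stop("missing time point(s) in DE results: ", paste(miss, collapse = ", "))
  sel <- lapply(split(de, de$age), function(sub) {
    sort(unique(sub$gene[sub$significant]))
  })
  list(selected = sel, detail = de[de$gene %in% unlist(sel) & de$significant, ,
                                   drop = FALSE])
}

#' Set algebra summary of two DE gene sets
#'
#' Reports sizes, intersection, union, asymmetric differences and the two
#' headline percentages: shared genes as a fraction of the first set and
#' second-set-only genes as a fraction of the second set.
#'
#' @param set_a,set_b character vectors of gene symbols.
#' @param label_a,label_b display labels.
#' @return a `tcx_setsummary` list with `n_a`, `n_b`, `n_shared`, `n_union`,
#'   `n_a_only`, `n_b_only`, `pct_shared_of_a`, `pct_b_only_of_b`.
#' @export
summarize_sets <- function(set_a, set_b, label_a = "P15", label_b = "P30") {
  a <- unique(toupper(set_a)); b <- unique(toupper(set_b))
  shared <- intersect(a, b)
  structure(list(
    label_a = label_a, label_b = label_b,
    n_a = length(a), n_b = length(b),
    n_shared = length(shared),
    n_union = length(union(a, b)),
    n_a_only = length(setdiff(a, b)),
    n_b_only = length(setdiff(b, a)),
    pct_shared_of_a = if (length(a) > 0) 100 * length(shared) / length(a) else 0,
    pct_b_only_of_b = if (length(b) > 0) 100 * length(setdiff(b, a)) / length(b) else 0,
    shared = shared), class = "tcx_setsummary")
}

#' @export
print.tcx_setsummary <- function(x, ...) {
  cat(sprintf("%s: %d  %s: %d  shared: %d  union: %d\n",
              x$label_a, x$n_a, x$label_b, x$n_b, x$n_shared, x$n_union))
  cat(sprintf("shared/%s = %.1f%%  %s-only/%s = %.1f%%\n",
              x$label_a, x$pct_shared_of_a, x$label_b, x$label_b,
              x$pct_b_only_of_b))
  invisible(x)
}

#' Per-time-point direction counts
#'
#' @param de output of [run_de()].
#' @return data.frame `age`, `time_h`, `n_up`, `n_down`.
#' @export
count_directions <- function(de) {
  agg <- stats::aggregate(cbind(n_up = de$direction == "up",
                                n_down = de$direction == "down"),
                          by = list(age = de$age, time_h = de$time_h), FUN = sum)
  agg[order(agg$age, agg$time_h), , drop = FALSE]
}

#' Baseline developmental contrast (control vs control across ages)
#'
#' Applies the same statistics and selection machinery with age as the
#' grouping factor, comparing the control (PBS) samples of the second age
#' group against those of the first at every shared time point. The result
#' feeds the developmental-confound report: overlap of the baseline DE set
#' with the seizure-responsive sets.
#'
#' @param study a rat-mode `tcx_study`.
#' @param rule a [selection_rule()].
#' @param n_permutations,seed passed to [qvalue_sam()].
#' @return data.frame like [run_de()] with `age` set to
#'   `"<age2>_vs_<age1>_baseline"`.
#' @export
baseline_contrast <- function(study, rule = selection_rule(),
                              n_permutations = "exhaustive", seed = 1) {
  stopifnot(study$mode == "rat")
  ages <- unique(study$design$age)
  if (length(ages) < 2) stop("baseline contrast needs two age groups")
  ctrl_arm <- unique(study$design$treatment)[1]
  norm <- normalize_study(study)
  label <- paste0(ages[2], "_vs_", ages[1], "_baseline")
  out <- list()
  for (tp in sort(unique(study$design$time_h))) {
    treated <- select_samples(study, age = ages[2], treatment = ctrl_arm,
                              time_h = tp)
    control <- select_samples(study, age = ages[1], treatment = ctrl_arm,
                              time_h = tp)
    if (length(treated) == 0 || length(control) == 0) next
    genes <- presence_filter(study, treated, control, rule)
    if (length(genes) == 0) next
    fc <- fold_change(norm, treated, control, genes = genes)
    p <- ttest_p(norm, treated, control, genes = genes)
    qv <- qvalue_sam(norm, treated, control, genes = genes,
                     n_permutations = n_permutations, seed = seed)
    q <- stats::setNames(qv$q, qv$gene)[genes]
    dir <- de_direction(fc, p, q, rule)
    out[[length(out) + 1L]] <- data.frame(
      gene = genes, age = label, time_h = tp, fc = unname(fc),
      p = unname(p), q = unname(q), direction = unname(dir),
      significant = unname(dir != "none"), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
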