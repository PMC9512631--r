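test_that("presence filter applies the two-of-three / all-samples rules", {
  st <- tiny_study(
    list(KEEP  = c(100, 110, 90, 50, 55, 45),
         DROP  = c(100, 110, 90, 50, 55, 45),
         ALLP  = c(100, 110, 90, 50, 55, 45)),
    calls_rows = list(KEEP = c("P", "P", "A", "A", "A", "A"),
                      DROP = c("P", "A", "A", "M", "A", "A"),
                      ALLP = rep("P", 6)))
  trt <- tiny_treated(st); ctl <- tiny_control(st)
  kept <- presence_filter(st, trt, ctl, selection_rule())
  expect_true("KEEP" %in% kept)   # Present in 2/3 controls
  expect_false("DROP" %in% kept)
  kept_all <- presence_filter(st, trt, ctl, human_selection_rule())
  expect_identical(kept_all, "ALLP")
  expect_error(presence_filter(st, trt[1], ctl, selection_rule()),
               "replicate count")
})

test_that("median normalization hits 1 per sample and is scale-equivariant", {
  g <- generate_study(design_spec(age_groups = "P15",
                                  time_points_h = c(1, 6),
                                  n_genes = 20),
                      no_effects(), seed = 9)
  st <- g$study
  norm <- normalize_study(st)
  expect_equal(unname(apply(norm$signals, 2, median)), rep(1, ncol(norm$signals)))
  st2 <- st
  st2$signals[, 1] <- st2$signals[, 1] * 10
  norm2 <- normalize_study(st2)
  expect_equal(norm2$signals[, 1], norm$signals[, 1])
})

test_that("degenerate normalization inputs behave as specified", {
  sig <- matrix(c(3, 7), 1, 2, dimnames = list("A", c("s1", "s2")))
  calls <- matrix("P", 1, 2, dimnames = dimnames(sig))
  design <- data.frame(sample_id = c("s1", "s2"), age = "P15",
                       treatment = c("PBS", "KA"), time_h = 1, replicate = 1)
  one <- normalize_study(expression_study(sig, calls, design))
  expect_equal(unname(one$signals), matrix(1, 1, 2))
  sig2 <- matrix(c(2, 2, 3, 4), 2, 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  calls2 <- matrix("P", 2, 2, dimnames = dimnames(sig2))
  expect_error(normalize_study(expression_study(sig2, calls2, design)),
               "zero-variance")
})

test_that("fold change is the ratio of group means with exact reciprocity", {
  st <- tiny_study(list(G1 = c(100, 100, 100, 250, 250, 250)))
  trt <- tiny_treated(st); ctl <- tiny_control(st)
  expect_equal(unname(fold_change(st, trt, ctl)), 2.5)
  same <- tiny_study(list(G1 = c(100, 110, 90, 100, 110, 90)))
  expect_equal(unname(fold_change(same, tiny_treated(same), tiny_control(same))),
               1)
  g <- generate_study(design_spec(n_genes = 25), effect_spec(n_de = 5), seed = 2)
  norm <- normalize_study(g$study)
  a <- select_samples(norm, age = "P30", treatment = "KA", time_h = 6)
  b <- select_samples(norm, age = "P30", treatment = "PBS", time_h = 6)
  expect_equal(unname(fold_change(norm, a, b) * fold_change(norm, b, a)),
               rep(1, 25))
  expect_error(fold_change(st, character(0), ctl), "non-empty")
  expect_error(fold_change(st, trt, trt), "overlap")
})

test_that("injected log2 effect of +2 with negligible noise gives fold 4", {
  eff <- data.frame(gene = "G00001", age = "P30", time_h = 24, lfc = 2)
  g <- generate_study(design_spec(n_genes = 40),
                      effect_spec(effects = eff, noise_sd = 1e-9), seed = 3)
  st <- g$study
  trt <- select_samples(st, age = "P30", treatment = "KA", time_h = 24)
  ctl <- select_samples(st, age = "P30", treatment = "PBS", time_h = 24)
  fc <- fold_change(st, trt, ctl)
  expect_equal(unname(fc["G00001"]), 4, tolerance = 1e-5)
})

test_that("vectorized t-test agrees with stats::t.test and handles degeneracy", {
  set.seed(42)
  sig <- matrix(2^rnorm(10 * 6, 8, 1), 10, 6,
                dimnames = list(sprintf("G%02d", 1:10),
                                c(paste0("c", 1:3), paste0("t", 1:3))))
  calls <- matrix("P", 10, 6, dimnames = dimnames(sig))
  design <- data.frame(sample_id = colnames(sig), age = "P15",
                       treatment = rep(c("PBS", "KA"), each = 3),
                       time_h = 1, replicate = rep(1:3, 2))
  st <- expression_study(sig, calls, design)
  p <- ttest_p(st, paste0("t", 1:3), paste0("c", 1:3))
  oracle <- apply(log2(sig), 1, function(x)
    t.test(x[4:6], x[1:3], var.equal = TRUE)$p.value)
  expect_equal(unname(p), unname(oracle))

  ident <- tiny_study(list(G1 = rep(c(100, 120, 90), 2)))
  expect_equal(unname(ttest_p(ident, tiny_treated(ident), tiny_control(ident))),
               1)
  flat <- tiny_study(list(G1 = c(4, 4, 4, 8, 8, 8)))
  expect_equal(unname(ttest_p(flat, tiny_treated(flat), tiny_control(flat))),
               .Machine$double.xmin)
})

test_that("well-separated groups give p below 0.001", {
  st <- tiny_study(list(G1 = 2^c(1, 1.01, 0.99, 8, 8.1, 7.9)))
  expect_lt(unname(ttest_p(st, tiny_treated(st), tiny_control(st))), 0.001)
})

test_that("null p-values are approximately uniform", {
  g <- generate_study(flat_design(1000), no_effects(), seed = 12)
  norm <- normalize_study(g$study)
  p <- ttest_p(norm, select_samples(norm, treatment = "KA"),
               select_samples(norm, treatment = "PBS"))
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})

test_that("3v3 exhaustive permutation set has exactly choose(6,3) assignments", {
  g <- generate_study(flat_design(60), no_effects(), seed = 2)
  norm <- normalize_study(g$study)
  qv <- qvalue_sam(norm, select_samples(norm, treatment = "KA"),
                   select_samples(norm, treatment = "PBS"))
  expect_equal(attr(qv, "n_permutations"), 20)
  expect_true(all(qv$q >= 0 & qv$q <= 1))
  # requesting more than exist falls back to all of them, identically
  qv2 <- qvalue_sam(norm, select_samples(norm, treatment = "KA"),
                    select_samples(norm, treatment = "PBS"),
                    n_permutations = 500)
  expect_equal(qv2$q, qv$q)
})

test_that("q is monotone non-increasing in |d|", {
  g <- generate_study(flat_design(300),
                      effect_spec(effects = data.frame(
                        gene = sprintf("G%05d", 1:10), age = "P30",
                        time_h = 24, lfc = 2)), seed = 5)
  norm <- normalize_study(g$study)
  qv <- qvalue_sam(norm, select_samples(norm, treatment = "KA"),
                   select_samples(norm, treatment = "PBS"))
  ord <- order(abs(qv$d), decreasing = TRUE)
  expect_true(all(diff(qv$q[ord]) >= 0))
})

test_that("joint selection rule flags genes by the at-least-one-time-point rule", {
  de <- data.frame(
    gene = rep(c("UP6", "NEVER", "DOWN24"), each = 2),
    age = "P30",
    time_h = rep(c(6, 24), 3),
    fc = c(2.5, 1.1, 3.0, 3.0, 1.0, 0.4),
    p = c(0.01, 0.5, 0.2, 0.2, 0.9, 0.01),
    q = c(0.01, 0.9, 0.01, 0.01, 0.9, 0.04),
    stringsAsFactors = FALSE)
  rule <- selection_rule()
  de$direction <- tcx:::de_direction(de$fc, de$p, de$q, rule)
  de$significant <- de$direction != "none"
  sel <- select_significant(de, rule)
  expect_setequal(sel$selected$P30, c("UP6", "DOWN24"))
  expect_equal(de$direction[de$gene == "UP6" & de$time_h == 6], "up")
  expect_equal(de$direction[de$gene == "DOWN24" & de$time_h == 24], "down")
  expect_error(select_significant(de, rule, times = c(1, 6, 24)),
               "missing time point")
})

test_that("loosening any threshold never shrinks the selected set", {
  set.seed(31)
  de <- data.frame(gene = sprintf("G%03d", 1:200), age = "P30",
                   time_h = sample(c(1, 6, 24), 200, TRUE),
                   fc = 2^runif(200, -3, 3),
                   p = runif(200), q = runif(200), stringsAsFactors = FALSE)
  strict <- selection_rule()
  apply_rule <- function(rule) {
    d <- de
    d$direction <- tcx:::de_direction(d$fc, d$p, d$q, rule)
    d$significant <- d$direction != "none"
    select_significant(d, rule)$selected$P30
  }
  base <- apply_rule(strict)
  looser <- list(selection_rule(fc_up = 1.5),
                 selection_rule(fc_down = 0.7),
                 selection_rule(p_max = 0.2),
                 selection_rule(q_max = 0.5),
                 selection_rule(use_q = FALSE))
  for (rule in looser) expect_true(all(base %in% apply_rule(rule)))
})

test_that("set summaries satisfy inclusion-exclusion on random sets", {
  set.seed(77)
  pool <- sprintf("G%03d", 1:80)
  for (i in 1:100) {
    a <- sample(pool, sample(0:40, 1))
    b <- sample(pool, sample(0:40, 1))
    s <- summarize_sets(a, b)
    expect_equal(s$n_union, s$n_a + s$n_b - s$n_shared)
    expect_equal(s$n_a_only + s$n_b_only + s$n_shared, s$n_union)
    # brute-force oracle
    expect_equal(s$n_shared, sum(unique(a) %in% unique(b)))
  }
  empty <- summarize_sets(character(0), character(0))
  expect_equal(empty$n_union, 0)
  expect_equal(empty$pct_shared_of_a, 0)
})

test_that("baseline age contrast recovers injected developmental effects", {
  base_eff <- data.frame(gene = sprintf("G%05d", 1:5), lfc = 3)
  g <- generate_study(design_spec(n_genes = 300, time_points_h = c(1, 6, 24)),
                      effect_spec(effects = data.frame(
                        gene = character(), age = character(),
                        time_h = numeric(), lfc = numeric()),
                        baseline_age_effects = base_eff),
                      seed = 21)
  bl <- baseline_contrast(g$study, seed = 21)
  sel <- select_significant(bl, selection_rule())
  found <- unlist(sel$selected)
  expect_setequal(found, toupper(base_eff$gene))

  g0 <- generate_study(design_spec(n_genes = 300, time_points_h = c(1, 6, 24)),
                       no_effects(), seed = 22)
  bl0 <- baseline_contrast(g0$study, seed = 22)
  expect_equal(sum(bl0$significant), 0)
})

test_that("direction counts tally up/down per age and time", {
  de <- data.frame(gene = c("A", "B", "C", "D"), age = "P15",
                   time_h = c(6, 6, 24, 24),
                   fc = c(3, 0.3, 4, 5), p = 0.01, q = 0.01,
                   direction = c("up", "down", "up", "up"),
                   significant = TRUE, stringsAsFactors = FALSE)
  cnt <- count_directions(de)
  expect_equal(cnt$n_up[cnt$time_h == 24], 2)
  expect_equal(cnt$n_down[cnt$time_h == 6], 1)
})
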