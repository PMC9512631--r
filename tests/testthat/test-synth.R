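test_that("rat factorial design yields |ages| x |treatments| x |times| x reps profiles", {
  g <- generate_study(design_spec(n_genes = 50), effect_spec(n_de = 0), seed = 1)
  expect_equal(ncol(g$study$signals), 60)

  combos <- list(c(1, 2, 3, 2), c(2, 2, 2, 4), c(2, 3, 5, 1))
  for (cb in combos) {
    d <- design_spec(age_groups = paste0("A", seq_len(cb[1])),
                     treatments = paste0("T", seq_len(cb[2])),
                     time_points_h = seq_len(cb[3]),
                     replicates_per_cell = cb[4], n_genes = 20)
    g <- generate_study(d, effect_spec(n_de = 0), seed = 2)
    expect_equal(ncol(g$study$signals), prod(cb))
  }
})

test_that("zero injected effects give an empty ground-truth table", {
  g <- generate_study(design_spec(n_genes = 10), no_effects(), seed = 4)
  expect_equal(nrow(g$truth), 0)
})

test_that("identical seeds reproduce the study exactly; different seeds differ", {
  d <- design_spec(n_genes = 40)
  a <- generate_study(d, effect_spec(n_de = 5), seed = 7)
  b <- generate_study(d, effect_spec(n_de = 5), seed = 7)
  expect_identical(a$study$signals, b$study$signals)
  expect_identical(a$study$calls, b$study$calls)
  expect_identical(a$truth, b$truth)
  c <- generate_study(d, effect_spec(n_de = 5), seed = 8)
  expect_false(identical(a$study$signals, c$study$signals))
})

test_that("invalid design dimensions are rejected", {
  expect_error(design_spec(n_genes = 0), "invalid design")
  expect_error(design_spec(treatments = "PBS"), "invalid design")
  expect_error(design_spec(replicates_per_cell = 0), "invalid design")
  expect_error(design_spec(human_mode = TRUE, human_controls = 0),
               "invalid design")
})

test_that("human mode produces the case/control tissue layout", {
  g <- generate_study(design_spec(n_genes = 30, human_mode = TRUE),
                      effect_spec(effects = data.frame(gene = "G00001",
                                                       lfc = 2)),
                      seed = 1)
  expect_equal(ncol(g$study$signals), 11)
  expect_equal(sum(g$study$design$condition == "MTLE"), 7)
  expect_equal(sum(g$study$design$condition == "control"), 4)
  expect_equal(sum(g$study$design$tissue == "hippocampus"), 3)
})

test_that("detection calls are valid tokens and track signal intensity", {
  g <- generate_study(design_spec(n_genes = 400), no_effects(), seed = 3)
  expect_true(all(g$study$calls %in% c("P", "M", "A")))
  present_frac <- rowMeans(g$study$calls == "P")
  mean_log2 <- rowMeans(log2(g$study$signals))
  expect_gt(cor(mean_log2, present_frac, method = "spearman"), 0.8)
})

test_that("injected effects appear in the treated arm at the right cells", {
  eff <- data.frame(gene = "G00003", age = "P30", time_h = 24, lfc = 2)
  g <- generate_study(design_spec(n_genes = 10),
                      effect_spec(effects = eff, noise_sd = 1e-9), seed = 5)
  st <- g$study
  ka <- select_samples(st, age = "P30", treatment = "KA", time_h = 24)
  pbs <- select_samples(st, age = "P30", treatment = "PBS", time_h = 24)
  expect_equal(mean(log2(st$signals["G00003", ka])) -
                 mean(log2(st$signals["G00003", pbs])), 2, tolerance = 1e-6)
  other <- select_samples(st, age = "P15", treatment = "KA", time_h = 24)
  expect_equal(mean(log2(st$signals["G00003", other])) -
                 mean(log2(st$signals["G00003",
                   select_samples(st, age = "P15", treatment = "PBS",
                                  time_h = 24)])), 0, tolerance = 1e-6)
})

test_that("alias_rate = 0 gives a pure identity alias table", {
  corp <- generate_annotation_corpus(annotation_corpus_spec(alias_rate = 0),
                                     c("AA", "BB"), seed = 1)
  expect_identical(corp$aliases$alias, corp$aliases$canonical)
})

test_that("empty gene list for the corpus generator is an error", {
  expect_error(generate_annotation_corpus(annotation_corpus_spec(),
                                          character(0)), "non-empty")
})

test_that("every membership template maps to exactly its own pathway", {
  lex <- default_pathway_lexicon()
  memb <- tcx:::membership_templates()
  for (pw in names(memb)) {
    for (phrase in memb[[pw]]) {
      expect_identical(tcx:::match_pathways(norm_text(phrase), lex), pw)
    }
  }
  tails <- tcx:::regulation_tails()
  for (pw in names(tails)) {
    expect_identical(tcx:::match_pathways(norm_text(tails[[pw]]), lex), pw)
  }
})

test_that("a positive-JNK-regulator ground truth emits the canonical phrase", {
  found <- FALSE
  for (s in 1:30) {
    corp <- generate_annotation_corpus(annotation_corpus_spec(alias_rate = 0),
                                       sprintf("G%03d", 1:40), seed = s)
    tr <- corp$truth$regulators
    hit <- tr$pathway == "JNK" & tr$polarity == "positive"
    if (!any(hit)) next
    found <- TRUE
    g <- tr$gene[hit][1]
    descs <- unlist(lapply(corp$sources, function(src)
      src$description[toupper(src$symbol) == g]))
    expect_true(any(grepl("positive regulation of JNK cascade", descs)))
    break
  }
  expect_true(found)
})

test_that("zero-noise Ct tables encode injected folds exactly", {
  ct <- generate_ct_table(c("GA", "GB"), c(1, 8), ct_noise_sd = 0, seed = 1)
  res <- ddct_fold(ct)
  expect_equal(res$ddct[res$gene == "GA"], 0)
  expect_equal(res$ddct[res$gene == "GB"], -3)
  expect_equal(res$fold[res$gene == "GB"], 8)
})

test_that("ct generator rejects bad inputs", {
  expect_error(generate_ct_table("GA", 2, housekeeping = character(0)),
               "housekeeping")
  expect_error(generate_ct_table("GA", 0), "> 0")
  expect_error(generate_ct_table("ACTB", 2), "overlap")
})
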