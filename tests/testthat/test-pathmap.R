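test_that("families partition the 13 pathways 3 + 6 + 4", {
  expect_setequal(names(MAPK_FAMILIES), MAPK_PATHWAYS)
  expect_equal(as.vector(table(MAPK_FAMILIES)[c("Classical", "SAPK", "Other")]),
               c(3L, 6L, 4L))
})

test_that("pathway assignment matches quoted-style annotation phrases", {
  comp <- composite_of(list(
    NFKB1 = c("TGF-β signaling pathway", "NF-κB cascade"),
    FOS = c("activated by p38 MAPK signaling",
            "activated by classical MAPK signaling",
            "TGF-beta signaling pathway",
            "nerve growth factor pathway (NGF)",
            "PDGF signaling pathway"),
    NONE = "some unrelated description"))
  asg <- assign_pathways(comp)
  sets <- pathway_sets(asg)
  expect_setequal(sets$NFKB1, c("TGF-beta", "NF-kappaB"))
  expect_setequal(sets$FOS, c("p38", "ERK1/2", "TGF-beta", "Growth Factor"))
  expect_equal(length(sets$FOS), 4)
  expect_null(sets$NONE)
  expect_equal(attr(asg, "unannotated"), "NONE")
  bad_lex <- data.frame(phrase = "x", pathway = "NotAPathway")
  expect_error(assign_pathways(comp, bad_lex), "unknown pathway")
})

test_that("unique-gene criterion keeps only pathways with a single-pathway DE gene", {
  asg <- data.frame(
    gene = c("S1", "M1", "M1", "M2", "M2"),
    pathway = c("JNK", "Wnt", "p53", "Wnt", "p53"))
  expect_equal(unique_gene_criterion(asg, c("S1", "M1", "M2")), "JNK")
  expect_equal(unique_gene_criterion(asg, c("M1", "M2")), character(0))

  corp <- generate_annotation_corpus(annotation_corpus_spec(alias_rate = 0),
                                     sprintf("U%03d", 1:60), seed = 3)
  comp <- build_composite(corp$sources, corp$aliases)
  asg2 <- assign_pathways(comp)
  de <- unique(corp$truth$pathways$gene)
  got <- unique_gene_criterion(asg2, de)
  truth_sets <- split(corp$truth$pathways$pathway, corp$truth$pathways$gene)
  brute <- unique(unlist(truth_sets[lengths(truth_sets) == 1]))
  expect_setequal(got, brute)
})

test_that("single/multiple partition and its percentage are exact", {
  part <- partition_single_multiple(data.frame(
    gene = c("A", "B", "B", "C"), pathway = c("JNK", "JNK", "Wnt", "p53")))
  expect_setequal(part$single, c("A", "C"))
  expect_equal(part$multiple, "B")
  expect_equal(part$n_annotated, 3)
  expect_equal(part$pct_multiple, 100 / 3)

  all_single <- partition_single_multiple(data.frame(
    gene = c("A", "B"), pathway = c("JNK", "Wnt")))
  expect_equal(all_single$pct_multiple, 0)

  set.seed(4)
  genes <- sprintf("R%02d", 1:30)
  asg <- do.call(rbind, lapply(genes, function(g)
    data.frame(gene = g, pathway = sample(MAPK_PATHWAYS, sample(1:5, 1)),
               stringsAsFactors = FALSE)))
  part2 <- partition_single_multiple(asg)
  sizes <- table(unique(asg)$gene)
  expect_setequal(part2$single, names(sizes)[sizes == 1])
  expect_setequal(part2$multiple, names(sizes)[sizes >= 2])
  expect_equal(length(intersect(part2$single, part2$multiple)), 0)
})

test_that("family summary routes single-pathway genes to their family", {
  asg <- data.frame(gene = c("A", "B", "C"),
                    pathway = c("p38", "Wnt", "ERK1/2"))
  fam <- family_summary(c("A", "B", "C"), asg)
  expect_equal(unname(fam), c(1L, 1L, 1L))
  expect_equal(names(fam), c("Classical", "SAPK", "Other"))
  expect_error(family_summary("M", data.frame(gene = c("M", "M"),
                                              pathway = c("p38", "Wnt"))),
               "single-pathway")
})

test_that("array plots increment exactly choose(n,2) cells on the right triangle", {
  mk_asg <- function(n) data.frame(gene = "G", pathway = MAPK_PATHWAYS[seq_len(n)])
  up4 <- array_plot_matrix(mk_asg(4), c(G = "up"))
  expect_equal(sum(up4[upper.tri(up4)]), 6)
  expect_equal(sum(up4[lower.tri(up4)]), 0)
  down2 <- array_plot_matrix(mk_asg(2), c(G = "down"))
  expect_equal(sum(down2[lower.tri(down2)]), 1)
  expect_equal(sum(down2), 1)
  all13 <- array_plot_matrix(mk_asg(13), c(G = "up"))
  expect_equal(sum(all13), 78)
  expect_error(array_plot_matrix(mk_asg(1), c(G = "up")), "fewer than 2")
  expect_true(all(diag(up4) == 0))
})

test_that("array plot totals equal the sum of per-gene pair counts", {
  set.seed(6)
  genes <- sprintf("A%02d", 1:15)
  asg <- do.call(rbind, lapply(genes, function(g)
    data.frame(gene = g, pathway = sample(MAPK_PATHWAYS, sample(2:7, 1)),
               stringsAsFactors = FALSE)))
  dirs <- setNames(sample(c("up", "down"), 15, TRUE), genes)
  mat <- array_plot_matrix(asg, dirs)
  n_per_gene <- table(asg$gene)
  expect_equal(sum(mat), sum(choose(n_per_gene, 2)))
  up_genes <- names(dirs)[dirs == "up"]
  expect_equal(sum(mat[upper.tri(mat)]),
               sum(choose(n_per_gene[up_genes], 2)))
})

test_that("breadth split separates <=4 from >=5 pathway genes", {
  asg <- rbind(data.frame(gene = "N2", pathway = MAPK_PATHWAYS[1:2]),
               data.frame(gene = "N6", pathway = MAPK_PATHWAYS[1:6]))
  sp <- split_by_breadth(asg, c("N2", "N6"))
  expect_equal(sp$le, "N2")
  expect_equal(sp$ge, "N6")
})

test_that("regulator polarity follows the signed-phrase grammar", {
  comp <- composite_of(list(
    IL1B = c("positive regulation of p38 MAPK cascade",
             "positive regulation of JNK cascade"),
    SCG2 = c("negative regulation of JNK cascade",
             "positive regulation of TGF-beta receptor signaling pathway"),
    AMBI = c("positive regulation of Wnt receptor signaling pathway",
             "negative regulation of Wnt receptor signaling pathway"),
    NUP62 = "regulation of Ras protein signal transduction",
    NOPE = "regulation of neurotransmitter secretion"))
  reg <- classify_regulators(comp)
  pol <- function(g, pw) reg$polarity[reg$gene == g & reg$pathway == pw]
  expect_equal(pol("IL1B", "p38"), "positive")
  expect_equal(pol("IL1B", "JNK"), "positive")
  expect_true("IL1B" %in% attr(reg, "multi_pathway"))
  expect_equal(pol("SCG2", "JNK"), "negative")
  expect_equal(pol("SCG2", "TGF-beta"), "positive")
  expect_equal(pol("AMBI", "Wnt"), "general")
  expect_equal(pol("NUP62", "Ras/Rab"), "general")
  expect_false("NOPE" %in% reg$gene)
  expect_equal(attr(reg, "n_unparsed"), 1L)
})

test_that("regulator classification ignores annotation order", {
  d1 <- list(G = c("positive regulation of JNK cascade",
                   "negative regulation of JNK cascade"))
  d2 <- list(G = rev(d1$G))
  r1 <- classify_regulators(composite_of(d1))
  r2 <- classify_regulators(composite_of(d2))
  expect_equal(r1$polarity, r2$polarity)
  expect_equal(r1$polarity, "general")
})

test_that("enzyme flags follow the keyword lexicon with dual => phosphatase", {
  comp <- composite_of(list(
    DUSP1 = c("dual specificity phosphatase", "MAP kinase phosphatase"),
    KIN = "protein kinase activity",
    PLAIN = "axon guidance",
    REGK = "positive regulation of protein kinase activity"))
  enz <- classify_enzymes(comp)
  row <- function(g) enz[enz$gene == g, ]
  expect_true(row("DUSP1")$phosphatase)
  expect_true(row("DUSP1")$dual_specificity)
  expect_true(row("DUSP1")$mapkkk)
  expect_false(row("DUSP1")$kinase)
  expect_true(row("KIN")$kinase)
  expect_false(any(unlist(row("PLAIN")[, c("kinase", "phosphatase",
                                           "dual_specificity", "mapkkk")])))
  expect_equal(row("REGK")$reg_kinase, "positive")
  expect_equal(row("PLAIN")$reg_kinase, "none")
})

test_that("corpus regulator and enzyme truth is recovered exactly", {
  corp <- generate_annotation_corpus(
    annotation_corpus_spec(n_sources = 3, alias_rate = 0.4),
    sprintf("RX%03d", 1:80), seed = 11)
  comp <- build_composite(corp$sources, corp$aliases)
  reg <- classify_regulators(comp)
  truth <- corp$truth$regulators
  key <- function(d) sort(paste(d$gene, d$pathway, d$polarity))
  expect_equal(key(reg), key(truth))
  enz <- classify_enzymes(comp)
  m <- merge(corp$truth$enzymes, enz, by = "gene",
             suffixes = c("_truth", "_got"))
  for (fl in c("kinase", "phosphatase", "dual_specificity", "mapkkk"))
    expect_equal(m[[paste0(fl, "_got")]], m[[paste0(fl, "_truth")]])
})

test_that("pathway table counts all-gene and single-pathway columns per age", {
  asg <- rbind(data.frame(gene = "A", pathway = "JNK"),
               data.frame(gene = "B", pathway = c("JNK", "Wnt")),
               data.frame(gene = "C", pathway = "Wnt"))
  tab <- pathway_table(asg, list(P15 = c("A", "B"), P30 = c("A", "B", "C")))
  expect_equal(tab$P15_all[tab$pathway == "JNK"], 2L)
  expect_equal(tab$P15_single[tab$pathway == "JNK"], 1L)
  expect_equal(tab$P15_all[tab$pathway == "Wnt"], 1L)
  expect_equal(tab$P30_single[tab$pathway == "Wnt"], 1L)
})
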