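# Synthetic-data generation: expression studies, annotation corpora and
# qPCR Ct tables with the statistical structure the analysis assumes.

#' Specify a study design
#'
#' Defaults emulate the rat factorial seizure study: two postnatal ages
#' (P15, P30), vehicle (PBS) vs kainic acid (KA), five post-injection time
#' points (1, 6, 24, 72, 240 h) and three independent hybridizations per
#' condition — 2 x 2 x 5 x 3 = 60 expression profiles. `human_mode` replaces
#' the factorial layout with a case/control tissue design (3 MTLE hippocampi
#' + 4 MTLE neocortices vs 4 control neocortices).
#'
#' @param age_groups,treatments,time_points_h,replicates_per_cell factorial
#'   design factors (rat mode). `treatments[1]` is the control arm.
#' @param n_genes number of genes on the simulated array.
#' @param human_mode logical; use the case/control layout instead.
#' @param human_cases_hippocampus,human_cases_neocortex,human_controls
#'   group sizes in human mode.
#' @return a `tcx_design` list.
#' @export
design_spec <- function(age_groups = c("P15", "P30"),
                        treatments = c("PBS", "KA"),
                        time_points_h = c(1, 6, 24, 72, 240),
                        replicates_per_cell = 3,
                        n_genes = 8799,
                        human_mode = FALSE,
                        human_cases_hippocampus = 3,
                        human_cases_neocortex = 4,
                        human_controls = 4) {
  if (!human_mode) {
    if (length(age_groups) < 1 || length(treatments) < 2 ||
        length(time_points_h) < 1 || replicates_per_cell < 1)
      stop("invalid design dimensions: need >=1 age, >=2 treatments, >=1 time, >=1 replicate")
    if (anyDuplicated(time_points_h)) stop("duplicated time points")
  } else {
    if (human_cases_hippocampus < 1 || human_cases_neocortex < 1 ||
        human_controls < 1)
      stop("invalid design dimensions: all human group sizes must be >= 1")
  }
  if (n_genes < 1) stop("invalid design dimensions: n_genes must be >= 1")
  structure(list(age_groups = age_groups, treatments = treatments,
                 time_points_h = time_points_h,
                 replicates_per_cell = replicates_per_cell,
                 n_genes = n_genes, human_mode = human_mode,
                 human_cases_hippocampus = human_cases_hippocampus,
                 human_cases_neocortex = human_cases_neocortex,
                 human_controls = human_controls),
            class = "tcx_design")
}

#' Specify injected effects and the noise/detection model
#'
#' Signals are log-normal: log2 signal = gene baseline + injected effect +
#' N(0, `noise_sd`). Detection calls are generated by thresholding a
#' logistic function of the log2 signal with added randomness, emulating the
#' intensity-dependence of Present/Marginal/Absent calls without
#' re-implementing the probe-level algorithm (calls are an input contract).
#'
#' @param effects data.frame of injected treatment effects with columns
#'   `gene`, `age`, `time_h`, `lfc` (log2 fold change, KA vs PBS; negative =
#'   downregulation), or `NULL` for none. In human mode the columns are
#'   `gene`, `lfc` (case vs control).
#' @param n_de number of DE genes to auto-generate when `effects` is `NULL`
#'   at [generate_study()] time (0 = all-null study).
#' @param baseline_age_effects optional data.frame `gene`, `lfc` of
#'   developmental baseline differences applied to the second age group in
#'   all samples (PBS and KA alike); exercised by the baseline
#'   age-vs-age contrast.
#' @param baseline_log2_mean,baseline_log2_sd distribution of per-gene
#'   baseline log2 expression.
#' @param noise_sd multiplicative log-normal noise scale (log2 units).
#' @param detect_midpoint,detect_slope logistic detection model: P(Present)
#'   = plogis(slope * (log2 signal - midpoint)).
#' @param marginal_band probability mass given to Marginal calls.
#' @param pooling if `TRUE`, replicate noise is shrunk by sqrt(4) to mimic
#'   RNA pooled from four animals per array; off by default.
#' @return a `tcx_effects` list.
#' @export
effect_spec <- function(effects = NULL, n_de = 150,
                        baseline_age_effects = NULL,
                        baseline_log2_mean = 6, baseline_log2_sd = 1.5,
                        noise_sd = 0.3,
                        detect_midpoint = 4, detect_slope = 1.2,
                        marginal_band = 0.05,
                        pooling = FALSE) {
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (!is.null(effects) && !all(is.finite(effects$lfc)))
    stop("effect magnitudes must be finite")
  structure(list(effects = effects, n_de = n_de,
                 baseline_age_effects = baseline_age_effects,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 noise_sd = noise_sd, detect_midpoint = detect_midpoint,
                 detect_slope = detect_slope, marginal_band = marginal_band,
                 pooling = pooling),
            class = "tcx_effects")
}

gene_names <- function(n) toupper(sprintf("G%05d", seq_len(n)))

# Auto-generate a truth table of injected effects. The second age group
# (P30-like) receives larger magnitudes over longer durations than the
# first (P15-like), mirroring the qualitative age asymmetry of the seizure
# response; exact values are configuration, not claims.
make_default_effects <- function(design, n_de) {
  genes <- gene_names(design$n_genes)
  de_genes <- sample(genes, min(n_de, design$n_genes))
  ages <- design$age_groups
  times <- sort(design$time_points_h)
  rows <- list()
  for (g in de_genes) {
    scope <- sample(c("first", "second", "both"), 1, prob = c(0.2, 0.5, 0.3))
    dir_sign <- if (stats::runif(1) < 0.75) 1 else -1
    add_age <- function(age, mature) {
      max_dur <- if (mature) length(times) else min(3, length(times))
      dur <- sample(seq_len(max_dur), 1)
      start <- sample(seq_len(max(1, length(times) - dur + 1)), 1)
      mag <- if (mature) stats::runif(1, 1.5, 5) else stats::runif(1, 1.2, 3)
      data.frame(gene = g, age = age, time_h = times[start:(start + dur - 1)],
                 lfc = dir_sign * mag, stringsAsFactors = FALSE)
    }
    if (scope %in% c("first", "both") && length(ages) >= 1)
      rows[[length(rows) + 1L]] <- add_age(ages[1], mature = FALSE)
    if (scope %in% c("second", "both") && length(ages) >= 2)
      rows[[length(rows) + 1L]] <- add_age(ages[2], mature = TRUE)
  }
  if (length(rows) == 0)
    return(data.frame(gene = character(), age = character(),
                      time_h = numeric(), lfc = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Generate a synthetic expression study
#'
#' Draws per-gene baselines, injects the treatment effects of `effects` into
#' the KA arm (case arm in human mode), adds log-normal replicate noise and
#' produces intensity-dependent detection calls. Identical seeds give
#' byte-identical output.
#'
#' @param design a [design_spec()].
#' @param effects an [effect_spec()].
#' @param seed integer seed; all randomness derives from it.
#' @return list with elements `study` (a `tcx_study`) and `truth`
#'   (data.frame of injected effects: `gene`, `age`, `time_h`, `lfc`,
#'   `direction`; empty when nothing was injected).
#' @export
generate_study <- function(design = design_spec(), effects = effect_spec(),
                           seed = 1) {
  stopifnot(inherits(design, "tcx_design"), inherits(effects, "tcx_effects"))
  with_seed(derive_seed(seed, "study"), {
    genes <- gene_names(design$n_genes)
    baseline <- stats::rnorm(design$n_genes, effects$baseline_log2_mean,
                             effects$baseline_log2_sd)
    names(baseline) <- genes

    truth <- effects$effects
    if (is.null(truth)) truth <- make_default_effects(design, effects$n_de)

    if (design$human_mode) {
      design_df <- data.frame(
        sample_id = c(sprintf("MTLE_HC_%d", seq_len(design$human_cases_hippocampus)),
                      sprintf("MTLE_NC_%d", seq_len(design$human_cases_neocortex)),
                      sprintf("CTRL_NC_%d", seq_len(design$human_controls))),
        tissue = c(rep("hippocampus", design$human_cases_hippocampus),
                   rep("neocortex", design$human_cases_neocortex),
                   rep("neocortex", design$human_controls)),
        condition = c(rep("MTLE", design$human_cases_hippocampus +
                            design$human_cases_neocortex),
                      rep("control", design$human_controls)),
        stringsAsFactors = FALSE)
      eff_of <- function(s) {
        e <- numeric(design$n_genes); names(e) <- genes
        if (design_df$condition[design_df$sample_id == s] == "MTLE" &&
            nrow(truth) > 0) {
          tg <- toupper(truth$gene)
          e[tg] <- truth$lfc
        }
        e
      }
      mode <- "human"
    } else {
      grid <- expand.grid(replicate = seq_len(design$replicates_per_cell),
                          time_h = design$time_points_h,
                          treatment = design$treatments,
                          age = design$age_groups,
                          stringsAsFactors = FALSE)
      design_df <- data.frame(
        sample_id = sprintf("%s_%s_%gh_r%d", grid$age, grid$treatment,
                            grid$time_h, grid$replicate),
        age = grid$age, treatment = grid$treatment, time_h = grid$time_h,
        replicate = grid$replicate, stringsAsFactors = FALSE)
      treated_arm <- design$treatments[2]
      base_age <- effects$baseline_age_effects
      eff_of <- function(s) {
        row <- design_df[design_df$sample_id == s, ]
        e <- numeric(design$n_genes); names(e) <- genes
        if (!is.null(base_age) && length(design$age_groups) >= 2 &&
            row$age == design$age_groups[2]) {
          e[toupper(base_age$gene)] <- e[toupper(base_age$gene)] + base_age$lfc
        }
        if (row$treatment == treated_arm && nrow(truth) > 0) {
          hit <- truth$age == row$age & truth$time_h == row$time_h
          if (any(hit))
            e[toupper(truth$gene[hit])] <- e[toupper(truth$gene[hit])] + truth$lfc[hit]
        }
        e
      }
      mode <- "rat"
    }

    n_s <- nrow(design_df)
    sd_rep <- effects$noise_sd / if (isTRUE(effects$pooling)) 2 else 1
    log2sig <- matrix(0, design$n_genes, n_s,
                      dimnames = list(genes, design_df$sample_id))
    for (s in design_df$sample_id) {
      log2sig[, s] <- baseline + eff_of(s) +
        stats::rnorm(design$n_genes, 0, sd_rep)
    }
    signals <- 2^log2sig

    p_present <- stats::plogis(effects$detect_slope *
                                 (log2sig - effects$detect_midpoint))
    u <- matrix(stats::runif(length(p_present)), nrow = nrow(p_present))
    calls <- matrix("A", nrow(p_present), ncol(p_present),
                    dimnames = dimnames(log2sig))
    calls[u < p_present] <- "P"
    calls[u >= p_present & u < p_present + effects$marginal_band] <- "M"

    study <- expression_study(signals, calls, design_df, mode = mode)
    if (nrow(truth) > 0) {
      truth$gene <- toupper(truth$gene)
      truth$direction <- ifelse(truth$lfc > 0, "up", "down")
    } else {
      truth <- data.frame(gene = character(), age = character(),
                          time_h = numeric(), lfc = numeric(),
                          direction = character(), stringsAsFactors = FALSE)
    }
    list(study = study, truth = truth)
  })
}

# ---------------------------------------------------------------------------
# Annotation corpus generation

# Membership phrase templates, one or more per pathway; every template maps
# to exactly its pathway under the default lexicon (checked in tests).
membership_templates <- function() {
  list(
    "ERK1/2" = c("activated by classical MAPK signaling", "ERK cascade"),
    "Growth Factor" = c("nerve growth factor pathway (NGF)",
                        "PDGF signaling pathway",
                        "growth factor signaling"),
    "Ras/Rab" = c("Ras protein signal transduction",
                  "Rab protein signal transduction"),
    "p38" = c("activated by p38 MAPK signaling", "p38 MAPK cascade"),
    "Rho/Cdc42/Rac" = c("Rho protein signal transduction",
                        "Cdc42 protein signal transduction",
                        "Rac protein signal transduction"),
    "JNK" = c("JNK cascade"),
    "p53" = c("p53 signaling pathway"),
    "TGF-beta" = c("TGF-beta signaling pathway",
                   "TGF-beta receptor signaling pathway"),
    "TNF-alpha" = c("TNF-alpha signaling", "tumor necrosis factor mediated signaling"),
    "NF-kappaB" = c("NF-kappaB cascade", "I-kappaB kinase/NF-kappaB cascade"),
    "Wnt" = c("Wnt receptor signaling pathway"),
    "JAK/STAT" = c("JAK-STAT cascade"),
    "PI3K/AKT" = c("phosphoinositide 3-kinase cascade", "AKT signaling pathway"))
}

# Regulation-object templates: tails that map to exactly one pathway.
regulation_tails <- function() {
  c("ERK1/2" = "ERK cascade",
    "Growth Factor" = "epidermal growth factor receptor signaling pathway",
    "Ras/Rab" = "Ras protein signal transduction",
    "p38" = "p38 MAPK cascade",
    "Rho/Cdc42/Rac" = "Rho protein signal transduction",
    "JNK" = "JNK cascade",
    "p53" = "p53 signaling pathway",
    "TGF-beta" = "TGF-beta receptor signaling pathway",
    "TNF-alpha" = "TNF-alpha signaling",
    "NF-kappaB" = "I-kappaB kinase/NF-kappaB cascade",
    "Wnt" = "Wnt receptor signaling pathway",
    "JAK/STAT" = "JAK-STAT cascade",
    "PI3K/AKT" = "AKT signaling pathway")
}

filler_vocabulary <- function() {
  c("inflammatory response", "immune response", "apoptosis",
    "cell cycle arrest", "cell proliferation", "transcription factor activity",
    "regulation of transcription", "synaptic transmission",
    "calcium ion binding", "calcium signaling", "mitochondrial membrane",
    "glial cell differentiation", "axon guidance", "chemokine activity",
    "cytokine activity", "heat shock protein binding", "oxidative stress response")
}

#' Specify a synthetic annotation corpus
#'
#' @param n_sources number of simulated annotation databases (>= 1).
#' @param alias_rate expected number of aliases per gene (Poisson mean; 0
#'   disables aliasing so the alias table maps each symbol to itself only).
#' @param p_pathway probability a gene carries >= 1 pathway annotation.
#' @param p_regulator probability an annotated gene also carries a
#'   pathway-regulation phrase.
#' @param p_enzyme probability a gene carries kinase/phosphatase phrases.
#' @param max_pathways largest pathway-set size generated.
#' @return a `tcx_corpus_spec` list.
#' @export
annotation_corpus_spec <- function(n_sources = 3, alias_rate = 0.3,
                                   p_pathway = 0.8, p_regulator = 0.3,
                                   p_enzyme = 0.25, max_pathways = 7) {
  if (n_sources < 1) stop("need at least one annotation source")
  if (alias_rate < 0) stop("alias_rate must be >= 0")
  structure(list(n_sources = n_sources, alias_rate = alias_rate,
                 p_pathway = p_pathway, p_regulator = p_regulator,
                 p_enzyme = p_enzyme, max_pathways = max_pathways),
            class = "tcx_corpus_spec")
}

#' Generate a multi-source annotation corpus with ground truth
#'
#' Emits `n_sources` symbol/description tables plus an alias table, together
#' with the ground-truth pathway sets, regulator polarities and enzyme flags
#' encoded in the description strings. Every description is assigned to at
#' least one source (so the union over sources is complete), genes may
#' appear under an alias in some sources, and the emitted strings parse back
#' to the ground truth via the composite-database and pathway-mapping
#' machinery — the round trip is exact by construction.
#'
#' @param spec an [annotation_corpus_spec()].
#' @param genes non-empty character vector of canonical symbols.
#' @param seed integer seed.
#' @return list with `sources` (list of data.frames `symbol`, `description`),
#'   `aliases` (data.frame `alias`, `canonical`; includes identity rows),
#'   and `truth` (list: `pathways` long data.frame, `regulators` long
#'   data.frame with polarity, `enzymes` flag data.frame, `unannotated`
#'   character vector).
#' @export
generate_annotation_corpus <- function(spec = annotation_corpus_spec(),
                                       genes, seed = 1) {
  stopifnot(inherits(spec, "tcx_corpus_spec"))
  if (length(genes) == 0) stop("gene list must be non-empty")
  genes <- toupper(genes)
  with_seed(derive_seed(seed, "corpus"), {
    memb <- membership_templates()
    tails <- regulation_tails()
    fill <- filler_vocabulary()

    truth_pw <- list(); truth_reg <- list(); truth_enz <- list()
    descs <- list()  # gene -> character vector
    unannotated <- character(0)

    for (g in genes) {
      ds <- sample(fill, sample(1:3, 1))
      if (stats::runif(1) < spec$p_pathway) {
        n_pw <- sample(seq_len(spec$max_pathways), 1,
                       prob = (0.55 * 0.55^(seq_len(spec$max_pathways) - 1)))
        pws <- sample(MAPK_PATHWAYS, n_pw)
        for (pw in pws) {
          ds <- c(ds, sample(memb[[pw]], 1))
          truth_pw[[length(truth_pw) + 1L]] <-
            data.frame(gene = g, pathway = pw, stringsAsFactors = FALSE)
        }
        if (stats::runif(1) < spec$p_regulator) {
          reg_pws <- sample(pws, min(length(pws), sample(1:2, 1)))
          for (pw in reg_pws) {
            pol <- sample(c("positive", "negative", "general"), 1,
                          prob = c(0.45, 0.25, 0.3))
            if (pol == "general" && stats::runif(1) < 0.5) {
              # both signed phrases for the same pathway collapse to general
              ds <- c(ds, paste("positive regulation of", tails[[pw]]),
                      paste("negative regulation of", tails[[pw]]))
            } else if (pol == "general") {
              ds <- c(ds, paste("regulation of", tails[[pw]]))
            } else {
              ds <- c(ds, paste(pol, "regulation of", tails[[pw]]))
            }
            truth_reg[[length(truth_reg) + 1L]] <-
              data.frame(gene = g, pathway = pw, polarity = pol,
                         stringsAsFactors = FALSE)
          }
        }
      } else {
        unannotated <- c(unannotated, g)
      }
      kin <- phos <- dual <- mkkk <- FALSE
      if (stats::runif(1) < spec$p_enzyme) {
        if (stats::runif(1) < 0.5) {
          kin <- TRUE
          ds <- c(ds, "protein kinase activity")
          if (stats::runif(1) < 0.3) {
            mkkk <- TRUE
            ds <- c(ds, "MAP kinase kinase kinase cascade")
          }
        } else {
          phos <- TRUE
          if (stats::runif(1) < 0.4) {
            dual <- TRUE; mkkk <- TRUE
            ds <- c(ds, "dual specificity phosphatase", "MAP kinase phosphatase")
          } else {
            ds <- c(ds, "protein phosphatase activity")
          }
        }
      }
      truth_enz[[length(truth_enz) + 1L]] <-
        data.frame(gene = g, kinase = kin, phosphatase = phos,
                   dual_specificity = dual, mapkkk = mkkk,
                   stringsAsFactors = FALSE)
      descs[[g]] <- unique(ds)
    }

    # alias table: identity rows plus Poisson-many synthetic aliases per gene
    extra_alias <- if (spec$alias_rate > 0)
      stats::rpois(length(genes), spec$alias_rate) else rep(0L, length(genes))
    alias_rows <- data.frame(alias = genes, canonical = genes,
                             stringsAsFactors = FALSE)
    alias_map <- list()  # gene -> non-canonical aliases
    for (i in seq_along(genes)) {
      if (extra_alias[i] > 0) {
        al <- sprintf("%s-ALT%d", genes[i], seq_len(extra_alias[i]))
        alias_map[[genes[i]]] <- al
        alias_rows <- rbind(alias_rows,
                            data.frame(alias = al, canonical = genes[i],
                                       stringsAsFactors = FALSE))
      }
    }

    # distribute each description to >= 1 source; pick a symbol per source
    sources <- replicate(spec$n_sources,
                         list(symbol = character(0), description = character(0)),
                         simplify = FALSE)
    for (g in genes) {
      als <- c(g, alias_map[[g]])
      for (d in descs[[g]]) {
        srcs <- which(stats::runif(spec$n_sources) < 0.6)
        if (length(srcs) == 0) srcs <- sample(spec$n_sources, 1)
        for (k in srcs) {
          sym <- sample(als, 1)
          sources[[k]]$symbol <- c(sources[[k]]$symbol, sym)
          sources[[k]]$description <- c(sources[[k]]$description, d)
        }
      }
    }
    sources <- lapply(sources, function(s)
      data.frame(symbol = s$symbol, description = s$description,
                 stringsAsFactors = FALSE))

    bind_or_empty <- function(lst, cols) {
      if (length(lst) > 0) {
        df <- do.call(rbind, lst); rownames(df) <- NULL; df
      } else {
        as.data.frame(stats::setNames(rep(list(character(0)), length(cols)),
                                      cols), stringsAsFactors = FALSE)
      }
    }
    list(sources = sources,
         aliases = alias_rows,
         truth = list(
           pathways = bind_or_empty(truth_pw, c("gene", "pathway")),
           regulators = bind_or_empty(truth_reg, c("gene", "pathway", "polarity")),
           enzymes = do.call(rbind, truth_enz),
           unannotated = unannotated))
  })
}

#' Generate a synthetic qPCR Ct table
#'
#' Housekeeping genes get a common per-sample Ct; each target gene gets a
#' baseline Ct in controls and baseline − log2(fold) in the treated group,
#' plus Gaussian cycle noise, so the expected 2^(−ΔΔCt) equals the injected
#' fold change.
#'
#' @param genes character vector of target genes.
#' @param true_folds numeric vector of injected fold changes (recycled to
#'   `length(genes)`); must be > 0.
#' @param n_control,n_treated samples per group.
#' @param housekeeping names of housekeeping genes (>= 1).
#' @param ct_noise_sd Gaussian Ct noise (cycles); 0 gives exact arithmetic.
#' @param seed integer seed.
#' @return long data.frame `sample`, `gene`, `ct`, `is_housekeeping`,
#'   `group` (a `CtTable` in the pipeline's vocabulary).
#' @export
generate_ct_table <- function(genes, true_folds, n_control = 3, n_treated = 3,
                              housekeeping = c("ACTB", "GAPDH"),
                              ct_noise_sd = 0.2, seed = 1) {
  if (length(housekeeping) < 1) stop("at least one housekeeping gene required")
  if (any(true_folds <= 0)) stop("true folds must be > 0")
  genes <- toupper(genes)
  housekeeping <- toupper(housekeeping)
  if (any(genes %in% housekeeping))
    stop("target genes overlap housekeeping genes")
  true_folds <- rep_len(true_folds, length(genes))
  with_seed(derive_seed(seed, "ct"), {
    samples <- c(sprintf("ctrl_%d", seq_len(n_control)),
                 sprintf("trt_%d", seq_len(n_treated)))
    group <- c(rep("control", n_control), rep("treated", n_treated))
    base_hk <- stats::runif(length(housekeeping), 18, 20)
    base_gene <- stats::runif(length(genes), 22, 30)
    rows <- list()
    for (si in seq_along(samples)) {
      for (hi in seq_along(housekeeping)) {
        rows[[length(rows) + 1L]] <- data.frame(
          sample = samples[si], gene = housekeeping[hi],
          ct = base_hk[hi] + stats::rnorm(1, 0, ct_noise_sd),
          is_housekeeping = TRUE, group = group[si],
          stringsAsFactors = FALSE)
      }
      for (gi in seq_along(genes)) {
        shift <- if (group[si] == "treated") -log2(true_folds[gi]) else 0
        rows[[length(rows) + 1L]] <- data.frame(
          sample = samples[si], gene = genes[gi],
          ct = base_gene[gi] + shift + stats::rnorm(1, 0, ct_noise_sd),
          is_housekeeping = FALSE, group = group[si],
          stringsAsFactors = FALSE)
      }
    }
    ct <- do.call(rbind, rows)
    rownames(ct) <- NULL
    ct
  })
}
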