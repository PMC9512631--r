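# Ingest: the in-memory study container and its tab-delimited serialization.

VALID_CALLS <- c("P", "M", "A")

#' Construct a validated expression study
#'
#' Bundles a positive signal matrix (genes x samples), a matching matrix of
#' MAS5-style detection calls (Present/Marginal/Absent) and a sample design
#' table into a single object shared by all analysis stages. Gene identity is
#' the canonical symbol, matched case-insensitively and stored upper-case.
#'
#' @param signals numeric matrix, genes x samples, strictly positive, with
#'   gene symbols as rownames and sample IDs as colnames.
#' @param calls character matrix of the same shape with values "P", "M", "A".
#' @param design data.frame with one row per sample. Rat (factorial) mode
#'   requires columns `sample_id`, `age`, `treatment`, `time_h`, `replicate`;
#'   human (case-control) mode requires `sample_id`, `tissue`, `condition`.
#' @param mode `"rat"` for the factorial seizure design, `"human"` for the
#'   case-control surgical-tissue design.
#' @return an object of class `tcx_study`.
#' @export
expression_study <- function(signals, calls, design, mode = c("rat", "human")) {
  mode <- match.arg(mode)
  if (!is.matrix(signals) || !is.numeric(signals))
    stop("`signals` must be a numeric matrix")
  if (is.null(rownames(signals)) || is.null(colnames(signals)))
    stop("`signals` needs gene rownames and sample colnames")
  rownames(signals) <- toupper(rownames(signals))
  if (anyDuplicated(rownames(signals)))
    stop("duplicated gene IDs: ",
         paste(unique(rownames(signals)[duplicated(rownames(signals))]),
               collapse = ", "))
  if (any(!is.finite(signals)) || any(signals <= 0))
    stop("signals must be finite and strictly positive")

  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  rownames(calls) <- toupper(rownames(calls))
  if (!identical(dim(calls), dim(signals)))
    stop("`calls` and `signals` differ in shape")
  bad <- which(matrix(!(calls %in% VALID_CALLS), nrow(calls)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("unknown detection call '%s' at gene %s, sample %s",
                 calls[bad[1, 1], bad[1, 2]],
                 rownames(calls)[bad[1, 1]], colnames(calls)[bad[1, 2]]))
  }
  if (!identical(rownames(calls), rownames(signals)) ||
      !identical(colnames(calls), colnames(signals)))
    stop("`calls` and `signals` dimnames disagree")

  design <- as.data.frame(design, stringsAsFactors = FALSE)
  req <- if (mode == "rat") {
    c("sample_id", "age", "treatment", "time_h", "replicate")
  } else {
    c("sample_id", "tissue", "condition")
  }
  miss <- setdiff(req, names(design))
  if (length(miss) > 0)
    stop("design table lacks columns: ", paste(miss, collapse = ", "))
  extra <- setdiff(design$sample_id, colnames(signals))
  absent <- setdiff(colnames(signals), design$sample_id)
  if (length(extra) > 0 || length(absent) > 0)
    stop("sample-ID mismatch between design and matrix; ",
         "design-only: [", paste(extra, collapse = ", "), "] ",
         "matrix-only: [", paste(absent, collapse = ", "), "]")
  design <- design[match(colnames(signals), design$sample_id), , drop = FALSE]
  rownames(design) <- NULL

  structure(list(signals = signals, calls = calls, design = design,
                 mode = mode),
            class = "tcx_study")
}

#' @export
print.tcx_study <- function(x, ...) {
  cat(sprintf("tcx_study (%s mode): %d genes x %d samples\n",
              x$mode, nrow(x$signals), ncol(x$signals)))
  if (x$mode == "rat") {
    cat("  ages:      ", paste(unique(x$design$age), collapse = ", "), "\n")
    cat("  treatments:", paste(unique(x$design$treatment), collapse = ", "), "\n")
    cat("  times (h): ", paste(sort(unique(x$design$time_h)), collapse = ", "), "\n")
  } else {
    cat("  tissues:   ", paste(unique(x$design$tissue), collapse = ", "), "\n")
    cat("  conditions:", paste(unique(x$design$condition), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Select sample IDs by design fields
#'
#' @param study a `tcx_study`.
#' @param age,treatment,time_h,tissue,condition optional filters; `NULL`
#'   means no constraint on that field.
#' @return character vector of matching sample IDs.
#' @export
select_samples <- function(study, age = NULL, treatment = NULL, time_h = NULL,
                           tissue = NULL, condition = NULL) {
  d <- study$design
  keep <- rep(TRUE, nrow(d))
  if (!is.null(age)) keep <- keep & d$age %in% age
  if (!is.null(treatment)) keep <- keep & d$treatment %in% treatment
  if (!is.null(time_h)) keep <- keep & d$time_h %in% time_h
  if (!is.null(tissue)) keep <- keep & d$tissue %in% tissue
  if (!is.null(condition)) keep <- keep & d$condition %in% condition
  d$sample_id[keep]
}

#' Write a study to a directory of tab-delimited files
#'
#' Emits `signals.tsv` (gene column + one column per sample), `calls.tsv`
#' (same shape, P/M/A tokens) and `design.tsv`. Numeric values are written
#' with 17 significant digits so a read-back reproduces the study exactly.
#'
#' @param study a `tcx_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig <- data.frame(gene = rownames(study$signals), study$signals,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(sig, file.path(dir, "signals.tsv"))
  cal <- data.frame(gene = rownames(study$calls), study$calls,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(cal, file.path(dir, "calls.tsv"))
  write_tsv(study$design, file.path(dir, "design.tsv"))
  invisible(dir)
}

#' Load a study from tab-delimited files
#'
#' Counterpart of [write_study()]. In strict mode (default) any malformed row
#' aborts with an error naming the offending gene/sample; in lenient mode
#' malformed rows (non-positive signal or unknown call token) are dropped
#' with a warning.
#'
#' @param dir directory containing `signals.tsv`, `calls.tsv`, `design.tsv`.
#' @param mode `"rat"` or `"human"`.
#' @param strict abort on malformed rows (default) instead of dropping them.
#' @return a validated `tcx_study`.
#' @export
read_study <- function(dir, mode = c("rat", "human"), strict = TRUE) {
  mode <- match.arg(mode)
  paths <- file.path(dir, c("signals.tsv", "calls.tsv", "design.tsv"))
  miss <- paths[!file.exists(paths)]
  if (length(miss) > 0) stop("missing study files: ", paste(miss, collapse = ", "))
  sig <- read_tsv(paths[1])
  cal <- read_tsv(paths[2])
  design <- read_tsv(paths[3])
  if ("time_h" %in% names(design)) design$time_h <- as.double(design$time_h)
  if ("replicate" %in% names(design)) design$replicate <- as.integer(design$replicate)

  sig_m <- as.matrix(sig[, -1, drop = FALSE])
  storage.mode(sig_m) <- "double"
  rownames(sig_m) <- toupper(sig$gene)
  cal_m <- as.matrix(cal[, -1, drop = FALSE])
  rownames(cal_m) <- toupper(cal$gene)

  if (!identical(rownames(cal_m), rownames(sig_m)))
    stop("gene IDs differ between signals.tsv and calls.tsv")
  if (!identical(colnames(cal_m), colnames(sig_m)))
    stop("sample-ID mismatch between signals.tsv and calls.tsv; ",
         "signals-only: [", paste(setdiff(colnames(sig_m), colnames(cal_m)), collapse = ", "),
         "] calls-only: [", paste(setdiff(colnames(cal_m), colnames(sig_m)), collapse = ", "), "]")

  bad_sig <- !apply(is.finite(sig_m) & sig_m > 0, 1, all)
  bad_cal <- !apply(matrix(cal_m %in% VALID_CALLS, nrow = nrow(cal_m)), 1, all)
  bad <- bad_sig | bad_cal
  if (any(bad)) {
    if (strict) {
      i <- which(bad)[1]
      if (bad_cal[i]) {
        j <- which(!(cal_m[i, ] %in% VALID_CALLS))[1]
        stop(sprintf("unknown detection call '%s' at gene %s, sample %s",
                     cal_m[i, j], rownames(cal_m)[i], colnames(cal_m)[j]))
      }
      j <- which(!(is.finite(sig_m[i, ]) & sig_m[i, ] > 0))[1]
      stop(sprintf("non-positive signal at gene %s, sample %s",
                   rownames(sig_m)[i], colnames(sig_m)[j]))
    }
    warning(sprintf("dropping %d malformed gene row(s): %s", sum(bad),
                    paste(utils::head(rownames(sig_m)[bad], 5), collapse = ", ")))
    sig_m <- sig_m[!bad, , drop = FALSE]
    cal_m <- cal_m[!bad, , drop = FALSE]
  }

  study <- expression_study(sig_m, cal_m, design, mode = mode)
  tcx_log(sprintf("loaded study: %d genes, %d samples (%s mode)",
                  nrow(study$signals), ncol(study$signals), mode))
  study
}
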