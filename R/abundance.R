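#' Per-sample cell-type composition table
#'
#' Computes per-sample category proportions against a declared denominator:
#' `"all"` divides by the sample's total cells; `"parent"` divides each
#' category by its parent-lineage cell count in that sample (for granular
#' subsets relative to their parent group). Zero-count categories are 0;
#' a parent with 0 cells in a sample yields a missing entry, not 0.
#'
#' @param categories per-cell category labels (major type, granular subset, or
#'   tumor state).
#' @param sample_meta data.frame with per-cell `sample`, `patient`,
#'   `timepoint` columns (timepoints must be "pre" or "on").
#' @param denominator `"all"` or `"parent"`.
#' @param parents per-cell parent-lineage labels; required when
#'   `denominator = "parent"`.
#' @return a `CompositionTable` data.frame: sample, patient, timepoint, then
#'   one proportion column per category.
#' @export
composition_table <- function(categories, sample_meta,
                              denominator = c("all", "parent"),
                              parents = NULL) {
  denominator <- match.arg(denominator)
  if (!all(sample_meta$timepoint %in% c("pre", "on"))) {
    stop("configuration error: unknown timepoint label(s): ",
         paste(setdiff(unique(sample_meta$timepoint), c("pre", "on")), collapse = ", "))
  }
  if (denominator == "parent" && is.null(parents)) {
    stop("denominator = 'parent' requires per-cell parent labels")
  }
  categories <- as.character(categories)
  samples <- unique(sample_meta[, c("sample", "patient", "timepoint")])
  samples <- samples[order(samples$sample), ]
  cats <- sort(unique(categories))
  props <- matrix(NA_real_, nrow(samples), length(cats),
                  dimnames = list(samples$sample, cats))
  for (i in seq_len(nrow(samples))) {
    in_s <- sample_meta$sample == samples$sample[i]
    for (j in seq_along(cats)) {
      in_cat <- in_s & categories == cats[j]
      denom <- if (denominator == "all") sum(in_s) else {
        parent_of_cat <- unique(parents[categories == cats[j]])
        sum(in_s & parents %in% parent_of_cat)
      }
      props[i, j] <- if (denom > 0) sum(in_cat) / denom else NA_real_
    }
  }
  out <- cbind(samples, as.data.frame(props, check.names = FALSE))
  rownames(out) <- NULL
  class(out) <- c("CompositionTable", "data.frame")
  attr(out, "categories") <- cats
  attr(out, "denominator") <- denominator
  out
}

#' Pre- versus on-treatment comparison of compositions
#'
#' Per category: a two-sample Student t-test over all samples
#' (`mode = "all-samples"`) or a paired t-test over patients with both
#' timepoints (`mode = "paired-only"`), two-sided, with Bonferroni correction
#' over the categories tested in this invocation
#' (`p_adjusted = min(1, p * n_categories)`). Categories with insufficient
#' samples (or zero variance of the differences) are skipped with a warning.
#'
#' @param table a [composition_table()].
#' @param mode `"all-samples"` or `"paired-only"`.
#' @return a `ComparisonResult` data.frame: category, mean_pre, mean_on,
#'   t_statistic, p_raw, p_adjusted, n_pre, n_on, mode.
#' @export
paired_comparison <- function(table, mode = c("all-samples", "paired-only")) {
  mode <- match.arg(mode)
  cats <- attr(table, "categories")
  if (is.null(cats)) cats <- setdiff(names(table), c("sample", "patient", "timepoint"))
  rows <- lapply(cats, function(cat) {
    pre <- table[table$timepoint == "pre", c("patient", cat)]
    on <- table[table$timepoint == "on", c("patient", cat)]
    if (mode == "paired-only") {
      common <- intersect(pre$patient[!is.na(pre[[cat]])],
                          on$patient[!is.na(on[[cat]])])
      x <- pre[[cat]][match(common, pre$patient)]
      y <- on[[cat]][match(common, on$patient)]
      if (length(common) < 2) {
        warning("category ", cat, ": fewer than 2 complete pairs; skipped")
        return(NULL)
      }
      if (stats::sd(x - y) == 0) {
        if (all(x == y)) {
          tt <- list(statistic = 0, p.value = 1)
        } else {
          warning("category ", cat, ": constant nonzero paired difference; skipped")
          return(NULL)
        }
      } else {
        tt <- stats::t.test(x, y, paired = TRUE)
      }
      n_pre <- n_on <- length(common)
    } else {
      x <- pre[[cat]][!is.na(pre[[cat]])]
      y <- on[[cat]][!is.na(on[[cat]])]
      if (length(x) < 2 || length(y) < 2) {
        warning("category ", cat, ": fewer than 2 samples in a group; skipped")
        return(NULL)
      }
      if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        tt <- if (mean(x) == mean(y)) list(statistic = 0, p.value = 1) else {
          warning("category ", cat, ": zero variance in both groups; skipped")
          return(NULL)
        }
      } else {
        tt <- stats::t.test(x, y, var.equal = TRUE)
      }
      n_pre <- length(x); n_on <- length(y)
    }
    data.frame(category = cat,
               mean_pre = mean(x), mean_on = mean(y),
               t_statistic = unname(tt$statistic), p_raw = tt$p.value,
               n_pre = n_pre, n_on = n_on, mode = mode,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no category had enough samples to test")
  out$p_adjusted <- pmin(1, out$p_raw * length(cats))
  class(out) <- c("ComparisonResult", "data.frame")
  out
}

#' Pre/on comparison of the positive-cell fraction for one gene
#'
#' Computes, per sample, the fraction of malignant cells positive for `gene`
#' under `positivity_rule` (default: raw count > 0), then compares pre versus
#' on timepoints through [paired_comparison()].
#'
#' @param counts a `CountMatrix` (raw counts; positivity is evaluated on it).
#' @param malignant named or aligned logical vector of malignant calls.
#' @param gene gene symbol.
#' @param positivity_rule function mapping a count vector to a logical vector
#'   (default `function(x) x > 0`).
#' @param mode passed to [paired_comparison()] (default `"paired-only"`).
#' @return a `ComparisonResult` with one row for the positive fraction, with
#'   the per-sample fractions attached as `attr(out, "fractions")`; when no
#'   sample has a positive cell (t undefined) the result carries `NA`
#'   statistics.
#' @export
positive_fraction_test <- function(counts, malignant, gene,
                                   positivity_rule = function(x) x > 0,
                                   mode = "paired-only") {
  stopifnot(inherits(counts, "CountMatrix"))
  if (!gene %in% colnames(counts$counts)) {
    near <- utils::head(agrep(gene, colnames(counts$counts), value = TRUE,
                              max.distance = 0.2), 5)
    stop("gene ", gene, " not measured",
         if (length(near)) paste0("; nearest symbols: ", paste(near, collapse = ", ")))
  }
  positive <- positivity_rule(as.numeric(counts$counts[, gene]))
  meta <- counts$cell_meta
  mal <- as.logical(malignant)
  samples <- unique(meta[, c("sample", "patient", "timepoint")])
  frac <- vapply(samples$sample, function(s) {
    sel <- meta$sample == s & mal
    if (!sum(sel)) return(NA_real_)
    mean(positive[sel])
  }, numeric(1))
  tab <- cbind(samples, positive_fraction = unname(frac))
  class(tab) <- c("CompositionTable", "data.frame")
  attr(tab, "categories") <- "positive_fraction"
  if (all(is.na(frac)) || all(frac == 0, na.rm = TRUE)) {
    out <- data.frame(category = "positive_fraction", mean_pre = NA_real_,
                      mean_on = NA_real_, t_statistic = NA_real_,
                      p_raw = NA_real_, n_pre = NA_integer_, n_on = NA_integer_,
                      mode = mode, p_adjusted = NA_real_,
                      stringsAsFactors = FALSE)
  } else {
    out <- paired_comparison(tab, mode = mode)
  }
  attr(out, "fractions") <- tab
  out
}
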