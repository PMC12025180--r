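# Evaluation protocol: Dice index, patient-level two-fold cross-validation,
# final-window averaging of test traces, the paired t-test and paired
# Cohen's d effect size, and tabular report generation.

#' Dice index between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both masks are empty.
#' Probabilistic predictions should be thresholded at 0.5 before calling.
#'
#' @param pred_mask,true_mask binary masks (logical or 0/1) of equal shape.
#' @return scalar in `[0, 1]`.
#' @export
dice_index <- function(pred_mask, true_mask) {
  if (!identical(dim(pred_mask), dim(true_mask))) {
    stop("masks must have identical shapes")
  }
  a <- pred_mask > 0.5
  b <- true_mask > 0.5
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

#' Arithmetic mean over the final window of a metric trace
#'
#' Averaging the test metric over the last `window` epochs gives a more
#' stable measure than the final epoch alone when test sets are small.
#'
#' @param trace numeric vector of per-epoch metric values.
#' @param window window length (default 100).
#' @return scalar mean of the last `window` entries.
#' @export
final_window_average <- function(trace, window = 100L) {
  if (length(trace) < window) {
    stop("trace has length ", length(trace), " but the window requires at least ", window)
  }
  mean(utils::tail(trace, window))
}

#' Paired t-test (closed form)
#'
#' Two-sided paired t-test on equal-length series: `t = mean(d) / (sd(d) /
#' sqrt(n))` with `d = x - y`, the sample standard deviation using the
#' `n - 1` denominator, and the p-value from the t distribution with `n - 1`
#' degrees of freedom.
#'
#' @param x,y paired numeric series (e.g. per-epoch test metrics of two
#'   models over the final window).
#' @return list with `t`, `p`, `df`, `mean_diff`.
#' @export
paired_t_test <- function(x, y) {
  if (length(x) != length(y)) stop("paired series must have equal length")
  n <- length(x)
  if (n < 2) stop("paired t-test needs n >= 2")
  d <- x - y
  s <- stats::sd(d)
  if (s == 0) stop("degenerate paired t-test: all differences are identical (zero variance)")
  t <- mean(d) / (s / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  list(t = t, p = p, df = n - 1, mean_diff = mean(d))
}

#' Paired Cohen's d (d_z)
#'
#' Effect size of a paired comparison: `mean(d) / sd(d)` with `d = x - y`;
#' the sign is preserved. Conventional magnitude thresholds: small <= 0.2,
#' medium 0.5, large >= 0.8.
#'
#' @param x,y paired numeric series.
#' @return scalar effect size.
#' @export
cohens_d <- function(x, y) {
  if (length(x) != length(y)) stop("paired series must have equal length")
  d <- x - y
  s <- stats::sd(d)
  if (s == 0) stop("degenerate effect size: zero variance of differences")
  mean(d) / s
}

#' Patient-level two-fold partition
#'
#' One seeded random halving at patient level, applied per condition (the
#' same partition is reused across runs given the seed). A patient's eyes
#' never straddle folds; per-condition fold sizes differ by at most one
#' patient.
#'
#' @param manifest dataset manifest with `patient_id` and `condition`.
#' @param seed partition seed.
#' @return data.frame `sample_id`, `patient_id`, `condition`, `fold` (1/2).
#' @export
make_folds <- function(manifest, seed = 0L) {
  out <- lapply(split(manifest, manifest$condition), function(m) {
    pts <- unique(m$patient_id)
    if (length(pts) < 2) stop("condition ", m$condition[1], " has fewer than 2 patients")
    half <- with_seed(derive_seed(seed, "folds", m$condition[1]), {
      sample(pts, floor(length(pts) / 2))
    })
    data.frame(sample_id = m$sample_id, patient_id = m$patient_id,
               condition = m$condition,
               fold = ifelse(m$patient_id %in% half, 1L, 2L),
               stringsAsFactors = FALSE)
  })
  folds <- do.call(rbind, out)
  rownames(folds) <- NULL
  ok <- tapply(folds$fold, folds$patient_id, function(f) length(unique(f)) == 1L)
  if (!all(ok)) stop("internal error: a patient's eyes landed in both folds")
  folds[match(manifest$sample_id, folds$sample_id), ]
}

#' Two-fold cross-validation
#'
#' Trains on one fold and tests on the other, then swaps, with the same
#' patient-level random partition applied to each condition. `train_fn`
#' does the actual model fitting and evaluation, so the orchestration is
#' agnostic to the model variant under test.
#'
#' @param dataset in-memory dataset with a `manifest`.
#' @param train_fn `function(train_rows, test_rows, fold)` returning a named
#'   list of per-condition per-epoch test Dice traces (numeric vectors).
#' @param seed partition seed.
#' @param window final-window length for [final_window_average()].
#' @return an `faz_eval_report`: list with `folds`, `traces` (per fold), and
#'   `final_window_mean` (per condition, averaged over folds).
#' @export
two_fold_cv <- function(dataset, train_fn, seed = 0L, window = 100L) {
  folds <- make_folds(dataset$manifest, seed)
  traces <- list()
  for (fold in 1:2) {
    train_rows <- which(folds$fold == fold)
    test_rows <- which(folds$fold != fold)
    traces[[fold]] <- train_fn(train_rows, test_rows, fold)
  }
  conds <- unique(dataset$manifest$condition)
  fwm <- sapply(conds, function(cn) {
    mean(vapply(traces, function(tr) {
      if (is.null(tr[[cn]])) return(NA_real_)
      final_window_average(tr[[cn]], min(window, length(tr[[cn]])))
    }, numeric(1)), na.rm = TRUE)
  })
  structure(list(folds = folds, traces = traces, final_window_mean = fwm,
                 window = window),
            class = "faz_eval_report")
}

#' Write evaluation report files
#'
#' Writes `tables/dice.csv` (rows: model variants; columns: conditions plus
#' Mean), `stats.json` (paired t-test p-values and Cohen's d per
#' comparison), and `folds.tsv`. Missing traces are listed in the stats
#' block under `missing`, never silently dropped. Output is deterministic
#' for identical inputs.
#'
#' @param traces named list (model variant) of named lists (condition) of
#'   per-epoch test Dice traces.
#' @param comparisons named list of pairs `c(variant_a, variant_b)` to be
#'   tested per condition over the final window.
#' @param dir output directory.
#' @param window final-window length.
#' @param folds optional fold assignment data.frame.
#' @return the report list, invisibly.
#' @export
make_report <- function(traces, comparisons = list(), dir, window = 100L,
                        folds = NULL) {
  dir.create(file.path(dir, "tables"), recursive = TRUE, showWarnings = FALSE)
  conds <- unique(unlist(lapply(traces, names)))
  missing <- character(0)
  tab <- data.frame(model = names(traces), stringsAsFactors = FALSE)
  for (cn in conds) {
    tab[[cn]] <- vapply(names(traces), function(v) {
      tr <- traces[[v]][[cn]]
      if (is.null(tr)) {
        missing <<- c(missing, paste(v, cn, sep = "/"))
        return(NA_real_)
      }
      round(100 * final_window_average(tr, min(window, length(tr))), 1)
    }, numeric(1))
  }
  tab$Mean <- round(rowMeans(tab[, conds, drop = FALSE], na.rm = TRUE), 1)
  utils::write.csv(tab, file.path(dir, "tables", "dice.csv"), row.names = FALSE)
  stats <- list()
  for (cmp in names(comparisons)) {
    pair <- comparisons[[cmp]]
    stats[[cmp]] <- lapply(stats::setNames(conds, conds), function(cn) {
      a <- traces[[pair[1]]][[cn]]
      b <- traces[[pair[2]]][[cn]]
      if (is.null(a) || is.null(b)) return(list(error = "missing trace"))
      w <- min(window, length(a), length(b))
      a <- utils::tail(a, w); b <- utils::tail(b, w)
      tt <- tryCatch(paired_t_test(a, b), error = function(e) NULL)
      dd <- tryCatch(cohens_d(a, b), error = function(e) NULL)
      list(t = if (!is.null(tt)) tt$t else NA, p = if (!is.null(tt)) tt$p else NA,
           cohens_d = if (!is.null(dd)) dd else NA, n = w)
    })
  }
  blob <- list(window = window, comparisons = stats, missing = missing)
  jsonlite::write_json(blob, file.path(dir, "stats.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE)
  if (!is.null(folds)) {
    utils::write.table(folds[, c("sample_id", "fold")], file.path(dir, "folds.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(table = tab, stats = blob))
}
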