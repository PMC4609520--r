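# Loss functions, the repeated ten-fold cross-validation protocol, and
# per-disease report tables.

#' Zero-one accuracy of single-label predictions
#'
#' Fraction of exactly matching labels, `(1/n) sum delta(pred_i, truth_i)`.
#'
#' @param pred,truth Equal-length nonempty label vectors.
#' @return A number in `[0, 1]`.
#' @export
zero_one_accuracy <- function(pred, truth) {
  if (length(pred) != length(truth)) stop_config("length mismatch")
  if (!length(pred)) stop_config("empty prediction vector")
  mean(pred == truth)
}

as_label_sets <- function(x) {
  if (is.matrix(x)) apply(x, 1L, function(r) which(r == 1L), simplify = FALSE)
  else if (is.list(x)) x
  else stop_config("label sets must be a list or a 0/1 matrix")
}

#' Hamming loss for multi-label predictions
#'
#' Per record, the size of the symmetric difference between predicted and
#' true label sets divided by the true set size (the literal normalization
#' of the source definition, which can exceed 1 when predictions are
#' large); averaged over records. `normalize = "universe"` divides by the
#' label-universe size instead, the conventional bounded variant.
#'
#' @param pred_sets,truth_sets Lists of label index vectors, or 0/1
#'   matrices (rows = records). Truth sets must be nonempty under the
#'   `"truth"` normalization.
#' @param normalize `"truth"` (default) or `"universe"`.
#' @param universe_size Label-universe size, required for `"universe"`.
#' @return Nonnegative mean loss; 0 iff every record matches exactly.
#' @export
hamming_loss <- function(pred_sets, truth_sets,
                         normalize = c("truth", "universe"),
                         universe_size = NULL) {
  normalize <- match.arg(normalize)
  pred <- as_label_sets(pred_sets)
  truth <- as_label_sets(truth_sets)
  if (length(pred) != length(truth) || !length(pred))
    stop_config("pred and truth must be nonempty lists of equal length")
  per <- vapply(seq_along(pred), function(i) {
    sd_size <- length(setdiff(pred[[i]], truth[[i]])) +
      length(setdiff(truth[[i]], pred[[i]]))
    denom <- if (normalize == "truth") length(truth[[i]])
             else universe_size %||%
               stop_config("universe_size required for normalize='universe'")
    if (denom == 0L)
      stop_config("record %d: empty truth set has undefined normalization", i)
    sd_size / denom
  }, numeric(1L))
  mean(per)
}

#' @rdname hamming_loss
#' @details `hamming_accuracy()` reports `1 - loss`, floored at 0.
#' @export
hamming_accuracy <- function(pred_sets, truth_sets,
                             normalize = c("truth", "universe"),
                             universe_size = NULL) {
  max(0, 1 - hamming_loss(pred_sets, truth_sets, normalize, universe_size))
}

#' Repeated k-fold cross-validation plan
#'
#' @param n_folds Folds per repeat (default 10).
#' @param n_repeats Independent reshuffles of the dataset (default 20, for
#'   `n_folds * n_repeats` runs in total).
#' @param seed Integer seed; each repeat uses a derived sub-seed.
#' @param stratify Stratify fold assignment by a label vector (off by
#'   default: the protocol divides the data purely at random).
#' @return An object of class `cv_plan`.
#' @export
cv_plan <- function(n_folds = 10L, n_repeats = 20L, seed = 1L,
                    stratify = FALSE) {
  if (n_folds < 2L) stop_config("n_folds must be at least 2")
  if (n_repeats < 1L) stop_config("n_repeats must be at least 1")
  structure(list(n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats), seed = as.integer(seed),
                 stratify = isTRUE(stratify)), class = "cv_plan")
}

#' Fold assignments for every repeat
#'
#' Each repeat shuffles the `n` indices independently (seeded) into
#' `n_folds` parts whose sizes differ by at most one; every index appears
#' exactly once per repeat.
#'
#' @param n Number of records (`n >= n_folds`).
#' @param plan A [cv_plan()].
#' @param strata Optional label vector of length `n` used when the plan is
#'   stratified.
#' @return List of length `n_repeats`; each element an integer vector of
#'   fold ids in `1..n_folds`.
#' @export
make_folds <- function(n, plan = cv_plan(), strata = NULL) {
  if (n < plan$n_folds) stop_config("need n >= n_folds")
  lapply(seq_len(plan$n_repeats), function(r)
    with_local_seed(child_seed(plan$seed, r), {
      if (plan$stratify && !is.null(strata)) {
        f <- integer(n)
        for (g in unique(strata)) {
          idx <- which(strata == g)
          f[idx] <- sample(rep_len(seq_len(plan$n_folds), length(idx)))
        }
        f
      } else sample(rep_len(seq_len(plan$n_folds), n))
    }))
}

#' Run the repeated cross-validation protocol
#'
#' For each of the `n_repeats * n_folds` runs, the trainer is fitted on the
#' other folds and evaluated on the held-out fold, under either the
#' zero-one ICD-10 annotation accuracy or the Hamming acupoint
#' recommendation accuracy. Per-disease and overall means and standard
#' deviations are taken across runs (percent scale); set
#' `aggregate = "repeats"` to average folds within a repeat first and take
#' the spread across the repeats instead. A failing run is recorded,
#' excluded with a warning, and counted in the result.
#'
#' @param ds A `clinical_dataset`.
#' @param trainer `function(train_ds, seed)` returning either an object
#'   whose `predict(object, test_ds)` yields a list with elements `tuple`
#'   (data frame with `icd10`, `tcm`) and/or `acupoints` (0/1 matrix) — as
#'   [fit_selective_ensemble()] and [fit_multioutput_boost()] products do —
#'   or such a prediction `function(test_ds)` directly.
#' @param plan A [cv_plan()].
#' @param loss_kind `"zero_one"` (ICD-10 annotation) or `"hamming"`
#'   (acupoint recommendation).
#' @param hamming_normalize Passed to [hamming_loss()].
#' @param disease_names Optional names for the per-disease rows.
#' @param aggregate `"runs"` (spread across all runs, default) or
#'   `"repeats"` (spread across repeat-level fold averages).
#' @return An object of class `eval_result` with `per_disease`
#'   (disease, n, mean, sd), `overall` (mean, sd), `loss_kind`, `n_runs`,
#'   `n_failed`, and the per-run accuracy vector `run_accuracy`.
#' @export
run_crossval <- function(ds, trainer, plan = cv_plan(),
                         loss_kind = c("zero_one", "hamming"),
                         hamming_normalize = "truth",
                         disease_names = NULL,
                         aggregate = c("runs", "repeats")) {
  loss_kind <- match.arg(loss_kind)
  aggregate <- match.arg(aggregate)
  n <- n_records(ds)
  truth_icd <- icd10_index(ds)
  diseases <- sort(unique(truth_icd))
  folds <- make_folds(n, plan, strata = if (plan$stratify) truth_icd)
  run_acc <- numeric(0)
  run_repeat <- integer(0)
  per_dis <- NULL
  n_failed <- 0L
  for (r in seq_len(plan$n_repeats)) {
    for (f in seq_len(plan$n_folds)) {
      test_idx <- which(folds[[r]] == f)
      res <- tryCatch({
        model <- trainer(ds[-test_idx], child_seed(plan$seed, r * 1009L + f))
        pred <- if (is.function(model)) model(ds[test_idx])
                else predict(model, ds[test_idx])
        acc_of <- function(rows) {
          if (loss_kind == "zero_one")
            zero_one_accuracy(pred$tuple$icd10[rows], truth_icd[test_idx][rows])
          else
            hamming_accuracy(pred$acupoints[rows, , drop = FALSE],
                             ds$acupoints[test_idx[rows], , drop = FALSE],
                             normalize = hamming_normalize,
                             universe_size = ds$schema$n_acupoints)
        }
        overall <- acc_of(seq_along(test_idx))
        by_dis <- vapply(diseases, function(d) {
          rows <- which(truth_icd[test_idx] == d)
          if (!length(rows)) NA_real_ else acc_of(rows)
        }, numeric(1L))
        list(overall = overall, by_dis = by_dis)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        n_failed <- n_failed + 1L
        warning("run (repeat ", r, ", fold ", f, ") failed and was excluded: ",
                conditionMessage(res))
        next
      }
      run_acc <- c(run_acc, res$overall)
      run_repeat <- c(run_repeat, r)
      per_dis <- rbind(per_dis, res$by_dis)
    }
  }
  if (!length(run_acc)) stop_config("every cross-validation run failed")
  agg <- function(x, grp) {
    if (aggregate == "repeats")
      x <- vapply(split(x, grp), mean, numeric(1L), na.rm = TRUE)
    c(mean = mean(x, na.rm = TRUE) * 100,
      sd = (if (sum(!is.na(x)) > 1L) sd(x, na.rm = TRUE) else 0) * 100)
  }
  ov <- agg(run_acc, run_repeat)
  pd <- t(vapply(seq_along(diseases), function(j)
    agg(per_dis[, j], run_repeat), numeric(2L)))
  nm <- disease_names %||%
    (attr(ds, "config")$disease_names[
       match(diseases, attr(ds, "config")$disease_to_icd10)] %||%
       paste0("label_", diseases))
  structure(list(
    per_disease = data.frame(disease = nm, icd10 = diseases,
                             n = as.integer(table(factor(truth_icd,
                                                         levels = diseases))),
                             mean = pd[, 1L], sd = pd[, 2L]),
    overall = ov, loss_kind = loss_kind,
    n_runs = length(run_acc) + n_failed, n_failed = n_failed,
    run_accuracy = run_acc, run_repeat = run_repeat),
    class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}

#' Count diseases where the first method is strictly best
#'
#' Given a per-disease mean-accuracy table with one column per method,
#' counts the diseases on which method 1 strictly exceeds every other
#' method; ties count as not best. The count is invariant under permuting
#' the comparison methods.
#'
#' @param table Numeric matrix or data frame, rows = diseases, columns =
#'   methods (method of interest first), no missing cells.
#' @return Integer count.
#' @export
count_best_method <- function(table) {
  m <- as.matrix(table)
  if (ncol(m) < 1L) stop_config("need at least one method column")
  if (any(is.na(m))) stop_config("missing cells in the accuracy table")
  if (ncol(m) == 1L) return(nrow(m))
  sum(apply(m, 1L, function(row) all(row[1L] > row[-1L])))
}

#' Render an evaluation result as a fixed-layout text table
#'
#' `"table4"` style prints one row per disease with its record count and
#' `mean ± sd` cell; `"table5"` style prints the per-disease mean only.
#' Cells round half-away-from-zero to one decimal; the overall `Total` row
#' comes last.
#'
#' @param result An `eval_result`.
#' @param style `"table4"` or `"table5"`.
#' @return Character vector of table lines.
#' @export
render_report <- function(result, style = c("table4", "table5")) {
  style <- match.arg(style)
  pd <- result$per_disease
  lines <- if (style == "table4") {
    c(sprintf("%-3s %-28s %6s %14s", "No.", "Name", "Size", "Accuracy"),
      sprintf("%-3d %-28s %6d %6s ± %s", seq_len(nrow(pd)), pd$disease,
              pd$n, fmt1(pd$mean), fmt1(pd$sd)))
  } else {
    c(sprintf("%-3s %-28s %9s", "No.", "Name", "Accuracy"),
      sprintf("%-3d %-28s %9s", seq_len(nrow(pd)), pd$disease, fmt1(pd$mean)))
  }
  c(lines,
    sprintf("%-3s %-28s %6d %6s ± %s", "", "Total", sum(pd$n),
            fmt1(result$overall[["mean"]]), fmt1(result$overall[["sd"]])))
}
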