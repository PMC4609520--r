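#' Configuration of the base-learner pool
#'
#' The pool mixes two learner kinds trained on independent bootstrap
#' samples: axis-aligned decision trees (in-package CART, unlimited depth by
#' default) and regularized linear margin classifiers (ridge multinomial
#' models via \pkg{glmnet}, standing in for the kernel machines of the
#' original setup, which have no offline implementation here). The reference
#' configuration uses 500 learners of each kind.
#'
#' @param m_tree Number of tree learners (default 500).
#' @param m_margin Number of margin learners (default 500).
#' @param bootstrap_fraction Fraction of the training set drawn with
#'   replacement per learner (default 1.0).
#' @param seed Pool seed; learner `i` uses a seed derived from `(seed, i)`
#'   only, so results are independent of training order.
#' @param tree_max_depth,tree_min_leaf Tree hyperparameters.
#' @param margin_lambda,margin_alpha `glmnet` regularization (ridge by
#'   default).
#' @param retry_cap Resampling attempts when a bootstrap misses a class.
#' @return An object of class `pool_config`.
#' @export
pool_config <- function(m_tree = 500L, m_margin = 500L,
                        bootstrap_fraction = 1.0, seed = 1L,
                        tree_max_depth = Inf, tree_min_leaf = 1L,
                        margin_lambda = 1e-2, margin_alpha = 0,
                        retry_cap = 25L) {
  if (m_tree < 0L || m_margin < 0L || m_tree + m_margin < 1L)
    stop_config("pool must contain at least one learner")
  if (bootstrap_fraction <= 0)
    stop_config("bootstrap_fraction must be positive")
  structure(list(m_tree = as.integer(m_tree), m_margin = as.integer(m_margin),
                 bootstrap_fraction = bootstrap_fraction,
                 seed = as.integer(seed), tree_max_depth = tree_max_depth,
                 tree_min_leaf = as.integer(tree_min_leaf),
                 margin_lambda = margin_lambda, margin_alpha = margin_alpha,
                 retry_cap = as.integer(retry_cap)),
            class = "pool_config")
}

#' Bootstrap sample of a clinical dataset
#'
#' Draws `round(fraction * n)` records with replacement, seeded
#' reproducibly. Sampling with replacement induces the differences between
#' the base learners' training sets that the ensemble relies on.
#'
#' @param ds A `clinical_dataset`.
#' @param fraction Sample size as a fraction of `n_records(ds)`.
#' @param seed Integer seed.
#' @return A `clinical_dataset` (duplicates permitted) with attribute
#'   `indices`.
#' @export
bootstrap_sample <- function(ds, fraction = 1.0, seed = 1L) {
  n <- n_records(ds)
  if (n < 1L) stop_config("cannot bootstrap an empty dataset")
  if (fraction <= 0) stop_config("fraction must be positive")
  size <- max(1L, as.integer(round(fraction * n)))
  idx <- with_local_seed(seed, sample.int(n, size, replace = TRUE))
  out <- ds[idx]
  attr(out, "indices") <- idx
  out
}

label_space <- function(ds) {
  list(icd10 = sort(unique(icd10_index(ds))),
       tcm = ds$schema$tcm_codes[ds$schema$tcm_codes %in% unique(ds$tcm)])
}

# One base learner: two coupled classifiers (ICD-10 head and TCM head)
# sharing a bootstrap sample, plus bounded margin scores for every binary
# task (per-ICD-label, per-TCM-code, per-acupoint one-vs-rest).
train_base_learner <- function(ds, kind, seed, cfg, labels) {
  n <- n_records(ds)
  boot <- NULL
  for (try in seq_len(cfg$retry_cap)) {
    cand <- bootstrap_sample(ds, cfg$bootstrap_fraction,
                             child_seed(seed, try))
    ls <- label_space(cand)
    if (setequal(ls$icd10, labels$icd10) && setequal(ls$tcm, labels$tcm)) {
      boot <- cand
      break
    }
  }
  if (is.null(boot))
    stop_config(paste0("bootstrap sample still missing a class after %d ",
                       "attempts (learner seed %d); the training set is too ",
                       "small or too imbalanced"), cfg$retry_cap, seed)
  X <- feature_matrix(boot)
  y <- match(icd10_index(boot), labels$icd10)
  z <- match(boot$tcm, labels$tcm)
  acu <- boot$acupoints
  lrn <- list(kind = kind, seed = seed, labels = labels,
              schema = ds$schema, n_train = n_records(boot))
  if (kind == "tree") {
    lrn$model_y <- fit_cart(X, y, n_classes = length(labels$icd10),
                            max_depth = cfg$tree_max_depth,
                            min_leaf = cfg$tree_min_leaf, aux = acu)
    lrn$model_z <- fit_cart(X, z, n_classes = length(labels$tcm),
                            max_depth = cfg$tree_max_depth,
                            min_leaf = cfg$tree_min_leaf)
    lrn$complexity <- lrn$model_y$n_leaves + lrn$model_z$n_leaves
  } else if (kind == "margin") {
    fit_mn <- function(codes, n_cls) {
      if (n_cls < 2L) return(NULL)  # degenerate single-class head
      suppressWarnings(glmnet::glmnet(
        X, factor(codes, levels = seq_len(n_cls)), family = "multinomial",
        alpha = cfg$margin_alpha, lambda = cfg$margin_lambda,
        standardize = FALSE))
    }
    lrn$model_y <- fit_mn(y, length(labels$icd10))
    lrn$model_z <- fit_mn(z, length(labels$tcm))
    # class-conditional acupoint frequencies on the bootstrap sample
    lrn$acu_freq <- t(vapply(seq_along(labels$icd10), function(c) {
      rows <- which(y == c)
      colMeans(acu[rows, , drop = FALSE])
    }, numeric(ncol(acu))))
    nz <- function(fit) if (is.null(fit)) 0L else
      sum(vapply(fit$beta, function(b) sum(abs(b) > 1e-8), integer(1L)))
    lrn$complexity <- nz(lrn$model_y) + nz(lrn$model_z)
  } else stop_config("unknown learner kind '%s'", kind)
  class(lrn) <- "base_learner"
  lrn
}

#' @export
print.base_learner <- function(x, ...) {
  cat(sprintf("<base_learner: %s, trained on %d records, complexity %d>\n",
              x$kind, x$n_train, x$complexity))
  invisible(x)
}

margin_class_probs <- function(lrn, X, head = c("y", "z")) {
  head <- match.arg(head)
  fit <- lrn[[paste0("model_", head)]]
  n_cls <- length(if (head == "y") lrn$labels$icd10 else lrn$labels$tcm)
  if (is.null(fit)) return(matrix(1, nrow(X), 1L))  # single-class head
  p <- predict(fit, X, type = "response")
  matrix(p[, , 1L], nrow = nrow(X), ncol = n_cls)
}

tuple_class_probs <- function(lrn, X, head) {
  if (lrn$kind == "tree")
    predict(lrn[[paste0("model_", head)]], X, type = "dist")
  else margin_class_probs(lrn, X, head)
}

#' Tuple prediction of a base learner
#'
#' Every base learner emits the full label tuple `(ICD-10 label, TCM
#' diagnosis)` for each record, realized as two coupled heads sharing the
#' learner's bootstrap sample. Ties in class scores resolve to the lowest
#' label index, so prediction is deterministic.
#'
#' @param h A fitted `base_learner`.
#' @param newdata A `clinical_dataset` or feature matrix
#'   (see [feature_matrix()]).
#' @return A data frame with integer column `icd10` (label index) and
#'   character column `tcm`.
#' @export
predict_tuple <- function(h, newdata) {
  stopifnot(inherits(h, "base_learner"))
  X <- if (inherits(newdata, "clinical_dataset")) feature_matrix(newdata)
       else as.matrix(newdata)
  py <- tuple_class_probs(h, X, "y")
  pz <- tuple_class_probs(h, X, "z")
  data.frame(
    icd10 = h$labels$icd10[max.col(py, ties.method = "first")],
    tcm = h$labels$tcm[max.col(pz, ties.method = "first")],
    stringsAsFactors = FALSE)
}

#' Bounded margin score of a base learner on one binary task
#'
#' Tasks are one-vs-rest views of the multi-output problem: `"icd10"` and
#' `"tcm"` tasks score one label against the rest, `"acupoint"` tasks score
#' one of the acupuncture-plan bits. Scores are `2 p - 1` for an internal
#' probability `p`, hence always in `[-1, 1]`: leaf distributions and leaf
#' acupoint frequencies for trees; model class probabilities and
#' probability-weighted class-conditional acupoint frequencies for margin
#' learners.
#'
#' @param h A fitted `base_learner`.
#' @param newdata A `clinical_dataset` or feature matrix.
#' @param task One of `"icd10"`, `"tcm"`, `"acupoint"`.
#' @param index Task index: an ICD-10 label index, a TCM code index into the
#'   schema's code set, or an acupoint column.
#' @return Numeric vector of margins in `[-1, 1]`.
#' @export
score_binary <- function(h, newdata, task = c("icd10", "tcm", "acupoint"),
                         index) {
  stopifnot(inherits(h, "base_learner"))
  task <- match.arg(task)
  X <- if (inherits(newdata, "clinical_dataset")) feature_matrix(newdata)
       else as.matrix(newdata)
  p <- switch(task,
    icd10 = {
      pos <- match(index, h$labels$icd10)
      if (is.na(pos)) rep(0, nrow(X))
      else tuple_class_probs(h, X, "y")[, pos]
    },
    tcm = {
      code <- h$schema$tcm_codes[index]
      pos <- match(code, h$labels$tcm)
      if (is.na(pos)) rep(0, nrow(X))
      else tuple_class_probs(h, X, "z")[, pos]
    },
    acupoint = {
      if (h$kind == "tree") predict(h$model_y, X, type = "aux")[, index]
      else {
        py <- tuple_class_probs(h, X, "y")
        as.numeric(py %*% h$acu_freq[, index])
      }
    })
  2 * p - 1
}

#' Train a pool of base learners on bootstrap samples
#'
#' Trains `m_tree` decision trees followed by `m_margin` margin learners,
#' each on an independent bootstrap sample of `ds`. Learner `i` depends only
#' on `(cfg$seed, i)`, so the pool is reproducible and order-independent. A
#' bootstrap sample missing an ICD-10 or TCM class is redrawn up to
#' `retry_cap` times before failing with a diagnostic.
#'
#' @param ds A nonempty `clinical_dataset` with every label present at least
#'   once.
#' @param cfg A [pool_config()].
#' @return A list of `base_learner` objects of length `m_tree + m_margin`,
#'   with class `learner_pool`.
#' @export
train_pool <- function(ds, cfg = pool_config()) {
  stopifnot(inherits(ds, "clinical_dataset"), inherits(cfg, "pool_config"))
  if (n_records(ds) < 1L) stop_config("training dataset is empty")
  labels <- label_space(ds)
  kinds <- c(rep("tree", cfg$m_tree), rep("margin", cfg$m_margin))
  pool <- lapply(seq_along(kinds), function(i)
    train_base_learner(ds, kinds[i], child_seed(cfg$seed, i), cfg, labels))
  structure(pool, class = c("learner_pool", "list"), config = cfg)
}

#' @export
print.learner_pool <- function(x, ...) {
  cat(sprintf("<learner_pool: %d learners (%d tree, %d margin)>\n",
              length(x), sum(vapply(x, `[[`, "", "kind") == "tree"),
              sum(vapply(x, `[[`, "", "kind") == "margin")))
  invisible(x)
}

#' Capacity estimates for the weight penalty of capacity-regularized boosting
#'
#' Each learner's complexity proxy `c_i` is its fitted size — total leaf
#' count for trees, count of non-negligible coefficients for margin
#' learners. The penalty coefficient is `r_i = sqrt(c_i / n_train)`,
#' normalized so the largest equals 1, giving bigger models a larger weight
#' cost in the boosting objective.
#'
#' @param pool A list of fitted `base_learner`s.
#' @param normalize Divide by the maximum (default); `FALSE` returns the raw
#'   `sqrt(c_i / n)` values.
#' @return Numeric vector `r`, with `max(r) = 1` when normalized (all zero
#'   if every model has zero size).
#' @export
complexity_estimates <- function(pool, normalize = TRUE) {
  r <- vapply(pool, function(h) sqrt(h$complexity / h$n_train), numeric(1L))
  m <- max(r)
  if (normalize && m > 0) r / m else r
}
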