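# Capacity-regularized boosting: combination weights are fitted by
# minimizing a convex surrogate of the margin loss plus a per-learner
# capacity penalty, under a nonnegativity and total-weight budget
# constraint, by cyclic coordinate descent.  The classical AdaBoost
# reweighting scheme is provided as the baseline it generalizes.

#' Configuration of the capacity-regularized boosting solver
#'
#' The solver minimizes
#' `(1/n) sum_j Phi(1 - y_j sum_i alpha_i h_i(x_j)) + lambda sum_i alpha_i r_i`
#' over `alpha >= 0` with `sum(alpha) <= weight_cap`, where `Phi` is a
#' convex margin surrogate and `r_i` a capacity estimate per learner
#' (see [complexity_estimates()]). The printed budget of the source
#' formulation, `1/n`, shrinks every weight toward zero as the sample
#' grows; the default `"unit"` cap of 1 is the practical reading, with
#' `"paper"` selecting the literal `1/n` budget.
#'
#' @param lambda Nonnegative regularization weight (default 0.1).
#' @param surrogate `"exponential"` (`Phi(u) = exp(u)`) or `"logistic"`
#'   (`Phi(u) = log(1 + exp(u))`).
#' @param complexities Optional vector `r` of nonnegative capacity
#'   penalties, one per learner; defaults to [complexity_estimates()] when
#'   fitted from a pool, or zero.
#' @param weight_cap `"unit"`, `"paper"`, or a positive number.
#' @param max_iters Cap on coordinate-descent sweeps.
#' @param tolerance Stop when a full sweep improves the objective by less.
#' @param seed Stored for provenance (the solver itself is deterministic).
#' @return An object of class `boost_config`.
#' @export
boost_config <- function(lambda = 0.1,
                         surrogate = c("exponential", "logistic"),
                         complexities = NULL, weight_cap = "unit",
                         max_iters = 200L, tolerance = 1e-8, seed = 1L) {
  surrogate <- match.arg(surrogate)
  if (lambda < 0) stop_config("lambda must be nonnegative")
  if (is.character(weight_cap) && !weight_cap %in% c("unit", "paper"))
    stop_config("weight_cap must be 'unit', 'paper', or a positive number")
  if (is.numeric(weight_cap) && weight_cap <= 0)
    stop_config("numeric weight_cap must be positive")
  if (!is.null(complexities) &&
      (any(!is.finite(complexities)) || any(complexities < 0)))
    stop_config("complexities must be finite and nonnegative")
  structure(list(lambda = lambda, surrogate = surrogate,
                 complexities = complexities, weight_cap = weight_cap,
                 max_iters = as.integer(max_iters), tolerance = tolerance,
                 seed = as.integer(seed)),
            class = "boost_config")
}

surrogate_fn <- function(name) {
  switch(name,
         exponential = function(u) exp(u),
         logistic = function(u) log1p(exp(u)),
         stop_config("unknown surrogate '%s'", name))
}

resolve_cap <- function(weight_cap, n) {
  if (is.numeric(weight_cap)) weight_cap
  else if (weight_cap == "unit") 1
  else 1 / n
}

# Eq-style objective over margin matrix H (n x m, entries in [-1, 1]) and
# labels y in {-1, +1}.
boost_objective <- function(alpha, yH, phi, lambda, r) {
  mean(phi(1 - as.numeric(yH %*% alpha))) + lambda * sum(alpha * r)
}

#' Fit combination weights by capacity-regularized boosting
#'
#' Cyclic coordinate descent on the convex objective described in
#' [boost_config()]: each sweep line-searches every coordinate over its
#' feasible interval `[0, cap - sum(alpha[-i])]` (golden-section search
#' with explicit endpoint checks, so the objective never increases), until
#' the per-sweep improvement falls below `tolerance` or `max_iters` sweeps.
#'
#' @param scores Numeric matrix of learner margin scores, one column per
#'   learner, entries in `[-1, 1]`.
#' @param labels Vector of `-1`/`+1` labels, one per row of `scores`.
#' @param cfg A [boost_config()].
#' @return An object of class `boost_model` with elements `alpha`
#'   (nonnegative, `sum(alpha) <= cap`), `objective_trace` (non-increasing),
#'   `cap`, `converged`, and the configuration.
#' @export
deepboost_weights <- function(scores, labels, cfg = boost_config()) {
  H <- as.matrix(scores)
  n <- nrow(H); m <- ncol(H)
  if (length(labels) != n) stop_config("labels must match rows of scores")
  if (!all(labels %in% c(-1, 1)))
    stop_config("labels must be -1/+1")
  if (any(!is.finite(H)) || any(abs(H) > 1 + 1e-9))
    stop_config("learner scores must be finite margins in [-1, 1]")
  r <- cfg$complexities %||% rep(0, m)
  if (length(r) != m)
    stop_config("complexities length %d does not match %d learners",
                length(r), m)
  phi <- surrogate_fn(cfg$surrogate)
  cap <- resolve_cap(cfg$weight_cap, n)
  yH <- H * labels
  alpha <- rep(0, m)
  margins <- rep(0, n)  # yH %*% alpha, maintained incrementally
  obj <- function(mg, a) mean(phi(1 - mg)) + cfg$lambda * sum(a * r)
  trace <- obj(margins, alpha)
  converged <- FALSE
  line_min <- function(f, lo, hi) {
    cand <- c(lo, hi)
    if (hi - lo > 1e-12)
      cand <- c(cand, optimize(f, c(lo, hi), tol = 1e-10)$minimum)
    vals <- vapply(cand, f, numeric(1L))
    list(x = cand[which.min(vals)], value = min(vals))
  }
  coord_sweep <- function() {
    for (i in seq_len(m)) {
      hi <- yH[, i]
      base <- margins - alpha[i] * hi
      upper <- max(0, cap - sum(alpha[-i]))
      f1 <- function(a) mean(phi(1 - (base + a * hi))) +
        cfg$lambda * (sum(alpha[-i] * r[-i]) + a * r[i])
      best <- line_min(f1, 0, upper)
      # accept only improvements: the trace must be non-increasing
      if (best$value < f1(alpha[i]) - 1e-15) alpha[i] <<- best$x
      margins <<- base + alpha[i] * hi
    }
  }
  # exchange step along e_i - e_j: keeps sum(alpha) fixed, so progress is
  # possible even when the total-weight budget is active (where single
  # coordinates can only move down)
  pair_sweep <- function() {
    if (m < 2L) return(invisible())
    for (i in seq_len(m - 1L)) for (j in seq(i + 1L, m)) {
      dij <- yH[, i] - yH[, j]
      f2 <- function(t) mean(phi(1 - (margins + t * dij))) +
        cfg$lambda * (sum(alpha * r) + t * (r[i] - r[j]))
      best <- line_min(f2, -alpha[i], alpha[j])
      if (best$value < f2(0) - 1e-15) {
        alpha[i] <<- alpha[i] + best$x
        alpha[j] <<- alpha[j] - best$x
        margins <<- margins + best$x * dij
      }
    }
  }
  for (it in seq_len(cfg$max_iters)) {
    before <- trace[length(trace)]
    coord_sweep()
    if (before - obj(margins, alpha) < cfg$tolerance) pair_sweep()
    trace <- c(trace, obj(margins, alpha))
    if (before - trace[length(trace)] < cfg$tolerance) {
      converged <- TRUE
      break
    }
  }
  structure(list(alpha = alpha, objective_trace = trace, cap = cap,
                 converged = converged, config = cfg, n = n),
            class = "boost_model")
}

#' @export
print.boost_model <- function(x, ...) {
  cat(sprintf(
    "<boost_model: %d learners, sum(alpha) = %.4g (cap %.4g), objective %.6g>\n",
    length(x$alpha), sum(x$alpha), x$cap,
    x$objective_trace[length(x$objective_trace)]))
  invisible(x)
}

#' Binary decision of a fitted boosting model
#'
#' Computes the weighted ensemble score `y' = sum_i alpha_i s_i(x) /
#' sum_i alpha_i` on the `[0, 1]` probability scale (`y' = 0` when all
#' weights are zero) and returns 1 exactly when `y' >= 0.5`, the decision
#' threshold of the combined learner.
#'
#' @param model A `boost_model`.
#' @param scores Matrix of learner scores on the new data, one column per
#'   learner; margins in `[-1, 1]` by default.
#' @param scale `"margin"` maps scores via `(s + 1) / 2` to `[0, 1]`
#'   first; `"unit"` treats them as already being probabilities.
#' @param type `"class"` for the 0/1 decision, `"response"` for `y'`.
#' @return Integer 0/1 vector, or numeric `y'` values.
#' @export
predict_binary <- function(model, scores, scale = c("margin", "unit"),
                           type = c("class", "response")) {
  stopifnot(inherits(model, "boost_model"))
  scale <- match.arg(scale); type <- match.arg(type)
  S <- as.matrix(scores)
  if (ncol(S) != length(model$alpha))
    stop_config("scores must have one column per fitted learner")
  P <- if (scale == "margin") (S + 1) / 2 else S
  tot <- sum(model$alpha)
  yp <- if (tot > 0) as.numeric(P %*% model$alpha) / tot
        else rep(0, nrow(S))
  if (type == "response") yp else as.integer(yp >= 0.5)
}

#' Classical AdaBoost over a weak-learner family
#'
#' Discrete AdaBoost: the sample distribution starts uniform
#' (`V_i = 1/n`); each round trains a weak learner on the weighted data,
#' computes its weighted error `eps_t`, assigns the round weight
#' `alpha_t = log((1 - eps_t) / eps_t) / 2`, and reweights the sample so
#' misclassified records are chosen again with high probability. Stops
#' early on a perfect round (`eps_t = 0`, weight capped) or a
#' no-better-than-chance round (`eps_t >= 1/2`, with a warning).
#'
#' @param weak_family Trainer `function(X, y, w, seed)` returning a
#'   predictor `function(Xnew) -> -1/+1`; see [stump_trainer()].
#' @param X Feature matrix.
#' @param y `-1`/`+1` labels.
#' @param rounds Number of boosting rounds.
#' @param seed Integer seed passed to each round's trainer.
#' @return An object of class `adaboost_model` with `alpha`,
#'   `round_learners`, and `distribution_trace` (each row sums to 1).
#' @export
adaboost_fit <- function(weak_family, X, y, rounds = 20L, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (!all(y %in% c(-1, 1))) stop_config("labels must be -1/+1")
  V <- rep(1 / n, n)
  alpha <- numeric(0)
  learners <- list()
  vtrace <- matrix(V, nrow = 1L)
  eps_floor <- 1e-10
  for (t in seq_len(rounds)) {
    h <- weak_family(X, y, V, child_seed(seed, t))
    pred <- h(X)
    eps <- sum(V[pred != y])
    if (eps >= 0.5) {
      warning("weak learner no better than chance (weighted error ",
              signif(eps, 4), "); stopping at round ", t - 1L)
      break
    }
    a <- 0.5 * log((1 - max(eps, eps_floor)) / max(eps, eps_floor))
    alpha <- c(alpha, a)
    learners[[length(learners) + 1L]] <- h
    V <- V * exp(-a * y * pred)
    V <- V / sum(V)
    vtrace <- rbind(vtrace, V)
    if (eps <= 0) break  # perfect round: further rounds cannot help
  }
  dimnames(vtrace) <- NULL
  structure(list(alpha = alpha, round_learners = learners,
                 distribution_trace = vtrace),
            class = "adaboost_model")
}

#' @export
predict.adaboost_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!length(object$alpha)) stop_config("adaboost model has no rounds")
  f <- rowSums(matrix(vapply(seq_along(object$alpha), function(t)
    object$alpha[t] * object$round_learners[[t]](X), numeric(nrow(X))),
    nrow = nrow(X)))
  ifelse(f >= 0, 1L, -1L)
}

#' Decision-stump trainer for AdaBoost
#'
#' Returns a weak-learner family fitting depth-1 weighted trees
#' (via the in-package CART), predicting in `-1`/`+1`.
#'
#' @return A `function(X, y, w, seed)` suitable for [adaboost_fit()].
#' @export
stump_trainer <- function() {
  function(X, y, w, seed) {
    cls <- ifelse(y > 0, 2L, 1L)
    tree <- fit_cart(X, cls, weights = w, n_classes = 2L, max_depth = 1L)
    function(Xnew) ifelse(predict(tree, Xnew, type = "class") == 2L, 1L, -1L)
  }
}

# Per-learner class/acupoint probabilities on a dataset, computed once and
# sliced by every one-vs-rest head.
pool_probabilities <- function(pool, newdata) {
  X <- if (inherits(newdata, "clinical_dataset")) feature_matrix(newdata)
       else as.matrix(newdata)
  lapply(pool, function(h) {
    py <- tuple_class_probs(h, X, "y")
    pz <- tuple_class_probs(h, X, "z")
    pacu <- if (h$kind == "tree") predict(h$model_y, X, type = "aux")
            else py %*% h$acu_freq
    list(py = py, pz = pz, pacu = pacu, labels = h$labels)
  })
}

head_margins <- function(probs, task, index, schema) {
  do.call(cbind, lapply(probs, function(p) {
    pr <- switch(task,
      icd10 = {
        pos <- match(index, p$labels$icd10)
        if (is.na(pos)) rep(0, nrow(p$py)) else p$py[, pos]
      },
      tcm = {
        pos <- match(schema$tcm_codes[index], p$labels$tcm)
        if (is.na(pos)) rep(0, nrow(p$pz)) else p$pz[, pos]
      },
      acupoint = p$pacu[, index])
    2 * pr - 1
  }))
}

#' Multi-output boosting over a base-learner pool
#'
#' Lifts the binary capacity-regularized booster to the full clinical-coding
#' output: one one-vs-rest boosted head per observed ICD-10 label and per
#' observed TCM code (predictions take the head with the largest ensemble
#' score `y'`), and one thresholded head per acupoint
#' (recommended when `y' >= 0.5`). Schema labels never observed in `ds` are
#' excluded from the heads with a warning and can never be predicted.
#'
#' @param pool A fitted list of `base_learner`s.
#' @param ds Training `clinical_dataset`.
#' @param cfg A [boost_config()]; when `cfg$complexities` is `NULL` the
#'   pool's [complexity_estimates()] are used.
#' @return An object of class `multioutput_boost`.
#' @export
fit_multioutput_boost <- function(pool, ds, cfg = boost_config()) {
  stopifnot(length(pool) >= 1L, inherits(ds, "clinical_dataset"))
  if (is.null(cfg$complexities))
    cfg$complexities <- complexity_estimates(pool)
  schema <- ds$schema
  labels <- label_space(ds)
  missing_icd <- setdiff(seq_len(schema$n_icd10), labels$icd10)
  missing_tcm <- setdiff(schema$tcm_codes, labels$tcm)
  if (length(missing_icd) || length(missing_tcm))
    warning("labels absent from training data are excluded from boosting: ",
            paste(c(paste0("icd10:", missing_icd), missing_tcm),
                  collapse = ", "))
  probs <- pool_probabilities(pool, ds)
  truth_icd <- icd10_index(ds)
  tcm_idx <- match(ds$tcm, schema$tcm_codes)
  fit_head <- function(task, index, pos_mask) {
    H <- head_margins(probs, task, index, schema)
    deepboost_weights(H, ifelse(pos_mask, 1, -1), cfg)
  }
  icd_heads <- lapply(labels$icd10, function(L)
    fit_head("icd10", L, truth_icd == L))
  tcm_pos <- match(labels$tcm, schema$tcm_codes)
  tcm_heads <- lapply(tcm_pos, function(i)
    fit_head("tcm", i, tcm_idx == i))
  acu_heads <- lapply(seq_len(schema$n_acupoints), function(t)
    fit_head("acupoint", t, ds$acupoints[, t] == 1L))
  structure(list(pool = pool, schema = schema, labels = labels,
                 icd_heads = icd_heads, tcm_heads = tcm_heads,
                 acu_heads = acu_heads, config = cfg),
            class = "multioutput_boost")
}

#' @export
print.multioutput_boost <- function(x, ...) {
  cat(sprintf(
    "<multioutput_boost: %d ICD-10 + %d TCM + %d acupoint heads over %d learners>\n",
    length(x$icd_heads), length(x$tcm_heads), length(x$acu_heads),
    length(x$pool)))
  invisible(x)
}

#' Predict from a multi-output boosted ensemble
#'
#' @param object A `multioutput_boost`.
#' @param newdata A `clinical_dataset` or feature matrix.
#' @param ... Unused.
#' @return A list with `tuple` (data frame `icd10`, `tcm`: argmax over the
#'   one-vs-rest head scores, ties to the lowest label index) and
#'   `acupoints` (0/1 matrix from the per-acupoint threshold rule).
#' @export
predict.multioutput_boost <- function(object, newdata, ...) {
  probs <- pool_probabilities(object$pool, newdata)
  schema <- object$schema
  n <- nrow(probs[[1L]]$py)
  head_resp <- function(heads, task, indices) {
    vapply(seq_along(heads), function(k) {
      H <- head_margins(probs, task, indices[k], schema)
      predict_binary(heads[[k]], H, type = "response")
    }, numeric(n))
  }
  icd_resp <- matrix(head_resp(object$icd_heads, "icd10", object$labels$icd10),
                     nrow = n)
  tcm_resp <- matrix(head_resp(object$tcm_heads, "tcm",
                               match(object$labels$tcm, schema$tcm_codes)),
                     nrow = n)
  acu_resp <- matrix(head_resp(object$acu_heads, "acupoint",
                               seq_len(schema$n_acupoints)), nrow = n)
  list(tuple = data.frame(
         icd10 = object$labels$icd10[max.col(icd_resp, ties.method = "first")],
         tcm = object$labels$tcm[max.col(tcm_resp, ties.method = "first")],
         stringsAsFactors = FALSE),
       acupoints = matrix(as.integer(acu_resp >= 0.5), nrow = n))
}
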