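# Shared fixtures (built once per test run) and independent oracles.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) assign(name, build(), envir = .fixtures)
  .fixtures[[name]]
}

# zero-noise variant of the small-scale generator config
zero_noise_cfg <- function(seed = 101L) {
  cfg <- default_config("small", seed = seed)
  cfg$keyword_on_prob <- 1
  cfg$keyword_bg_prob <- 0
  cfg$acupoint_flip_prob <- 0
  cfg
}

fx_ds_noisy <- function() fixture("ds_noisy", function()
  generate_records(default_config("small", seed = 42L)))

fx_ds0 <- function() fixture("ds0", function()
  generate_records(zero_noise_cfg(101L)))

fx_ds0_test <- function() fixture("ds0_test", function()
  generate_records(zero_noise_cfg(202L)))

fx_pool0 <- function() fixture("pool0", function()
  train_pool(fx_ds0(), pool_config(m_tree = 3L, m_margin = 3L, seed = 7L)))

fx_pool_noisy <- function() fixture("pool_noisy", function()
  train_pool(fx_ds_noisy(), pool_config(m_tree = 4L, m_margin = 4L,
                                        seed = 9L)))

# hand-built tiny dataset (3 ICD labels, 2 TCM codes) for IO tests
tiny_dataset <- function(n = 10L, seed = 5L, n_keywords = 6L) {
  schema <- clinical_schema(n_icd10 = 3L, n_basic = 2L,
                            n_keywords = n_keywords, n_acupoints = 4L,
                            tcm_codes = c("Z1", "Z2"))
  set.seed(seed)
  icd <- matrix(0L, n, 3L)
  icd[cbind(seq_len(n), sample(3L, n, TRUE))] <- 1L
  clinical_dataset(
    icd10 = icd,
    basic = matrix(rnorm(n * 2L), n),
    keywords = matrix(rbinom(n * n_keywords, 1L, 0.3), n),
    acupoints = matrix(rbinom(n * 4L, 1L, 0.4), n),
    tcm = sample(c("Z1", "Z2"), n, TRUE), schema = schema)
}

# lightweight 2835-record dataset (slim feature blocks) for protocol checks
protocol_ds <- function() {
  fixture("protocol_ds", function() {
    cfg <- default_config("paper", seed = 15L)
    schema <- clinical_schema(31L, 2L, 8L, 6L, cfg$schema$tcm_codes)
    gen <- synthetic_config(
      n_records = 2835L, schema = schema, class_prior = cfg$class_prior,
      disease_to_icd10 = cfg$disease_to_icd10,
      keyword_templates = lapply(1:21, function(i) ((i - 1L) %% 8L) + 1L),
      acupoint_templates = lapply(1:21, function(i) ((i - 1L) %% 6L) + 1L),
      tcm_dx_map = cfg$tcm_dx_map, seed = 15L)
    generate_records(gen)
  })
}

# Independent NDS oracle: the front index of a learner is the length of the
# longest chain of strict dominators ending at it (computed by memoized
# recursion, not by front peeling); final order (front, sum rank, index).
nds_oracle <- function(acc_rank, div_rank) {
  m <- length(acc_rank)
  front <- rep(NA_integer_, m)
  depth <- function(i) {
    if (!is.na(front[i])) return(front[i])
    doms <- which(acc_rank < acc_rank[i] & div_rank < div_rank[i])
    front[i] <<- if (!length(doms)) 1L
                 else 1L + max(vapply(doms, depth, integer(1L)))
    front[i]
  }
  for (i in seq_len(m)) depth(i)
  ord <- order(front, acc_rank + div_rank, seq_len(m))
  out <- integer(m)
  out[ord] <- seq_len(m)
  out
}

# Independent objective + refined-grid oracle for the boosting solver.
# The objective is convex, so recursively zooming a full grid onto the best
# feasible lattice point converges to the constrained optimum.
boost_oracle_objective <- function(alpha, H, y, lambda, r,
                                   surrogate = "exponential") {
  phi <- if (surrogate == "exponential") exp else function(u) log1p(exp(u))
  mean(phi(1 - as.numeric((H * y) %*% alpha))) + lambda * sum(alpha * r)
}

boost_grid_oracle <- function(H, y, lambda, r, cap = 1,
                              surrogate = "exponential",
                              points = 13L, zooms = 7L) {
  m <- ncol(H)
  lo <- rep(0, m); hi <- rep(cap, m)
  best <- NULL
  for (z in seq_len(zooms)) {
    axes <- lapply(seq_len(m), function(i)
      seq(lo[i], hi[i], length.out = points))
    grid <- as.matrix(expand.grid(axes))
    grid <- grid[rowSums(grid) <= cap + 1e-12, , drop = FALSE]
    vals <- apply(grid, 1L, boost_oracle_objective, H = H, y = y,
                  lambda = lambda, r = r, surrogate = surrogate)
    b <- which.min(vals)
    best <- list(alpha = grid[b, ], value = vals[b])
    step <- (hi - lo) / (points - 1L)
    lo <- pmax(0, best$alpha - step)
    hi <- pmin(cap, best$alpha + step)
  }
  best
}
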