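#' Configuration for the synthetic clinical-record generator
#'
#' The generator emulates the statistical structure the coding method
#' assumes: a latent disease class per record (multimodal data with one mode
#' per disease), a characteristic set of diagnosis keywords per disease that
#' fire with high probability against a low background rate, an acupuncture
#' template per disease subject to per-bit flip noise, per-disease basic-info
#' distributions, and a deterministic disease -> (ICD-10 label, TCM
#' diagnosis) assignment. It does not attempt realistic clinical text or
#' correlated comorbidities.
#'
#' @param n_records Number of records to draw.
#' @param schema A [clinical_schema()].
#' @param class_prior Probability vector over diseases (sums to 1).
#' @param disease_to_icd10 Injective integer map disease -> ICD-10 column.
#' @param keyword_templates List (per disease) of characteristic keyword
#'   column indices.
#' @param keyword_on_prob Probability a template keyword fires (default 0.9).
#' @param keyword_bg_prob Background keyword fire probability (default 0.02).
#' @param acupoint_templates List (per disease) of template acupoint columns.
#' @param acupoint_flip_prob Per-bit flip noise on the acupoint template
#'   (default 0.05).
#' @param basic_info_means,basic_info_sds Per-disease parameter matrices
#'   (`n_diseases x n_basic`) of the normal draws for basic info.
#' @param tcm_dx_map Character vector, disease -> TCM diagnosis code.
#' @param disease_names Optional display names, one per disease.
#' @param seed Integer seed; one global seed drives one reproducible stream.
#' @return An object of class `synthetic_config`.
#' @seealso [default_config()], [generate_records()]
#' @export
synthetic_config <- function(n_records, schema, class_prior, disease_to_icd10,
                             keyword_templates, acupoint_templates,
                             keyword_on_prob = 0.9, keyword_bg_prob = 0.02,
                             acupoint_flip_prob = 0.05,
                             basic_info_means = NULL, basic_info_sds = NULL,
                             tcm_dx_map = NULL, disease_names = NULL,
                             seed = 1L) {
  k <- length(class_prior)
  if (is.null(basic_info_means))
    basic_info_means <- matrix(rep(c(50, 0.5, 2, 0.3, 65, 165,
                                     rep(0, schema$n_basic))[seq_len(schema$n_basic)],
                                   each = k), nrow = k)
  if (is.null(basic_info_sds))
    basic_info_sds <- matrix(1, nrow = k, ncol = schema$n_basic)
  if (is.null(tcm_dx_map))
    tcm_dx_map <- schema$tcm_codes[(seq_len(k) - 1L) %%
                                     length(schema$tcm_codes) + 1L]
  cfg <- structure(list(
    n_records = as.integer(n_records), schema = schema,
    class_prior = as.numeric(class_prior),
    disease_to_icd10 = as.integer(disease_to_icd10),
    keyword_templates = lapply(keyword_templates, as.integer),
    acupoint_templates = lapply(acupoint_templates, as.integer),
    keyword_on_prob = keyword_on_prob, keyword_bg_prob = keyword_bg_prob,
    acupoint_flip_prob = acupoint_flip_prob,
    basic_info_means = as.matrix(basic_info_means),
    basic_info_sds = as.matrix(basic_info_sds),
    tcm_dx_map = as.character(tcm_dx_map),
    disease_names = disease_names %||% paste0("disease_", seq_len(k)),
    seed = as.integer(seed)), class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

#' @rdname synthetic_config
#' @param cfg A `synthetic_config`.
#' @export
validate_synthetic_config <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  s <- cfg$schema
  k <- length(cfg$class_prior)
  if (cfg$n_records <= 0L) stop_config("n_records must be positive")
  if (abs(sum(cfg$class_prior) - 1) > 1e-9 || any(cfg$class_prior < 0))
    stop_config("class_prior must be a probability vector summing to 1")
  pr <- c(cfg$keyword_on_prob, cfg$keyword_bg_prob, cfg$acupoint_flip_prob)
  if (any(pr < 0 | pr > 1)) stop_config("probabilities must lie in [0, 1]")
  if (length(cfg$disease_to_icd10) != k ||
      anyDuplicated(cfg$disease_to_icd10) ||
      any(cfg$disease_to_icd10 < 1L | cfg$disease_to_icd10 > s$n_icd10))
    stop_config("disease_to_icd10 must map diseases injectively into 1..%d",
                s$n_icd10)
  if (length(cfg$keyword_templates) != k || length(cfg$acupoint_templates) != k)
    stop_config("one keyword and one acupoint template required per disease")
  if (any(unlist(cfg$keyword_templates) < 1L |
          unlist(cfg$keyword_templates) > s$n_keywords))
    stop_config("keyword template index out of schema bounds")
  if (any(unlist(cfg$acupoint_templates) < 1L |
          unlist(cfg$acupoint_templates) > s$n_acupoints))
    stop_config("acupoint template index out of schema bounds")
  if (!all(dim(cfg$basic_info_means) == c(k, s$n_basic)) ||
      !all(dim(cfg$basic_info_sds) == c(k, s$n_basic)) ||
      any(cfg$basic_info_sds < 0))
    stop_config("basic_info_means/sds must be %d x %d with nonnegative sds",
                k, s$n_basic)
  if (length(cfg$tcm_dx_map) != k || !all(cfg$tcm_dx_map %in% s$tcm_codes))
    stop_config("tcm_dx_map must assign a schema TCM code to every disease")
  invisible(cfg)
}

# Per-disease record counts of the published 2835-record clinical dataset;
# the "paper"-scale class prior is proportional to these.
reference_disease_sizes <- function() {
  c(481L, 75L, 26L, 68L, 96L, 376L, 110L, 33L, 96L, 89L, 47L, 33L, 33L, 47L,
    145L, 124L, 145L, 355L, 33L, 397L, 26L)
}

reference_disease_names <- function() {
  c("Arthralgia syndrome", "Acne", "Epilepsy", "Tinnitus and deafness",
    "Abdominal pain", "Allergic rhinitis", "Neck and shoulder pain",
    "Cervical spondylosis", "Cough", "Facial paralysis",
    "Traumatic brain injury", "Migraine", "Ankylosing spondylitis",
    "Insomnia", "Headache", "Flaccidity syndrome", "Stomachache", "Asthma",
    "Palpitation", "Lumbocrural pain", "Urticaria and rubella")
}

block_templates <- function(k, width, n_cols) {
  lapply(seq_len(k), function(i)
    ((i - 1L) * width + seq_len(width) - 1L) %% n_cols + 1L)
}

#' Ready-made generator configurations
#'
#' `"paper"` reproduces the reference evaluation scale: 2835 records over 21
#' diseases with class sizes proportional to the published per-disease
#' counts, a (31, 11, 4000, 53) schema, and 8-keyword / 6-acupoint templates
#' per disease. `"small"` is a fast test-scale world: 240 records, 6
#' diseases, a (8, 11, 50, 16) schema.
#'
#' @param scale `"small"` or `"paper"`.
#' @param seed Integer seed stored in the config.
#' @return A [synthetic_config()].
#' @export
#' @examples
#' cfg <- default_config("small")
#' ds <- generate_records(cfg)
#' ds
default_config <- function(scale = c("small", "paper"), seed = 1L) {
  scale <- match.arg(scale)
  if (scale == "paper") {
    sizes <- reference_disease_sizes()
    k <- length(sizes)
    schema <- clinical_schema(31L, 11L, 4000L, 53L, paste0("Z", 1:10))
    synthetic_config(
      n_records = sum(sizes), schema = schema, class_prior = sizes / sum(sizes),
      disease_to_icd10 = seq_len(k),
      keyword_templates = block_templates(k, 8L, schema$n_keywords),
      acupoint_templates = block_templates(k, 6L, schema$n_acupoints),
      disease_names = reference_disease_names(), seed = seed)
  } else {
    k <- 6L
    schema <- clinical_schema(8L, 11L, 50L, 16L, paste0("Z", 1:4))
    synthetic_config(
      n_records = 240L, schema = schema, class_prior = rep(1 / k, k),
      disease_to_icd10 = seq_len(k),
      keyword_templates = block_templates(k, 8L, schema$n_keywords),
      acupoint_templates = block_templates(k, 6L, schema$n_acupoints),
      seed = seed)
  }
}

#' Draw a synthetic clinical dataset
#'
#' For each record a disease class is drawn from the class prior; the ICD-10
#' one-hot and TCM diagnosis follow deterministically from the class, the
#' keyword block is the union of template keyword draws
#' (`keyword_on_prob`) and background noise (`keyword_bg_prob`), the
#' acupoint block is the class template with independent per-bit flips, and
#' basic info is a per-class normal draw. Identical configs (including seed)
#' give identical datasets.
#'
#' @param cfg A [synthetic_config()].
#' @return A `clinical_dataset` with attributes `disease` (the generating
#'   class index per record) and `config`.
#' @export
generate_records <- function(cfg) {
  validate_synthetic_config(cfg)
  s <- cfg$schema
  n <- cfg$n_records
  k <- length(cfg$class_prior)
  with_local_seed(cfg$seed, {
    cls <- sample.int(k, n, replace = TRUE, prob = cfg$class_prior)
    kw <- matrix(rbinom(n * s$n_keywords, 1L, cfg$keyword_bg_prob),
                 nrow = n, ncol = s$n_keywords)
    acu <- matrix(0L, nrow = n, ncol = s$n_acupoints)
    basic <- matrix(0, nrow = n, ncol = s$n_basic)
    for (c in seq_len(k)) {
      rows <- which(cls == c)
      if (!length(rows)) next
      tk <- cfg$keyword_templates[[c]]
      fired <- matrix(rbinom(length(rows) * length(tk), 1L,
                             cfg$keyword_on_prob),
                      nrow = length(rows))
      kw[rows, tk] <- pmax(kw[rows, tk, drop = FALSE], fired)
      acu[rows, cfg$acupoint_templates[[c]]] <- 1L
      basic[rows, ] <- rep(cfg$basic_info_means[c, ], each = length(rows)) +
        matrix(rnorm(length(rows) * s$n_basic), nrow = length(rows)) *
          rep(cfg$basic_info_sds[c, ], each = length(rows))
    }
    if (cfg$acupoint_flip_prob > 0) {
      flips <- matrix(rbinom(n * s$n_acupoints, 1L, cfg$acupoint_flip_prob),
                      nrow = n)
      acu <- abs(acu - flips)
    }
    icd <- matrix(0L, nrow = n, ncol = s$n_icd10)
    icd[cbind(seq_len(n), cfg$disease_to_icd10[cls])] <- 1L
    ds <- clinical_dataset(icd10 = icd, basic = basic, keywords = kw,
                           acupoints = acu, tcm = cfg$tcm_dx_map[cls],
                           schema = s)
    attr(ds, "disease") <- cls
    attr(ds, "config") <- cfg
    ds
  })
}

#' Acupoint prediction by class-template lookup
#'
#' Reference predictor that returns, for each record, the acupoint template
#' of the disease encoded in its ICD-10 label. On zero-flip data this is the
#' exact generating template; its Hamming loss against observed acupoints
#' grows with the flip noise, which makes it a useful calibration baseline.
#'
#' @param cfg The generating [synthetic_config()].
#' @param ds A `clinical_dataset` drawn from `cfg`.
#' @return Integer 0/1 matrix of predicted acupoints.
#' @export
template_acupoints <- function(cfg, ds) {
  cls <- match(icd10_index(ds), cfg$disease_to_icd10)
  if (anyNA(cls)) stop_config("dataset carries ICD-10 labels unknown to cfg")
  out <- matrix(0L, nrow = n_records(ds), ncol = cfg$schema$n_acupoints)
  for (c in unique(cls))
    out[cls == c, cfg$acupoint_templates[[c]]] <- 1L
  out
}
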