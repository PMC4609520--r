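#' Keyword dictionary for diagnosis-text featurization
#'
#' A keyword dictionary is an ordered list of normalized keywords (disease
#' names, acupoint names, ZHENG pattern descriptions, severity terms). The
#' entry order is fixed and defines the positions of the boolean text-feature
#' vector produced by [match_keywords()]. Clinical deployments typically use
#' a dictionary of several thousand entries (the reference schema uses 4000).
#'
#' @param entries Character vector of keywords. Entries are normalized
#'   (lower-cased, internal whitespace collapsed) and must be unique after
#'   normalization.
#' @return An object of class `keyword_dictionary`.
#' @export
#' @examples
#' d <- keyword_dictionary(c("Huantiao", "Yinmen", "Taixi"))
#' match_keywords("needling at Huantiao and Taixi", d)
keyword_dictionary <- function(entries) {
  if (length(entries) == 0L) stop_config("keyword dictionary must be nonempty")
  entries <- normalize_text(as.character(entries))
  if (anyDuplicated(entries))
    stop_config("keyword dictionary entries must be unique after normalization")
  if (any(!nzchar(entries)))
    stop_config("keyword dictionary entries must be nonempty after normalization")
  structure(list(entries = entries, size = length(entries)),
            class = "keyword_dictionary")
}

#' @export
print.keyword_dictionary <- function(x, ...) {
  cat(sprintf("<keyword_dictionary: %d entries>\n", x$size))
  invisible(x)
}

#' @rdname keyword_dictionary
#' @param path File with one keyword per line; line order defines vector
#'   positions.
#' @export
read_keyword_dictionary <- function(path) {
  keyword_dictionary(readLines(path, warn = FALSE))
}

#' @rdname keyword_dictionary
#' @param dict A `keyword_dictionary`.
#' @export
write_keyword_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "keyword_dictionary"))
  writeLines(dict$entries, path)
  invisible(path)
}

normalize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Match dictionary keywords against free diagnosis text
#'
#' Each dictionary entry is tested independently for occurrence as a
#' substring of the normalized text (lower case, whitespace collapsed).
#' Overlapping entries both fire; there is no longest-match suppression.
#' The result is the boolean text-feature block of a clinical record.
#'
#' @param text A character scalar (or vector) of free diagnosis text.
#' @param dict A [keyword_dictionary()].
#' @return For a single text, an integer 0/1 vector of length `dict$size`;
#'   for a vector of texts, a matrix with one row per text.
#' @export
match_keywords <- function(text, dict) {
  if (!inherits(dict, "keyword_dictionary")) dict <- keyword_dictionary(dict)
  text <- normalize_text(as.character(text))
  hit <- function(tx) as.integer(vapply(
    dict$entries, function(e) grepl(e, tx, fixed = TRUE), logical(1L),
    USE.NAMES = FALSE))
  if (length(text) == 1L) hit(text)
  else t(vapply(text, hit, integer(dict$size), USE.NAMES = FALSE))
}

#' Declare the column schema of a clinical dataset
#'
#' A record carries four feature groups plus a TCM diagnosis: a one-hot
#' ICD-10 label vector (31-ary in the reference schema; exactly one element
#' set), an 11-ary real vector of basic patient information (age, gender,
#' job type, history, weight, height, ... encoded numerically), a boolean
#' keyword-match vector over the dictionary, and a boolean acupoint vector
#' (53-ary) describing the acupuncture plan.
#'
#' @param n_icd10,n_basic,n_keywords,n_acupoints Group widths.
#' @param tcm_codes Character vector of admissible TCM diagnosis codes
#'   (the finite diagnosis space Z); order fixes the code indexing used for
#'   deterministic tie-breaks.
#' @return An object of class `clinical_schema`.
#' @export
clinical_schema <- function(n_icd10 = 31L, n_basic = 11L, n_keywords = 4000L,
                            n_acupoints = 53L,
                            tcm_codes = paste0("Z", seq_len(10L))) {
  dims <- c(n_icd10 = n_icd10, n_basic = n_basic, n_keywords = n_keywords,
            n_acupoints = n_acupoints)
  if (any(dims < 1L)) stop_config("schema dimensions must be positive")
  tcm_codes <- as.character(tcm_codes)
  if (length(tcm_codes) < 1L || anyDuplicated(tcm_codes))
    stop_config("tcm_codes must be a nonempty set of distinct codes")
  structure(list(n_icd10 = as.integer(n_icd10), n_basic = as.integer(n_basic),
                 n_keywords = as.integer(n_keywords),
                 n_acupoints = as.integer(n_acupoints), tcm_codes = tcm_codes),
            class = "clinical_schema")
}

#' Construct a clinical dataset
#'
#' @param icd10 Integer 0/1 matrix, one row per record, `n_icd10` columns,
#'   exactly one element set per row.
#' @param basic Numeric matrix of basic patient information.
#' @param keywords Integer 0/1 keyword-match matrix.
#' @param acupoints Integer 0/1 acupoint matrix.
#' @param tcm Character vector of TCM diagnosis codes, one per record.
#' @param schema A [clinical_schema()]; defaults to one inferred from the
#'   matrix dimensions and observed codes.
#' @return An object of class `clinical_dataset`.
#' @export
clinical_dataset <- function(icd10, basic, keywords, acupoints, tcm,
                             schema = NULL) {
  icd10 <- as.matrix(icd10); basic <- as.matrix(basic)
  keywords <- as.matrix(keywords); acupoints <- as.matrix(acupoints)
  tcm <- as.character(tcm)
  if (is.null(schema))
    schema <- clinical_schema(ncol(icd10), ncol(basic), ncol(keywords),
                              ncol(acupoints),
                              if (length(tcm)) sort(unique(tcm)) else "Z1")
  ds <- structure(list(icd10 = icd10, basic = basic, keywords = keywords,
                       acupoints = acupoints, tcm = tcm, schema = schema),
                  class = "clinical_dataset")
  validate_dataset(ds)
  ds
}

#' Validate a clinical dataset against its schema
#'
#' Checks the record invariants: matching group widths, boolean groups
#' containing only 0/1, exactly one ICD-10 flag per record, and TCM codes
#' drawn from the schema's code set. Errors name the offending record.
#'
#' @param ds A `clinical_dataset`.
#' @return `ds`, invisibly.
#' @export
validate_dataset <- function(ds) {
  stopifnot(inherits(ds, "clinical_dataset"))
  s <- ds$schema
  n <- nrow(ds$icd10)
  if (n < 0L) stop_config("dataset must have a nonnegative record count")
  if (nrow(ds$basic) != n || nrow(ds$keywords) != n ||
      nrow(ds$acupoints) != n || length(ds$tcm) != n)
    stop_config("feature groups disagree on record count")
  if (ncol(ds$icd10) != s$n_icd10 || ncol(ds$basic) != s$n_basic ||
      ncol(ds$keywords) != s$n_keywords || ncol(ds$acupoints) != s$n_acupoints)
    stop_config("feature group widths do not match the declared schema")
  bad <- function(what, rows) stop_config(
    "record %d: %s", rows[1L], what)
  for (grp in c("icd10", "keywords", "acupoints")) {
    m <- ds[[grp]]
    nb <- which(rowSums(m != 0 & m != 1) > 0)
    if (length(nb)) bad(sprintf("non-binary value in %s block", grp), nb)
  }
  pc <- rowSums(ds$icd10)
  off <- which(pc != 1L)
  if (length(off)) bad(sprintf("ICD-10 one-hot popcount is %d, expected 1",
                               pc[off[1L]]), off)
  if (any(!is.finite(ds$basic)))
    bad("non-finite basic-info value", which(rowSums(!is.finite(ds$basic)) > 0))
  unk <- which(!(ds$tcm %in% s$tcm_codes))
  if (length(unk)) bad(sprintf("unknown TCM diagnosis code '%s'", ds$tcm[unk[1L]]),
                       unk)
  invisible(ds)
}

#' @export
print.clinical_dataset <- function(x, ...) {
  s <- x$schema
  cat(sprintf(paste0("<clinical_dataset: %d records | %d ICD-10 labels, ",
                     "%d basic, %d keywords, %d acupoints, %d TCM codes>\n"),
              n_records(x), s$n_icd10, s$n_basic, s$n_keywords, s$n_acupoints,
              length(s$tcm_codes)))
  invisible(x)
}

#' Number of records in a clinical dataset
#' @param ds A `clinical_dataset`.
#' @export
n_records <- function(ds) nrow(ds$icd10)

#' Row subset of a clinical dataset
#' @param x A `clinical_dataset`.
#' @param i Record indices (may repeat, as in a bootstrap sample).
#' @param ... Unused.
#' @export
`[.clinical_dataset` <- function(x, i, ...) {
  structure(list(icd10 = x$icd10[i, , drop = FALSE],
                 basic = x$basic[i, , drop = FALSE],
                 keywords = x$keywords[i, , drop = FALSE],
                 acupoints = x$acupoints[i, , drop = FALSE],
                 tcm = x$tcm[i], schema = x$schema),
            class = "clinical_dataset")
}

#' Predictor matrix of a dataset (basic info + keyword features)
#' @param ds A `clinical_dataset`.
#' @return Numeric matrix with `n_basic + n_keywords` columns.
#' @export
feature_matrix <- function(ds) {
  cbind(ds$basic, ds$keywords)
}

#' Integer ICD-10 label index of each record (position of the one-hot flag)
#' @param ds A `clinical_dataset`.
#' @export
icd10_index <- function(ds) max.col(ds$icd10, ties.method = "first")

dataset_colnames <- function(s) {
  c(paste0("icd10_", seq_len(s$n_icd10) - 1L),
    paste0("basic_", seq_len(s$n_basic) - 1L),
    paste0("kw_", seq_len(s$n_keywords) - 1L),
    paste0("acu_", seq_len(s$n_acupoints) - 1L),
    "tcm_dx")
}

#' Write a clinical dataset to delimited text
#'
#' One record per row, comma separated, with a header naming the column
#' groups `icd10_*`, `basic_*`, `kw_*`, `acu_*`, `tcm_dx`. Basic-info reals
#' are written with 17 significant digits so that [read_dataset()]
#' round-trips bit-exactly; repeated writes of the same dataset are
#' byte-identical.
#'
#' @param ds A `clinical_dataset`.
#' @param path Output file path.
#' @export
write_dataset <- function(ds, path) {
  validate_dataset(ds)
  s <- ds$schema
  header <- paste(dataset_colnames(s), collapse = ",")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con)
  n <- n_records(ds)
  if (n > 0L) {
    basic_chr <- matrix(sprintf("%.17g", ds$basic), nrow = n)
    rows <- do.call(paste, c(
      lapply(seq_len(s$n_icd10), function(j) ds$icd10[, j]),
      lapply(seq_len(s$n_basic), function(j) basic_chr[, j]),
      lapply(seq_len(s$n_keywords), function(j) ds$keywords[, j]),
      lapply(seq_len(s$n_acupoints), function(j) ds$acupoints[, j]),
      list(ds$tcm, sep = ",")))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read a clinical dataset from delimited text
#'
#' Inverse of [write_dataset()]. Column groups are recovered from the
#' header; every row is validated (boolean blocks, single ICD-10 flag) with
#' errors naming the offending row.
#'
#' @param path Input file path.
#' @param schema Optional [clinical_schema()] the file must conform to.
#' @return A `clinical_dataset`.
#' @export
read_dataset <- function(path, schema = NULL) {
  df <- read.csv(path, check.names = FALSE, colClasses = NA,
                 stringsAsFactors = FALSE)
  nm <- names(df)
  grp <- function(p) grep(paste0("^", p, "_\\d+$"), nm)
  ic <- grp("icd10"); ba <- grp("basic"); kw <- grp("kw"); ac <- grp("acu")
  tc <- which(nm == "tcm_dx")
  if (!length(ic) || !length(ba) || !length(kw) || !length(ac) ||
      length(tc) != 1L)
    stop_config("file '%s' does not carry the clinical dataset column groups",
                path)
  tcm <- as.character(df[[tc]])
  s <- schema %||% clinical_schema(length(ic), length(ba), length(kw),
                                   length(ac),
                                   if (length(tcm)) sort(unique(tcm)) else "Z1")
  if (length(ic) != s$n_icd10 || length(ba) != s$n_basic ||
      length(kw) != s$n_keywords || length(ac) != s$n_acupoints)
    stop_config("column groups in '%s' do not match the declared schema", path)
  as_mat <- function(ix) {
    m <- as.matrix(df[ix])
    dimnames(m) <- NULL
    m
  }
  clinical_dataset(icd10 = as_mat(ic), basic = as_mat(ba),
                   keywords = as_mat(kw), acupoints = as_mat(ac),
                   tcm = tcm, schema = s)
}
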