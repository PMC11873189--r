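#' Declare column roles and types for a tabular cohort
#'
#' A schema maps the columns of a delimited cohort file onto their roles:
#' the patient identifier, the survival time (months), the event indicator
#' (1 = death observed, 0 = censored), and the input features with declared
#' types. Categorical codebooks and continuous standardization statistics are
#' learned from training data and stored on the schema so that evaluation
#' cohorts are encoded identically.
#'
#' @param id,time,event column names for the patient id, survival time and
#'   event indicator.
#' @param features named character vector: names are feature column names,
#'   values their types among `"continuous"`, `"binary"`, `"categorical"`.
#' @param codebooks optional named list (one per categorical feature) mapping
#'   category labels to ordinal codes `0..n-1`.
#' @param standardize named list (one per continuous feature) of `c(mean, sd)`
#'   used to z-score values; usually filled by [read_cohort()] on training
#'   data.
#' @return an object of class `ct_schema`.
#' @export
ct_schema <- function(id, time, event, features,
                      codebooks = list(), standardize = list()) {
  stopifnot(is.character(features), length(features) >= 1L,
            !is.null(names(features)))
  bad <- setdiff(unique(features), c("continuous", "binary", "categorical"))
  if (length(bad)) stopf("unknown feature type(s): %s", paste(bad, collapse = ", "))
  structure(list(id = id, time = time, event = event, features = features,
                 codebooks = codebooks, standardize = standardize),
            class = "ct_schema")
}

#' Read a tabular cohort file
#'
#' Reads a UTF-8 delimited file (comma or tab, autodetected from the header
#' line), validates outcome columns, ordinal-encodes categorical features per
#' the schema's codebooks (building them from the data when absent), and
#' optionally z-scores continuous features. Empty cells and `"NA"` are
#' missing: they become absent features, never sentinel values.
#'
#' @param path file path.
#' @param schema a [ct_schema()].
#' @param standardize one of `"fit"` (compute mean/sd from this file and store
#'   them on the schema — use for training data), `"apply"` (use the schema's
#'   stored statistics), or `"none"`.
#' @return an object of class `ct_cohort`: fields `id`, `time`, `event`,
#'   numeric feature matrix `tab` (NA = missing) and the (possibly updated)
#'   `schema`.
#' @export
read_cohort <- function(path, schema, standardize = c("none", "fit", "apply")) {
  standardize <- match.arg(standardize)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          na.strings = c("", "NA"), stringsAsFactors = FALSE,
                          check.names = FALSE, fileEncoding = "UTF-8")
  as_ct_cohort(df, schema, standardize)
}

#' Build a cohort from an in-memory data frame
#'
#' Same contract as [read_cohort()] but starting from a `data.frame`.
#' @param df data frame, one row per patient.
#' @inheritParams read_cohort
#' @export
as_ct_cohort <- function(df, schema, standardize = c("none", "fit", "apply")) {
  standardize <- match.arg(standardize)
  for (col in c(schema$time, schema$event))
    if (!col %in% names(df)) stopf("required column '%s' missing from cohort", col)
  if (!schema$id %in% names(df))
    df[[schema$id]] <- sprintf("P%04d", seq_len(nrow(df)))
  time <- as.numeric(df[[schema$time]])
  event <- df[[schema$event]]
  if (anyNA(time) || any(time < 0)) stopf("survival times must be nonnegative and non-missing")
  if (!all(event %in% c(0, 1))) stopf("event indicator must be 0 (censored) or 1 (death)")
  feats <- names(schema$features)
  missing_cols <- setdiff(feats, names(df))
  if (length(missing_cols)) stopf("feature column(s) missing: %s", paste(missing_cols, collapse = ", "))

  enc <- encode_categoricals(df[feats], schema)
  tab <- enc$tab
  schema <- enc$schema

  cont <- feats[schema$features == "continuous"]
  if (standardize == "fit") {
    schema$standardize <- lapply(stats::setNames(cont, cont), function(f) {
      c(mean = mean(tab[, f], na.rm = TRUE), sd = stats::sd(tab[, f], na.rm = TRUE))
    })
    standardize <- "apply"
  }
  if (standardize == "apply" && length(schema$standardize)) {
    for (f in intersect(cont, names(schema$standardize))) {
      st <- schema$standardize[[f]]
      s <- if (is.finite(st[["sd"]]) && st[["sd"]] > 0) st[["sd"]] else 1
      tab[, f] <- (tab[, f] - st[["mean"]]) / s
    }
  }
  structure(list(id = as.character(df[[schema$id]]), time = time,
                 event = as.integer(event), tab = tab, schema = schema),
            class = "ct_cohort")
}

#' Ordinal-encode categorical features
#'
#' Converts each categorical column to integer ordinals `0..n-1` using the
#' schema codebook; when no codebook exists one is built from the sorted
#' unique labels and stored (so the mapping is deterministic and serialized
#' with the schema). A label unseen at encoding time maps to the reserved
#' "unseen" ordinal `n` with a warning. Continuous and binary columns pass
#' through unchanged.
#'
#' @param df data frame restricted to feature columns.
#' @param schema a [ct_schema()] whose codebooks are fixed from training data
#'   (or empty, in which case they are fitted here).
#' @return list with numeric matrix `tab` and the updated `schema`.
#' @export
encode_categoricals <- function(df, schema) {
  feats <- names(schema$features)
  tab <- matrix(NA_real_, nrow(df), length(feats), dimnames = list(NULL, feats))
  for (f in feats) {
    x <- df[[f]]
    if (schema$features[[f]] == "categorical") {
      cb <- schema$codebooks[[f]]
      if (is.null(cb)) {
        lev <- sort(unique(stats::na.omit(as.character(x))))
        if (!length(lev)) stopf("categorical feature '%s' has no observed levels and no codebook", f)
        cb <- stats::setNames(seq_along(lev) - 1L, lev)
        schema$codebooks[[f]] <- cb
      }
      if (is.numeric(x) && all(is.na(x) | (x %in% c(seq_along(cb) - 1L, length(cb))))) {
        # already ordinal-encoded (e.g. re-reading a written cohort): pass through
        tab[, f] <- as.numeric(x)
        next
      }
      xi <- as.character(x)
      unseen <- !is.na(xi) & !(xi %in% names(cb))
      if (any(unseen)) {
        warnf("feature '%s': %d value(s) unseen in codebook mapped to reserved ordinal %d",
              f, sum(unseen), length(cb))
      }
      code <- unname(cb[xi])
      code[unseen] <- length(cb)
      tab[, f] <- as.numeric(code)
    } else {
      tab[, f] <- suppressWarnings(as.numeric(x))
    }
  }
  list(tab = tab, schema = schema)
}

#' Write a cohort back to a delimited file
#'
#' Inverse of [read_cohort()] for a fixed dialect: missing features become
#' empty cells; `read_cohort(write_cohort(x))` is value-identical.
#' @param cohort a `ct_cohort`.
#' @param path output path; extension `.tsv` selects tab, else comma.
#' @export
write_cohort <- function(cohort, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  df <- data.frame(id = cohort$id, time = cohort$time, event = cohort$event,
                   check.names = FALSE)
  names(df) <- c(cohort$schema$id, cohort$schema$time, cohort$schema$event)
  df <- cbind(df, as.data.frame(cohort$tab, check.names = FALSE))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.ct_cohort <- function(x, ...) {
  cat(sprintf("<ct_cohort> %d patients, %d features, %.0f%% events, %.0f%% missing cells\n",
              length(x$id), ncol(x$tab), 100 * mean(x$event),
              100 * mean(is.na(x$tab))))
  invisible(x)
}

#' Extract per-patient records as (name, value) pair sets
#'
#' Each record keeps only non-missing features, reflecting the key-value
#' input contract of the model.
#' @param cohort a `ct_cohort`.
#' @return list of records: `id`, named numeric `features`, `time`, `event`.
#' @export
as_records <- function(cohort) {
  lapply(seq_along(cohort$id), function(i) {
    v <- cohort$tab[i, ]
    list(id = cohort$id[i], features = v[!is.na(v)],
         time = cohort$time[i], event = cohort$event[i])
  })
}

#' Number of non-missing features per patient
#' @param cohort a `ct_cohort`.
#' @export
feature_counts <- function(cohort) rowSums(!is.na(cohort$tab))
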