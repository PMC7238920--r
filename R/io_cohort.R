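#' Default white-matter association tract bundle names
#'
#' The 22 bilateral association bundles commonly exported from tractography
#' atlases (11 pathways, left and right). This is a documented default naming
#' convention; tract names in a cohort file are free strings taken from its
#' column headers and nothing in the package depends on this particular list.
#'
#' @return Character vector of 22 tract names.
#' @export
#' @examples
#' association_tracts_22()
association_tracts_22 <- function() {
  base <- c(
    "arcuate", "cingulum", "extreme_capsule", "frontal_aslant",
    "inferior_fronto_occipital", "inferior_longitudinal",
    "middle_longitudinal", "parietal_aslant", "superior_longitudinal",
    "uncinate", "vertical_occipital"
  )
  as.vector(t(outer(c("left", "right"), base, paste, sep = "_")))
}

#' Construct and validate a cohort table
#'
#' The single ingestion container for all downstream analysis: one row per
#' subject with group label, age, one FA value per named tract, and optional
#' cognitive test scores.
#'
#' @param subjects data.frame with columns `subject_id`, `group`, `age`.
#' @param fa numeric matrix, subjects x tracts, with column names; no missing
#'   values allowed.
#' @param cognition optional numeric matrix, subjects x tests, with column
#'   names; missing scores are allowed.
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(subjects, fa, cognition = NULL) {
  stopifnot(is.data.frame(subjects),
            all(c("subject_id", "group", "age") %in% names(subjects)))
  subjects$subject_id <- as.character(subjects$subject_id)
  subjects$group <- as.character(subjects$group)
  fa <- as.matrix(fa)
  storage.mode(fa) <- "double"

  if (anyDuplicated(subjects$subject_id))
    stop("validation error: duplicate subject_id: ",
         paste(unique(subjects$subject_id[duplicated(subjects$subject_id)]),
               collapse = ", "))
  bad_group <- setdiff(unique(subjects$group), c("control", "patient"))
  if (length(bad_group))
    stop("validation error: group labels must be 'control' or 'patient'; saw: ",
         paste(bad_group, collapse = ", "))
  if (any(!is.finite(subjects$age)) || any(subjects$age <= 0))
    stop("validation error: age must be positive and finite for all subjects")
  if (nrow(fa) != nrow(subjects))
    stop("validation error: fa row count does not match subjects")
  if (is.null(colnames(fa)) || anyDuplicated(colnames(fa)))
    stop("validation error: fa must have unique tract column names")
  if (ncol(fa) < 1L)
    stop("validation error: at least 1 tract required")
  if (sum(subjects$group == "control") < 1L)
    stop("validation error: at least 1 control required")
  if (any(!is.finite(fa))) {
    bad <- which(!is.finite(fa), arr.ind = TRUE)[1L, ]
    stop(sprintf("parse error: missing/non-finite FA for subject '%s', tract '%s'",
                 subjects$subject_id[bad[1L]], colnames(fa)[bad[2L]]))
  }
  rownames(fa) <- subjects$subject_id
  if (!is.null(cognition)) {
    cognition <- as.matrix(cognition)
    storage.mode(cognition) <- "double"
    if (nrow(cognition) != nrow(subjects))
      stop("validation error: cognition row count does not match subjects")
    if (is.null(colnames(cognition)))
      stop("validation error: cognition must have test column names")
    rownames(cognition) <- subjects$subject_id
  }
  structure(
    list(subjects = subjects[c("subject_id", "group", "age")],
         fa = fa, cognition = cognition),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf(
    "cohort_table: %d subjects (%d controls, %d patients), %d tracts%s\n",
    nrow(x$subjects), sum(x$subjects$group == "control"),
    sum(x$subjects$group == "patient"), ncol(x$fa),
    if (is.null(x$cognition)) ""
    else sprintf(", %d cognitive tests", ncol(x$cognition))
  ))
  invisible(x)
}

#' Default column schema for cohort files
#'
#' Maps file columns to roles. `tracts`/`cognition` may be `NULL`, in which
#' case columns prefixed `fa_` are taken as tracts (prefix stripped) and
#' columns prefixed `cog_` as cognitive tests.
#'
#' @param id,group,age column names for the subject identifier, group label
#'   and age.
#' @param tracts,cognition explicit column-name vectors, or `NULL` for
#'   prefix-based detection.
#' @return A list usable as the `schema` argument of [read_cohort()].
#' @export
cohort_schema <- function(id = "subject_id", group = "group", age = "age",
                          tracts = NULL, cognition = NULL) {
  list(id = id, group = group, age = age, tracts = tracts,
       cognition = cognition)
}

#' Read a cohort table from CSV/TSV
#'
#' Reads a delimited per-subject table (period decimal separator, UTF-8;
#' comma-delimited for `.csv`, tab-delimited for `.tsv`/`.txt`) and validates
#' it into a [cohort_table()]. Tract column order in the file is preserved.
#'
#' @param path path to the file.
#' @param schema a [cohort_schema()] list, or a path to a JSON file holding
#'   one; `NULL` for the default schema.
#' @return A `cohort_table`.
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  if (is.null(schema)) schema <- cohort_schema()
  if (is.character(schema) && length(schema) == 1L) {
    schema <- utils::modifyList(cohort_schema(),
                                jsonlite::fromJSON(schema, simplifyVector = TRUE))
  }
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                           colClasses = "character", check.names = FALSE,
                           na.strings = NULL, fileEncoding = "UTF-8",
                           comment.char = "#")
  for (role in c("id", "group", "age")) {
    if (!schema[[role]] %in% names(raw))
      stop(sprintf("schema error: required column '%s' (role '%s') not found",
                   schema[[role]], role))
  }
  tract_cols <- schema$tracts
  if (is.null(tract_cols)) {
    tract_cols <- grep("^fa_", names(raw), value = TRUE)
    tract_names <- sub("^fa_", "", tract_cols)
  } else tract_names <- tract_cols
  missing_tracts <- setdiff(tract_cols, names(raw))
  if (length(missing_tracts))
    stop("schema error: tract column(s) not found: ",
         paste(missing_tracts, collapse = ", "))
  if (!length(tract_cols))
    stop("schema error: no tract columns found (expected 'fa_' prefix or explicit schema$tracts)")
  cog_cols <- schema$cognition
  if (is.null(cog_cols)) {
    cog_cols <- grep("^cog_", names(raw), value = TRUE)
    cog_names <- sub("^cog_", "", cog_cols)
  } else {
    missing_cog <- setdiff(cog_cols, names(raw))
    if (length(missing_cog))
      stop("schema error: cognition column(s) not found: ",
           paste(missing_cog, collapse = ", "))
    cog_names <- cog_cols
  }

  parse_numeric <- function(cols, labels, allow_na) {
    m <- matrix(NA_real_, nrow(raw), length(cols),
                dimnames = list(NULL, labels))
    for (j in seq_along(cols)) {
      v <- suppressWarnings(as.numeric(raw[[cols[j]]]))
      bad <- which(is.na(v) & !(allow_na & raw[[cols[j]]] %in% c("NA", "", "NaN")))
      if (length(bad))
        stop(sprintf("parse error: non-numeric value '%s' in column '%s', row %d",
                     raw[[cols[j]]][bad[1L]], cols[j], bad[1L]))
      m[, j] <- v
    }
    m
  }
  age <- suppressWarnings(as.numeric(raw[[schema$age]]))
  if (anyNA(age)) {
    bad <- which(is.na(age))[1L]
    stop(sprintf("parse error: non-numeric age '%s' in row %d",
                 raw[[schema$age]][bad], bad))
  }
  fa <- parse_numeric(tract_cols, tract_names, allow_na = FALSE)
  cognition <- if (length(cog_cols))
    parse_numeric(cog_cols, cog_names, allow_na = TRUE) else NULL
  cohort_table(
    subjects = data.frame(subject_id = raw[[schema$id]],
                          group = raw[[schema$group]], age = age,
                          stringsAsFactors = FALSE),
    fa = fa, cognition = cognition
  )
}

#' Write a result table with a metadata header
#'
#' Writes a data.frame as CSV preceded by a commented metadata block
#' (`# key: value` lines); numeric values are written at full precision so
#' that [read_results()] reproduces them exactly. Missing cells are written
#' as the sentinel `NA`.
#'
#' @param table a data.frame; all numeric cells finite or `NA`.
#' @param path output path.
#' @param metadata named list echoed into the header; a
#'   `software_version` entry is added automatically.
#' @export
write_results <- function(table, path, metadata = list()) {
  stopifnot(is.data.frame(table))
  num <- vapply(table, is.numeric, logical(1L))
  for (j in which(num)) {
    v <- table[[j]]
    if (any(!is.finite(v) & !is.na(v)))
      stop("validation error: non-finite, non-missing value in column ",
           names(table)[j])
  }
  metadata <- c(metadata, list(
    software_version = as.character(utils::packageVersion("famdist"))))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (k in names(metadata))
    writeLines(sprintf("# %s: %s", k, paste(format(metadata[[k]], digits = 17),
                                            collapse = " ")), con)
  utils::write.csv(format_df_full(table), con, row.names = FALSE, quote = FALSE,
                   na = "NA")
  invisible(path)
}

# full-precision character rendering so write/read round-trips exactly
format_df_full <- function(df) {
  as.data.frame(lapply(df, function(v) {
    if (is.double(v)) {
      out <- vapply(v, function(x)
        if (is.na(x)) NA_character_ else sprintf("%.17g", x), character(1L))
      out
    } else v
  }), check.names = FALSE, stringsAsFactors = FALSE)
}

#' Read a result table written by [write_results()]
#'
#' @param path file path.
#' @return data.frame with the metadata block attached as attribute
#'   `"metadata"` (named character list).
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop("I/O error: no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- grep("^#", lines)
  meta <- list()
  if (length(hdr)) {
    kv <- sub("^#\\s*", "", lines[hdr])
    keys <- sub(":.*$", "", kv)
    vals <- trimws(sub("^[^:]*:", "", kv))
    meta <- stats::setNames(as.list(vals), keys)
  }
  df <- utils::read.csv(text = paste(lines[setdiff(seq_along(lines), hdr)],
                                     collapse = "\n"),
                        check.names = FALSE, stringsAsFactors = FALSE)
  attr(df, "metadata") <- meta
  df
}
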