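#' Export / import a cohort table with a data dictionary
#'
#' The table goes to plain CSV; a companion JSON dictionary records each
#' column's type (`binary`, `continuous`, `ordinal`, `identifier`),
#' units and domain membership, so an externally supplied table can be
#' validated against the same schema.
#'
#' @param table cohort table.
#' @param path CSV path.
#' @param dictionary_path JSON dictionary path (default: `path` with a
#'   `.dict.json` suffix).
#' @param spec optional `cohort_spec` used to annotate units and domain
#'   membership.
#' @return invisibly, the dictionary (a data.frame).
#' @export
export_cohort <- function(table, path, dictionary_path = NULL, spec = NULL) {
  if (is.null(dictionary_path)) dictionary_path <- paste0(path, ".dict.json")
  dict <- build_dictionary(table, spec)
  utils::write.csv(table, path, row.names = FALSE, na = "")
  jsonlite::write_json(dict, dictionary_path, dataframe = "rows", digits = NA)
  invisible(dict)
}

build_dictionary <- function(table, spec = NULL) {
  domain_of <- units_of <- character(0)
  if (!is.null(spec)) {
    for (d in spec$domain_specs) {
      for (v in names(d$variables)) {
        domain_of[v] <- d$name
        u <- d$variables[[v]]$rule$units
        units_of[v] <- if (is.null(u)) "" else u
      }
    }
  }
  rows <- lapply(names(table), function(col) {
    x <- table[[col]]
    type <- if (col == "participant_id") {
      "identifier"
    } else if (is.numeric(x) && all(x %in% c(0, 1) | is.na(x))) {
      "binary"
    } else if (is.numeric(x) && all(x == round(x) | is.na(x)) &&
               length(unique(x[!is.na(x)])) <= 12) {
      "ordinal"
    } else if (is.numeric(x)) {
      "continuous"
    } else {
      "categorical"
    }
    data.frame(column = col, type = type,
               units = if (col %in% names(units_of)) units_of[[col]] else "",
               domain = if (col %in% names(domain_of)) domain_of[[col]] else "",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @rdname export_cohort
#' @export
import_cohort <- function(path, dictionary_path = NULL) {
  if (is.null(dictionary_path)) dictionary_path <- paste0(path, ".dict.json")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  if (file.exists(dictionary_path)) {
    dict <- jsonlite::read_json(dictionary_path, simplifyVector = TRUE)
    for (i in seq_len(nrow(dict))) {
      col <- dict$column[i]
      if (!col %in% names(tab)) next
      if (dict$type[i] %in% c("binary", "ordinal", "continuous")) {
        tab[[col]] <- as.numeric(tab[[col]])
      }
    }
  }
  tab
}

#' Validate an input CSV against its data dictionary
#'
#' Pure check, no mutation: every column must be declared, types must
#' match (binary columns only 0/1/missing, numeric columns numeric),
#' `participant_id` must be unique, and positive-valued variables (e.g.
#' birthweight) must be positive.
#'
#' @param path CSV path.
#' @param dictionary_path JSON dictionary path.
#' @return a `validation_report`: data.frame of violations (kind, column,
#'   row, detail); zero rows means the file passes.
#' @export
validate_input_csv <- function(path, dictionary_path = NULL) {
  if (!file.exists(path)) stop("validate_input_csv: cannot read ", path)
  if (is.null(dictionary_path)) dictionary_path <- paste0(path, ".dict.json")
  if (!file.exists(dictionary_path)) {
    stop("validate_input_csv: cannot read dictionary ", dictionary_path)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         na.strings = c("", "NA"))
  dict <- jsonlite::read_json(dictionary_path, simplifyVector = TRUE)
  v <- list()
  add <- function(kind, column, row = NA_integer_, detail = "") {
    v[[length(v) + 1L]] <<- data.frame(kind = kind, column = column,
                                       row = row, detail = detail,
                                       stringsAsFactors = FALSE)
  }
  for (col in setdiff(names(tab), dict$column)) {
    add("undeclared column", col)
  }
  for (col in setdiff(dict$column, names(tab))) {
    add("missing column", col)
  }
  for (i in seq_len(nrow(dict))) {
    col <- dict$column[i]
    if (!col %in% names(tab)) next
    x <- tab[[col]]
    if (dict$type[i] == "binary") {
      bad <- which(!is.na(x) & !(x %in% c(0, 1)))
      for (r in utils::head(bad, 20L)) {
        add("non-binary value", col, r, as.character(x[r]))
      }
    } else if (dict$type[i] %in% c("continuous", "ordinal")) {
      if (!is.numeric(x)) add("non-numeric column", col)
    }
    if (col == "birthweight") {
      bad <- which(!is.na(x) & x <= 0)
      for (r in utils::head(bad, 20L)) add("non-positive value", col, r)
    }
    if (col == "participant_id" && anyDuplicated(x)) {
      add("duplicate identifier", col,
          detail = paste(sum(duplicated(x)), "duplicates"))
    }
  }
  report <- if (length(v)) do.call(rbind, v) else
    data.frame(kind = character(0), column = character(0),
               row = integer(0), detail = character(0))
  class(report) <- c("validation_report", class(report))
  report
}

#' @export
print.validation_report <- function(x, ...) {
  if (!nrow(x)) {
    cat("<validation_report> 0 violations\n")
  } else {
    cat("<validation_report>", nrow(x), "violation(s)\n")
    print(as.data.frame(x))
  }
  invisible(x)
}

#' Persist an imputation set as numbered CSVs plus a manifest
#'
#' @param imputation_set result of [impute_chained()].
#' @param dir output directory (created).
#' @return invisibly, the manifest list.
#' @export
export_imputation_set <- function(imputation_set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (m in seq_len(imputation_set$M)) {
    utils::write.csv(imputation_set$tables[[m]],
                     file.path(dir, sprintf("imputed_%03d.csv", m)),
                     row.names = FALSE, na = "")
  }
  manifest <- list(M = imputation_set$M, cycles = imputation_set$cycles,
                   seed = imputation_set$seed,
                   missing_counts = as.list(colSums(imputation_set$original_na)),
                   dropped_rows = length(imputation_set$dropped_rows %||% integer(0)),
                   log = imputation_set$log)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
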