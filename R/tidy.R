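# Tidy long-format profile tables: one row per
# (subject_id, tract_name, node_id, metric) observation.

tidy_columns <- c("subject_id", "tract_name", "node_id", "metric", "value")

check_tidy <- function(table) {
  if (!is.data.frame(table))
    stop("profile table must be a data.frame")
  missing_cols <- setdiff(tidy_columns, names(table))
  if (length(missing_cols))
    stop("profile table lacks column(s): ", paste(missing_cols, collapse = ", "))
  key <- paste(table$subject_id, table$tract_name, table$node_id,
               table$metric, sep = "\r")
  dup <- duplicated(key)
  if (any(dup))
    stop("duplicate profile key(s): ",
         paste(utils::head(gsub("\r", "/", key[dup]), 3L), collapse = "; "))
  invisible(table)
}

#' Write a tidy long-format profile table to CSV
#'
#' Columns are exactly `subject_id,tract_name,node_id,metric,value`; rows
#' are sorted by (subject, tract, node, metric) so output is deterministic.
#'
#' @param table data.frame with the five tidy columns.
#' @param path destination CSV path.
#' @return the path, invisibly.
#' @export
write_tidy_csv <- function(table, path) {
  check_tidy(table)
  table <- table[tidy_columns]
  ord <- order(table$subject_id, table$tract_name, table$node_id,
               table$metric, method = "radix")
  table <- table[ord, ]
  utils::write.table(table, path, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tidy long-format profile table from CSV
#'
#' @param path CSV path as written by [write_tidy_csv()].
#' @return data.frame with columns
#'   `subject_id, tract_name, node_id, metric, value`.
#' @export
read_tidy_csv <- function(path) {
  table <- utils::read.csv(path, stringsAsFactors = FALSE,
                           colClasses = c(subject_id = "character",
                                          tract_name = "character",
                                          node_id = "integer",
                                          metric = "character",
                                          value = "numeric"))
  check_tidy(table)
  table
}

#' Pivot a tidy table to the wide per-subject layout
#'
#' One row per subject, one column per (tract, node, metric) feature named
#' `tract.metric.node`. Used by the machine-learning layer (imputation,
#' profile tensors).
#'
#' @param table tidy data.frame.
#' @return wide data.frame; first column `subject_id`.
#' @export
tidy_to_wide <- function(table) {
  check_tidy(table)
  feat <- sprintf("%s.%s.%03d", table$tract_name, table$metric, table$node_id)
  subjects <- sort(unique(table$subject_id))
  features <- sort(unique(feat))
  wide <- matrix(NA_real_, length(subjects), length(features),
                 dimnames = list(subjects, features))
  wide[cbind(match(table$subject_id, subjects), match(feat, features))] <-
    table$value
  data.frame(subject_id = subjects, wide, row.names = NULL,
             check.names = FALSE)
}
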