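#' Subject x epoch-budget accuracy table
#'
#' A complete grid of classification accuracies (percent) with subjects as
#' rows and epoch budgets as columns, tagged with the experimental group it
#' belongs to (`"control"` = fine-tuned from the pretrained network,
#' `"baseline"` = trained from scratch).
#'
#' @param values Numeric matrix, subjects x budgets, in `[0, 100]`.
#' @param subjects Row identifiers.
#' @param budgets Column budgets (training epochs).
#' @param group `"control"` or `"baseline"`.
#' @return An `accuracy_table` object.
#' @export
accuracy_table <- function(values, subjects, budgets, group) {
  values <- as.matrix(values)
  if (nrow(values) != length(subjects) || ncol(values) != length(budgets)) {
    stop("`values` must be subjects x budgets")
  }
  if (anyNA(values)) stop("accuracy table has missing cells")
  if (any(values < 0 | values > 100)) {
    stop("accuracies must lie in [0, 100]")
  }
  dimnames(values) <- list(as.character(subjects), as.character(budgets))
  structure(list(values = values,
                 subjects = as.character(subjects),
                 budgets = as.integer(budgets),
                 group = group),
            class = "accuracy_table")
}

#' @export
print.accuracy_table <- function(x, ...) {
  cat(sprintf("%s-group accuracy table (%d subjects x %d budgets)\n",
              x$group, nrow(x$values), ncol(x$values)))
  print(round(x$values, 2))
  invisible(x)
}

#' Read / write the accuracy-table CSV codec
#'
#' The layout mirrors the published tables: a header row of epoch budgets
#' and a first column of subject identifiers, one accuracy cell per subject
#' and budget.
#'
#' @param path CSV path.
#' @param group Group tag to attach on read.
#' @return `read_accuracy_table` returns an [accuracy_table()];
#'   `write_accuracy_table` invisibly returns the path.
#' @export
read_accuracy_table <- function(path, group = c("control", "baseline")) {
  group <- match.arg(group)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("accuracy CSV needs a subject column and budgets")
  budgets <- suppressWarnings(as.integer(names(df)[-1]))
  if (anyNA(budgets)) stop("budget columns must have integer headers")
  accuracy_table(as.matrix(df[, -1]), subjects = df[[1]],
                 budgets = budgets, group = group)
}

#' @param table An [accuracy_table()].
#' @rdname read_accuracy_table
#' @export
write_accuracy_table <- function(table, path) {
  stopifnot(inherits(table, "accuracy_table"))
  df <- data.frame(subject = table$subjects, check.names = FALSE)
  df[as.character(table$budgets)] <- as.data.frame(table$values,
                                                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-budget column means
#'
#' Arithmetic mean of each budget column. `rounded = TRUE` (default) rounds
#' half up to two decimals, the precision of the published tables.
#'
#' @param table An [accuracy_table()].
#' @param rounded Round half-up to 2 decimals?
#' @return Named numeric vector, one mean per budget.
#' @export
column_means <- function(table, rounded = TRUE) {
  stopifnot(inherits(table, "accuracy_table"))
  m <- colMeans(table$values)
  if (rounded) m <- round_half_up(m, 2)
  m
}

#' Maximum cell of an accuracy table
#' @param table An [accuracy_table()].
#' @export
table_max <- function(table) {
  stopifnot(inherits(table, "accuracy_table"))
  max(table$values)
}

#' Packaged reference accuracy tables
#'
#' Loads the published subject x budget accuracy tables shipped with the
#' package (control group = fine-tuned network, baseline group = scratch
#' network; 10 subjects, budgets 10-60). File integrity is checked against
#' the recorded checksums.
#'
#' @return List with `control` and `baseline` [accuracy_table()]s.
#' @export
reference_tables <- function() {
  files <- c(control = "table1_control.csv", baseline = "table2_baseline.csv")
  sums <- c(table1_control.csv = "8a401f9b771fc780401f4c07195ee5d8",
            table2_baseline.csv = "de891c60310d7641ae493792a66d9cb2")
  out <- lapply(names(files), function(g) {
    path <- system.file("extdata", files[[g]], package = "fnirstransfer",
                        mustWork = TRUE)
    got <- unname(tools::md5sum(path))
    if (!identical(got, unname(sums[files[[g]]]))) {
      stop("fixture checksum mismatch for ", files[[g]],
           "; packaged table is corrupted")
    }
    read_accuracy_table(path, group = g)
  })
  names(out) <- names(files)
  out
}
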