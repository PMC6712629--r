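#' Logical-relationship matrix
#'
#' The actions x subjects grid used to annotate seed language patterns: a
#' marked cell means the action is a plausible negative life event for
#' that subject (e.g. <parents:be_sick>). Each subject belongs to exactly
#' one life-domain category (family, love, school, work, social in the
#' canonical design).
#'
#' @param cells logical matrix, rows = actions, columns = subjects, with
#'   dimnames.
#' @param subject_category named character vector mapping every subject
#'   to its category.
#' @return An object of class `lr_matrix`.
#' @export
lr_matrix <- function(cells, subject_category) {
  stopifnot(is.matrix(cells), is.logical(cells))
  if (is.null(rownames(cells)) || is.null(colnames(cells)))
    stop("cells must have action rownames and subject colnames")
  if (anyDuplicated(rownames(cells))) stop("duplicate action labels")
  if (anyDuplicated(colnames(cells))) stop("duplicate subject labels")
  missing_cat <- setdiff(colnames(cells), names(subject_category))
  if (length(missing_cat))
    stop("subjects without a category: ", paste(missing_cat, collapse = ", "))
  subject_category <- subject_category[colnames(cells)]
  structure(list(cells = cells,
                 actions = rownames(cells),
                 subjects = colnames(cells),
                 subject_category = subject_category),
            class = "lr_matrix")
}

#' @export
print.lr_matrix <- function(x, ...) {
  cat(sprintf("<lr_matrix> %d actions x %d subjects, %d marked cells, %d categories\n",
              length(x$actions), length(x$subjects), sum(x$cells),
              length(unique(x$subject_category))))
  invisible(x)
}

#' Seed patterns of a logical-relationship matrix
#'
#' @param lr an [lr_matrix()].
#' @return data.frame with columns `subject`, `action`, `category`
#'   (category of the subject), one row per marked cell.
#' @export
seed_patterns <- function(lr) {
  stopifnot(inherits(lr, "lr_matrix"))
  idx <- which(lr$cells, arr.ind = TRUE)
  data.frame(subject = lr$subjects[idx[, "col"]],
             action = lr$actions[idx[, "row"]],
             category = unname(lr$subject_category[lr$subjects[idx[, "col"]]]),
             stringsAsFactors = FALSE)
}

#' Combine annotator matrices into a consensus matrix
#'
#' Several annotators each mark the same actions x subjects grid; a cell
#' enters the consensus when at least `threshold` annotators marked it.
#' The default threshold is the number of annotators, i.e. unanimous
#' agreement (with three annotators, a symbol count of 3).
#'
#' @param matrices list of [lr_matrix()] objects on identical axes.
#' @param threshold minimum number of marks, default `length(matrices)`.
#' @return The consensus [lr_matrix()].
#' @export
aggregate_annotations <- function(matrices, threshold = length(matrices)) {
  if (!is.list(matrices) || length(matrices) < 1L)
    stop("need at least one annotator matrix")
  ref <- matrices[[1L]]
  stopifnot(inherits(ref, "lr_matrix"))
  for (m in matrices[-1L]) {
    stopifnot(inherits(m, "lr_matrix"))
    bad_a <- c(setdiff(m$actions, ref$actions), setdiff(ref$actions, m$actions))
    bad_s <- c(setdiff(m$subjects, ref$subjects), setdiff(ref$subjects, m$subjects))
    if (length(bad_a) || length(bad_s) ||
        !identical(m$actions, ref$actions) || !identical(m$subjects, ref$subjects))
      stop("annotator axes differ; offending labels: ",
           paste(unique(c(bad_a, bad_s, "(ordering)")), collapse = ", "))
  }
  counts <- Reduce(`+`, lapply(matrices, function(m) 1L * m$cells))
  lr_matrix(counts >= threshold, ref$subject_category)
}

#' Read a logical-relationship matrix from TSV
#'
#' Format: first row the subject headers (first field empty), second row
#' the per-subject category labels (first field `category`), then one row
#' per action: action label followed by 1/0 cells.
#'
#' @param path TSV file path.
#' @return An [lr_matrix()].
#' @export
read_lr_matrix <- function(path) {
  if (!file.exists(path)) stop("cannot read LR matrix: ", path)
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character", fileEncoding = "UTF-8")
  if (nrow(raw) < 3L) stop("LR matrix file too short: ", path)
  subjects <- as.character(raw[1L, -1L])
  if (tolower(raw[2L, 1L]) != "category")
    stop("format error in ", path, " line 2: expected 'category' row")
  categories <- setNames(as.character(raw[2L, -1L]), subjects)
  body <- raw[-(1:2), , drop = FALSE]
  actions <- body[[1L]]
  vals <- as.matrix(body[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "integer")
  if (anyNA(vals))
    stop("format error in ", path, ": non 0/1 cell at data line ",
         which(rowSums(is.na(vals)) > 0)[1L] + 2L)
  cells <- vals == 1L
  dimnames(cells) <- list(actions, subjects)
  lr_matrix(cells, categories)
}

#' Write a logical-relationship matrix to TSV
#'
#' @param lr an [lr_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lr_matrix <- function(lr, path) {
  stopifnot(inherits(lr, "lr_matrix"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste(c("", lr$subjects), collapse = "\t"),
               paste(c("category", unname(lr$subject_category)), collapse = "\t"),
               vapply(seq_along(lr$actions), function(i) {
                 paste(c(lr$actions[i], as.integer(lr$cells[i, ])), collapse = "\t")
               }, character(1))),
             con, useBytes = TRUE)
  invisible(path)
}
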