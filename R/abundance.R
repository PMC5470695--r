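#' Construct an abundance matrix
#'
#' The basic container of every pipeline: a strictly numeric entity-by-sample
#' matrix of abundances (instrument intensities, quantification scores, or
#' `2^induction-factor` values) with unique entity and sample identifiers and
#' an optional group label per sample.
#'
#' @param values Numeric matrix, entities in rows and samples in columns.
#'   Row and column names are used as entity and sample identifiers when
#'   `entity_ids`/`sample_ids` are not given.
#' @param entity_ids Character vector of unique entity identifiers.
#' @param sample_ids Character vector of unique sample identifiers.
#' @param groups Named character vector mapping sample id to group label.
#'   Samples without a label default to `"unassigned"`.
#'
#' @return An object of class `abundance_matrix`: the numeric matrix with
#'   ids as dimnames and a `groups` attribute.
#' @export
abundance_matrix <- function(values, entity_ids = rownames(values),
                             sample_ids = colnames(values), groups = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) {
    stop("abundance values must be numeric", call. = FALSE)
  }
  if (is.null(entity_ids)) entity_ids <- paste0("entity", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(ncol(values)))
  entity_ids <- as.character(entity_ids)
  sample_ids <- as.character(sample_ids)
  if (length(entity_ids) != nrow(values) || length(sample_ids) != ncol(values)) {
    stop("id lengths do not match matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(entity_ids)) {
    stop("duplicate entity ids: ",
         paste(unique(entity_ids[duplicated(entity_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  dimnames(values) <- list(entity_ids, sample_ids)
  grp <- rep("unassigned", length(sample_ids))
  names(grp) <- sample_ids
  if (!is.null(groups)) {
    if (is.null(names(groups))) {
      if (length(groups) != length(sample_ids)) {
        stop("unnamed `groups` must have one label per sample", call. = FALSE)
      }
      names(groups) <- sample_ids
    }
    unknown <- setdiff(names(groups), sample_ids)
    if (length(unknown)) {
      stop("group labels given for unknown samples: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    grp[names(groups)] <- as.character(groups)
  }
  structure(values, groups = grp, class = c("abundance_matrix", "matrix", "array"))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d entities x %d samples\n", nrow(x), ncol(x)))
  grp <- sample_groups(x)
  tab <- table(grp)
  cat("groups:", paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Sample group labels of an abundance matrix
#'
#' @param m An `abundance_matrix`.
#' @return Named character vector, one group label per sample.
#' @export
sample_groups <- function(m) {
  grp <- attr(m, "groups")
  if (is.null(grp)) {
    grp <- rep("unassigned", ncol(m))
    names(grp) <- colnames(m)
  }
  grp
}

#' Assign sample group labels
#'
#' Labels come either from a named character vector or from a two-column
#' delimited file `sample_id<TAB>group` (no header required; a header line
#' whose first field is `sample_id` is skipped).
#'
#' @param m An `abundance_matrix`.
#' @param groups Named character vector, or ignored when `file` is given.
#' @param file Path of a two-column sample/group table.
#' @param delimiter Field delimiter of `file`.
#' @return The matrix with updated group labels.
#' @export
assign_groups <- function(m, groups = NULL, file = NULL, delimiter = "\t") {
  if (!is.null(file)) {
    tab <- utils::read.table(file, sep = delimiter, header = FALSE,
                             colClasses = "character", quote = "",
                             comment.char = "", stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop("samples file must have two columns", call. = FALSE)
    if (nrow(tab) && identical(tolower(tab[1, 1]), "sample_id")) {
      tab <- tab[-1, , drop = FALSE]
    }
    groups <- stats::setNames(tab[[2]], tab[[1]])
  }
  abundance_matrix(unclass_matrix(m), groups = groups)
}

unclass_matrix <- function(m) {
  v <- as.matrix(m)
  attr(v, "groups") <- NULL
  class(v) <- NULL
  dimnames(v) <- dimnames(m)
  v
}

#' Read an entity-by-sample abundance matrix from delimited text
#'
#' Expects a UTF-8 file whose first row is a header (`id`, then the sample
#' labels) and whose first column holds entity identifiers. Missing values
#' may be encoded as empty cells or `NA`. The `pow2` transform maps each
#' cell `x` to `2^x`, converting log2-scale induction factors into positive
#' abundances before any downstream filtering.
#'
#' @param path File to read.
#' @param delimiter Field delimiter, default tab.
#' @param transform `"none"` or `"pow2"`.
#' @param groups Optional named character vector of sample group labels, or a
#'   path passed on to [assign_groups()] via `groups_file`.
#' @param groups_file Optional two-column sample/group file.
#' @return An [abundance_matrix()].
#' @export
read_matrix <- function(path, delimiter = "\t", transform = c("none", "pow2"),
                        groups = NULL, groups_file = NULL) {
  transform <- match.arg(transform)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, sep = delimiter, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 2) {
    stop("matrix file needs an id column and at least one sample column",
         call. = FALSE)
  }
  entity_ids <- raw[[1]]
  sample_ids <- colnames(raw)[-1]
  if (anyDuplicated(entity_ids)) {
    stop("format error: duplicate entity ids: ",
         paste(unique(entity_ids[duplicated(entity_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("format error: duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  cells <- as.matrix(raw[, -1, drop = FALSE])
  cells[!nzchar(trimws(cells))] <- NA_character_
  values <- suppressWarnings(
    matrix(as.numeric(cells), nrow = nrow(cells), ncol = ncol(cells)))
  bad <- which(is.na(values) & !is.na(cells) & toupper(trimws(cells)) != "NA",
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "parse error: non-numeric cell '%s' at row %d (entity '%s'), column '%s'",
      cells[bad[1, 1], bad[1, 2]], bad[1, 1], entity_ids[bad[1, 1]],
      sample_ids[bad[1, 2]]), call. = FALSE)
  }
  if (transform == "pow2") values <- 2^values
  abundance_matrix(values, entity_ids = entity_ids, sample_ids = sample_ids,
                   groups = groups) |>
    (\(m) if (is.null(groups_file)) m else assign_groups(m, file = groups_file))()
}

#' Keep only entities observed in every sample
#'
#' Downstream ranking and valuation require a complete, strictly positive
#' matrix, so entities with any missing, non-finite, zero or negative value
#' are dropped (mirroring the usual "observable in each sample" rule used
#' when quantification or identification can fail per run).
#'
#' @param m An [abundance_matrix()].
#' @return The filtered matrix. The dropped entities, with reasons, are
#'   attached as a data frame in the `"dropped"` attribute (empty when the
#'   input is already complete).
#' @export
filter_complete <- function(m) {
  stopifnot(inherits(m, "abundance_matrix"))
  v <- unclass_matrix(m)
  missing_any <- apply(v, 1L, function(r) any(is.na(r) | !is.finite(r)))
  nonpos_any <- apply(v, 1L, function(r) any(!is.na(r) & is.finite(r) & r <= 0))
  keep <- !missing_any & !nonpos_any
  if (!any(keep)) {
    stop("empty result: no entity is present and positive in every sample",
         call. = FALSE)
  }
  reason <- ifelse(missing_any, "missing value",
                   ifelse(nonpos_any, "non-positive value", ""))
  dropped <- data.frame(entity_id = rownames(v)[!keep],
                        reason = reason[!keep],
                        stringsAsFactors = FALSE)
  out <- abundance_matrix(v[keep, , drop = FALSE], groups = sample_groups(m))
  attr(out, "dropped") <- dropped
  out
}

#' Write a tabular result as delimited text
#'
#' Numeric cells are rendered with 17 significant digits so that a
#' write/read round trip reproduces double-precision values exactly.
#'
#' @param obj Matrix or data frame. Matrices are written with an `id` column
#'   from their row names.
#' @param path Output file.
#' @param delimiter Field delimiter, default tab.
#' @return Invisibly, `path`.
#' @export
write_table <- function(obj, path, delimiter = "\t") {
  if (is.matrix(obj)) {
    df <- data.frame(id = rownames(obj) %||% as.character(seq_len(nrow(obj))),
                     as.data.frame(unclass_matrix(obj)),
                     check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(obj, stringsAsFactors = FALSE)
  }
  fmt <- lapply(df, function(col) {
    if (is.double(col)) sprintf("%.17g", col) else as.character(col)
  })
  out <- as.data.frame(fmt, check.names = FALSE, stringsAsFactors = FALSE)
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) stop("cannot write to ", path, call. = FALSE))
  on.exit(close(con))
  utils::write.table(out, con, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
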