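#' Assemble a pairwise group dataset
#'
#' Stacks the compressed vectors of two groups into a subjects x columns
#' matrix with binary labels (`0` for `group_a`, `1` for `group_b`;
#' convention: pass the more-affected group second, so label 1 is the
#' "positive", more-affected class). With the balanced 7 + 7 design and
#' 19-channel recordings this is the 14 x 8170 matrix the classifiers see.
#'
#' @param vectors List of [compress_cube()] results (any groups; others are
#'   excluded).
#' @param group_a,group_b Group labels to contrast.
#' @return An object of class `pairwise_dataset`: list with `pair`, `X`,
#'   `y`, `subject_ids`, `column_names`, and `normalization`
#'   (`NULL` until [minmax_normalize()]).
#' @export
build_pairwise <- function(vectors, group_a, group_b) {
  groups <- vapply(vectors, `[[`, "", "group")
  sel <- vectors[groups %in% c(group_a, group_b)]
  sel <- c(sel[vapply(sel, `[[`, "", "group") == group_a],
           sel[vapply(sel, `[[`, "", "group") == group_b])
  if (!any(vapply(sel, `[[`, "", "group") == group_a) ||
      !any(vapply(sel, `[[`, "", "group") == group_b)) {
    stop("both groups need at least one subject (", group_a, " vs ", group_b, ")")
  }
  ids <- vapply(sel, `[[`, "", "subject_id")
  if (anyDuplicated(ids)) stop("duplicate subject_id across groups: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  cols <- sel[[1]]$column_names
  for (v in sel) {
    if (!identical(v$column_names, cols)) stop("inconsistent column sets")
  }
  X <- do.call(rbind, lapply(sel, function(v) v$values))
  rownames(X) <- ids
  y <- as.integer(vapply(sel, `[[`, "", "group") == group_b)
  structure(list(pair = c(group_a, group_b), X = X, y = y,
                 subject_ids = ids, column_names = cols,
                 normalization = NULL),
            class = "pairwise_dataset")
}

#' @export
print.pairwise_dataset <- function(x, ...) {
  cat(sprintf("<pairwise_dataset> %s vs %s: %d x %d (%s)\n",
              x$pair[1], x$pair[2], nrow(x$X), ncol(x$X),
              if (is.null(x$normalization)) "raw" else "min-max normalized"))
  invisible(x)
}

#' Min-max normalize a pairwise dataset
#'
#' Maps every column to `[0, 1]` by `(x - min) / (max - min)` computed over
#' all subjects of the pair (the per-column extrema are stored for audit).
#' Constant columns map to 0 with a diagnostic and are kept, preserving the
#' column contract. Note the extrema are taken over the full matrix before
#' cross-validation, which leaks fold statistics; normalization inside CV
#' training folds is available via `run_cv(normalize_within_folds = TRUE)`.
#'
#' @param ds A [build_pairwise()] result.
#' @return The normalized `pairwise_dataset` (idempotent on non-constant
#'   columns).
#' @export
minmax_normalize <- function(ds) {
  stopifnot(inherits(ds, "pairwise_dataset"))
  lo <- apply(ds$X, 2, min)
  hi <- apply(ds$X, 2, max)
  rng <- hi - lo
  const <- rng == 0
  if (any(const)) {
    adeeg_diag(sum(const), " constant column(s) mapped to 0 in min-max normalization")
    rng[const] <- 1
  }
  ds$X <- sweep(sweep(ds$X, 2, lo), 2, rng, "/")
  ds$X[, const] <- 0
  ds$normalization <- list(min = lo, max = hi)
  ds
}

#' Write the min-max normalization audit as JSON
#'
#' @param ds A normalized [minmax_normalize()] dataset.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_normalization_audit <- function(ds, path) {
  if (is.null(ds$normalization)) stop("dataset is not normalized")
  jsonlite::write_json(
    list(pair = ds$pair,
         columns = ds$column_names,
         min = ds$normalization$min,
         max = ds$normalization$max),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
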