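# SILAC TRAPP time-course analysis: protein-level log2(stress/control)
# ratio matrices, confidence and replicate-presence filtering, median
# aggregation, 2-fold change classification, and PCA.

#' Build a SILAC ratio matrix from long-format ratio tables
#'
#' Input rows carry protein, condition, time_min, replicate, log2_ratio and
#' peptides (the search-engine peptide count). Measurements from proteins
#' identified with fewer than `min_peptides` peptides are dropped (the
#' high-confidence filter); duplicate (protein, condition, time, replicate)
#' cells are an error.
#'
#' @param tables data.frame (or list of data.frames rbind-ed together).
#' @param min_peptides minimum peptide count (default 2).
#' @return a `silac_matrix`: long data.frame of retained measurements.
#' @export
build_silac_matrix <- function(tables, min_peptides = 2) {
  if (is.list(tables) && !is.data.frame(tables))
    tables <- do.call(rbind, tables)
  need <- c("protein", "condition", "time_min", "replicate", "log2_ratio",
            "peptides")
  if (!all(need %in% names(tables)))
    stopf("ratio tables need columns: %s", paste(need, collapse = ", "))
  key <- paste(tables$protein, tables$condition, tables$time_min,
               tables$replicate)
  if (anyDuplicated(key))
    stopf("duplicate (protein, condition, time, replicate) entries")
  if (any(!is.finite(tables$log2_ratio)))
    stopf("log2 ratios must be finite")
  out <- tables[tables$peptides >= min_peptides, need]
  rownames(out) <- NULL
  class(out) <- c("silac_matrix", "data.frame")
  out
}

#' Replicate-presence filtering
#'
#' Keeps a protein iff it has at least `min_replicates` non-missing
#' measurements at *every* (condition, time point) in scope -- the
#' "expressed in at least two replicates for every time point" rule.
#'
#' @param mat a `silac_matrix`.
#' @param min_replicates minimum replicates per scoped cell.
#' @param scope data.frame with `condition` and `time_min` columns; default
#'   all (condition, time) pairs present in the data.
#' @return the filtered `silac_matrix`.
#' @export
filter_presence <- function(mat, min_replicates = 2, scope = NULL) {
  if (is.null(scope))
    scope <- unique(mat[, c("condition", "time_min")])
  if (nrow(scope) == 0) stopf("empty scope")
  cell <- paste(mat$condition, mat$time_min)
  scoped <- mat[cell %in% paste(scope$condition, scope$time_min), ]
  tab <- table(scoped$protein, paste(scoped$condition, scoped$time_min))
  ok <- apply(tab >= min_replicates, 1, all) & ncol(tab) == nrow(scope)
  complete <- rownames(tab)[ok]
  out <- mat[mat$protein %in% complete, ]
  rownames(out) <- NULL
  class(out) <- c("silac_matrix", "data.frame")
  out
}

#' Median aggregation over replicates
#'
#' @param mat a `silac_matrix` (typically after [filter_presence()]).
#' @return numeric matrix proteins x (condition, time) cells, entries the
#'   per-cell median over non-missing replicates (NA where a protein was
#'   never measured in a cell). Column names are `condition_time`.
#' @export
aggregate_replicates <- function(mat) {
  cell <- paste(mat$condition, mat$time_min, sep = "_")
  cells <- unique(cell[order(mat$condition, mat$time_min)])
  proteins <- sort(unique(mat$protein))
  med <- tapply(mat$log2_ratio, list(factor(mat$protein, proteins),
                                     factor(cell, cells)), stats::median)
  out <- med[, cells, drop = FALSE]
  storage.mode(out) <- "numeric"
  out
}

#' Classify proteins by fold change at one time point
#'
#' Splits proteins into increased (`value > log2(fold_threshold)`) and
#' decreased (`value < -log2(fold_threshold)`) RNA association; the
#' inequality is strict ("greater than 2-fold"), so a protein at exactly
#' the threshold is unclassified.
#'
#' @param aggregated matrix from [aggregate_replicates()].
#' @param condition condition label.
#' @param time_min time point (default 16).
#' @param fold_threshold fold-change threshold (> 1; default 2).
#' @return list with `increased` and `decreased` protein id vectors.
#' @export
classify_changes <- function(aggregated, condition, time_min = 16,
                             fold_threshold = 2) {
  if (fold_threshold <= 1) stopf("fold_threshold must be > 1")
  col <- paste(condition, time_min, sep = "_")
  if (!col %in% colnames(aggregated))
    stopf("no column for condition '%s' at %s min", condition, time_min)
  v <- aggregated[, col]
  thr <- log2(fold_threshold)
  list(increased = rownames(aggregated)[!is.na(v) & v > thr],
       decreased = rownames(aggregated)[!is.na(v) & v < -thr])
}

#' Principal component analysis of an aggregated ratio matrix
#'
#' Complete cases only (proteins measured in every cell; no imputation).
#' Columns of the observation matrix are mean-centred but not scaled (raw
#' log2 ratios are already on a common scale), then decomposed by SVD.
#' `orientation = "samples"` treats the (condition, time) cells as
#' observations and proteins as variables; `"proteins"` is the transpose.
#' Sign convention: the largest-magnitude loading of each component is
#' positive.
#'
#' @param aggregated numeric matrix proteins x cells, no missing values.
#' @param orientation `"samples"` or `"proteins"`.
#' @return list with `scores` (observations x components), `loadings`
#'   (variables x components), `explained_variance` (fractions).
#' @export
run_pca <- function(aggregated, orientation = c("samples", "proteins")) {
  orientation <- match.arg(orientation)
  if (anyNA(aggregated))
    stopf("missing values: apply complete-case filtering first")
  x <- if (orientation == "samples") t(aggregated) else aggregated
  if (nrow(x) < 2 || ncol(x) < 2) stopf("need at least a 2 x 2 matrix")
  x <- scale(x, center = TRUE, scale = FALSE)
  sv <- svd(x)
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  loadings <- sv$v
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(x)
  rownames(loadings) <- colnames(x)
  ev <- sv$d^2 / sum(sv$d^2)
  list(scores = scores, loadings = loadings, explained_variance = ev)
}
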