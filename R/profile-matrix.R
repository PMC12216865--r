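#' Construct a ProfileMatrix
#'
#' @param values numeric matrix, one row per profile (replicate or sample),
#'   one column per feature; no missing values.
#' @param compoundIds character vector, compound of each row.
#' @param modality `"CP"` or `"TX"`.
#' @param rowIds profile identifiers (default: rownames of `values`, or
#'   generated).
#' @param featureNames feature identifiers (default: colnames of `values`,
#'   or generated).
#' @return a validated [ProfileMatrix-class].
#' @examples
#' v <- matrix(rnorm(6), 3, 2)
#' pm <- ProfileMatrix(v, compoundIds = c("a", "a", "b"), modality = "CP")
#' profileValues(pm)
#' @export
ProfileMatrix <- function(values, compoundIds, modality = c("CP", "TX"),
                          rowIds = NULL, featureNames = NULL) {
  modality <- match.arg(modality)
  .assert(is.matrix(values) && is.numeric(values),
          "'values' must be a numeric matrix")
  .assert(length(compoundIds) == nrow(values),
          "'compoundIds' must have one entry per row of 'values'")
  if (is.null(rowIds)) rowIds <- rownames(values)
  if (is.null(rowIds)) {
    rowIds <- if (modality == "TX") as.character(compoundIds)
              else sprintf("%s_r%d", compoundIds,
                           stats::ave(seq_along(compoundIds),
                                      as.character(compoundIds),
                                      FUN = seq_along))
  }
  if (is.null(featureNames)) featureNames <- colnames(values)
  if (is.null(featureNames))
    featureNames <- sprintf("f%04d", seq_len(ncol(values)))
  a <- t(values)
  dimnames(a) <- list(featureNames, rowIds)
  se <- SummarizedExperiment(
    assays = list(profile = a),
    colData = DataFrame(compound_id = as.character(compoundIds),
                        row.names = rowIds)
  )
  new("ProfileMatrix", se, modality = modality)
}

#' @rdname profileValues
#' @export
setMethod("profileValues", "ProfileMatrix", function(x) {
  t(assay(x, "profile"))
})

#' @rdname compoundIds
#' @export
setMethod("compoundIds", "ProfileMatrix", function(x) {
  stats::setNames(as.character(colData(x)$compound_id), colnames(x))
})

#' @rdname modality
#' @export
setMethod("modality", "ProfileMatrix", function(x) x@modality)

#' @export
setMethod("show", "ProfileMatrix", function(object) {
  cat(sprintf("ProfileMatrix (%s): %d profiles x %d features, %d compounds\n",
              object@modality, ncol(object), nrow(object),
              length(unique(colData(object)$compound_id))))
})

#' Read a profile matrix from a wide CSV/TSV file
#'
#' Expected layout: columns `row_id`, `compound_id`, then one numeric
#' column per feature (Z-scores).
#'
#' @param path file path (any delimiter `data.table::fread` detects).
#' @param modality `"CP"` or `"TX"`; TX uniqueness per compound is
#'   enforced.
#' @return a validated [ProfileMatrix-class].
#' @seealso [writeProfileMatrix()]
#' @export
readProfileMatrix <- function(path, modality = c("CP", "TX")) {
  modality <- match.arg(modality)
  .assert(file.exists(path), "file not found: ", path)
  dt <- data.table::fread(path, colClasses = list(character = 1:2))
  .assert(all(c("row_id", "compound_id") %in% colnames(dt)),
          "file must contain 'row_id' and 'compound_id' columns")
  feat <- setdiff(colnames(dt), c("row_id", "compound_id"))
  .assert(length(feat) > 0, "no feature columns found")
  vals <- as.matrix(dt[, feat, with = FALSE])
  .assert(is.numeric(vals), "feature columns must all be numeric")
  ProfileMatrix(vals, compoundIds = dt$compound_id, modality = modality,
                rowIds = dt$row_id, featureNames = feat)
}

#' Write a profile matrix to a wide CSV file
#'
#' @param x a [ProfileMatrix-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readProfileMatrix()]
#' @export
writeProfileMatrix <- function(x, path) {
  v <- profileValues(x)
  dt <- data.table::data.table(row_id = rownames(v),
                               compound_id = unname(compoundIds(x)))
  dt <- cbind(dt, data.table::as.data.table(v))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname aggregateReplicates
#' @export
setMethod("aggregateReplicates", "ProfileMatrix",
  function(x, method = c("median", "mean")) {
    method <- match.arg(method)
    .assert(modality(x) == "CP", "aggregation applies to CP profiles")
    v <- profileValues(x)
    out <- rowGroupAggregate(v, compoundIds(x), method = method)
    ProfileMatrix(out, compoundIds = rownames(out), modality = "CP",
                  rowIds = rownames(out), featureNames = colnames(out))
  })
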