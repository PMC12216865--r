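#' Construct a BioactivityMatrix
#'
#' @param labels numeric matrix of 0/1/NA entries; rownames are compound
#'   identifiers, colnames task identifiers.
#' @param family optional named character vector mapping task identifiers
#'   to protein target families.
#' @return a validated [BioactivityMatrix-class].
#' @export
BioactivityMatrix <- function(labels, family = character()) {
  .assert(is.matrix(labels), "'labels' must be a matrix")
  storage.mode(labels) <- "double"
  new("BioactivityMatrix", labels = labels,
      family = if (length(family)) family else character())
}

#' Label matrix of a BioactivityMatrix
#'
#' @param x a [BioactivityMatrix-class].
#' @return compound-by-task matrix in \{0, 1, NA\}.
#' @export
bioactivityLabels <- function(x) {
  .assert(is(x, "BioactivityMatrix"), "'x' must be a BioactivityMatrix")
  x@labels
}

#' Protein-family annotation of tasks
#'
#' @param x a [BioactivityMatrix-class].
#' @return named character vector (possibly empty).
#' @export
taskFamily <- function(x) {
  .assert(is(x, "BioactivityMatrix"), "'x' must be a BioactivityMatrix")
  x@family
}

#' @export
setMethod("show", "BioactivityMatrix", function(object) {
  lab <- object@labels
  obs <- sum(!is.na(lab))
  cat(sprintf(
    "BioactivityMatrix: %d compounds x %d tasks, %d observed labels (%.1f%% density, %.1f%% positive)\n",
    nrow(lab), ncol(lab), obs, 100 * obs / length(lab),
    100 * mean(lab, na.rm = TRUE)))
})

#' Read bioactivity labels from a sparse triplet CSV
#'
#' Expected columns: `compound_id`, `task_id`, `label` (0/1). Unobserved
#' (compound, task) combinations become `NA`. An optional task-annotation
#' CSV with columns `task_id`, `family` attaches protein-family labels.
#'
#' @param path triplet CSV path.
#' @param familyPath optional task-annotation CSV path.
#' @return a [BioactivityMatrix-class].
#' @seealso [writeBioactivityMatrix()]
#' @export
readBioactivityMatrix <- function(path, familyPath = NULL) {
  dt <- data.table::fread(path,
                          colClasses = list(character = c("compound_id",
                                                          "task_id")))
  .assert(all(c("compound_id", "task_id", "label") %in% colnames(dt)),
          "triplet file needs columns compound_id, task_id, label")
  cmp <- unique(dt$compound_id)
  tsk <- unique(dt$task_id)
  lab <- matrix(NA_real_, length(cmp), length(tsk),
                dimnames = list(cmp, tsk))
  lab[cbind(match(dt$compound_id, cmp), match(dt$task_id, tsk))] <- dt$label
  fam <- character()
  if (!is.null(familyPath)) {
    fd <- data.table::fread(familyPath, colClasses = "character")
    .assert(all(c("task_id", "family") %in% colnames(fd)),
            "family file needs columns task_id, family")
    fam <- stats::setNames(fd$family, fd$task_id)
    fam <- fam[names(fam) %in% tsk]
  }
  BioactivityMatrix(lab, family = fam)
}

#' Write bioactivity labels as a sparse triplet CSV
#'
#' @param x a [BioactivityMatrix-class].
#' @param path triplet CSV path (observed entries only).
#' @param familyPath optional path for the task-annotation CSV.
#' @return `path`, invisibly.
#' @export
writeBioactivityMatrix <- function(x, path, familyPath = NULL) {
  lab <- bioactivityLabels(x)
  idx <- which(!is.na(lab), arr.ind = TRUE)
  data.table::fwrite(data.table::data.table(
    compound_id = rownames(lab)[idx[, 1]],
    task_id = colnames(lab)[idx[, 2]],
    label = lab[idx]), path)
  if (!is.null(familyPath) && length(taskFamily(x)))
    data.table::fwrite(data.table::data.table(
      task_id = names(taskFamily(x)),
      family = unname(taskFamily(x))), familyPath)
  invisible(path)
}
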