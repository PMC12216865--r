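#' Build (CP replicate, TX) pretraining pairs
#'
#' Matches every Cell Painting replicate to its compound's single
#' transcriptomics profile. Compounds present in only one modality are
#' dropped (counts are reported via `message` and stored on the result).
#'
#' @param cp CP [ProfileMatrix-class].
#' @param tx TX [ProfileMatrix-class].
#' @return a [PairSet-class]; the number of pairs equals the number of CP
#'   replicates whose compound has a TX profile.
#' @examples
#' cp <- ProfileMatrix(matrix(rnorm(8), 4, 2),
#'                     compoundIds = c("a", "a", "a", "b"), modality = "CP")
#' tx <- ProfileMatrix(matrix(rnorm(4), 2, 2),
#'                     compoundIds = c("a", "c"), modality = "TX")
#' length(buildPairs(cp, tx))  # 3 replicates of compound "a"
#' @export
buildPairs <- function(cp, tx) {
  .assert(is(cp, "ProfileMatrix") && modality(cp) == "CP",
          "'cp' must be a CP ProfileMatrix")
  .assert(is(tx, "ProfileMatrix") && modality(tx) == "TX",
          "'tx' must be a TX ProfileMatrix")
  cpc <- compoundIds(cp)
  txc <- compoundIds(tx)
  common <- intersect(unique(cpc), txc)
  .assert(length(common) > 0, "no compound is present in both modalities")
  keep <- cpc %in% common
  nDropCp <- sum(!keep)
  nDropTx <- sum(!txc %in% common)
  if (nDropCp > 0 || nDropTx > 0)
    message(sprintf(
      "buildPairs: dropped %d CP replicate(s) and %d TX profile(s) lacking the other modality",
      nDropCp, nDropTx))
  new("PairSet",
      pairs = data.frame(cp_row_id = names(cpc)[keep],
                         compound_id = unname(cpc[keep]),
                         stringsAsFactors = FALSE),
      nDroppedCp = as.integer(nDropCp), nDroppedTx = as.integer(nDropTx))
}

#' @describeIn PairSet number of (CP, TX) pairs.
#' @param x a `PairSet`.
#' @export
setMethod("length", "PairSet", function(x) nrow(x@pairs))

#' Pairs as a data.frame
#'
#' @param x a [PairSet-class].
#' @return `data.frame` with columns `cp_row_id`, `compound_id`.
#' @export
pairTable <- function(x) {
  .assert(is(x, "PairSet"), "'x' must be a PairSet")
  x@pairs
}

#' @export
setMethod("show", "PairSet", function(object) {
  cat(sprintf("PairSet: %d (CP replicate, TX) pairs over %d compounds\n",
              nrow(object@pairs), length(unique(object@pairs$compound_id))))
  if (object@nDroppedCp > 0 || object@nDroppedTx > 0)
    cat(sprintf("  dropped: %d CP replicates, %d TX profiles\n",
                object@nDroppedCp, object@nDroppedTx))
})
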