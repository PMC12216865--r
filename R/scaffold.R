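#' Reserved scaffold key for acyclic molecules
#'
#' The Murcko scaffold (ring systems plus linkers) is empty for molecules
#' without rings; all acyclic compounds share this sentinel key so they
#' move between splits as one group.
#'
#' @return the sentinel scaffold key, a character scalar.
#' @export
acyclicScaffoldKey <- function() "__acyclic__"

#' Canonical Murcko scaffold keys from SMILES
#'
#' Computes the Bemis-Murcko scaffold (canonical SMILES of the ring
#' systems and their linkers) of each molecule by delegating to the RDKit
#' toolkit available as `python` on the PATH. Acyclic molecules receive
#' [acyclicScaffoldKey()]. Synthetic or precomputed scaffold keys can be
#' used everywhere else in the package, so this is the only function that
#' needs a cheminformatics toolkit.
#'
#' @param smiles character vector of SMILES strings.
#' @param python path to the python interpreter with RDKit (default
#'   `"python"` on the PATH).
#' @return character vector of scaffold keys, same length as `smiles`.
#' @examples
#' \dontrun{
#' murckoKey(c("c1ccccc1", "CC", "Cc1ccccc1"))
#' }
#' @export
murckoKey <- function(smiles, python = Sys.which("python")) {
  .assert(is.character(smiles) && length(smiles) > 0,
          "'smiles' must be a non-empty character vector")
  .assert(nzchar(python),
          "no python interpreter with RDKit found on the PATH")
  script <- tempfile(fileext = ".py")
  on.exit(unlink(script), add = TRUE)
  writeLines(c(
    "import sys",
    "from rdkit import Chem, RDLogger",
    "from rdkit.Chem.Scaffolds import MurckoScaffold",
    "RDLogger.DisableLog('rdApp.*')",
    "for line in sys.stdin:",
    "    smi = line.strip()",
    "    m = Chem.MolFromSmiles(smi)",
    "    if m is None:",
    "        print('\\t'.join(('ERROR', smi)))",
    "        continue",
    "    scaf = MurckoScaffold.MurckoScaffoldSmiles(mol=m)",
    "    print('\\t'.join(('OK', scaf)))"
  ), script)
  out <- suppressWarnings(
    system2(python, shQuote(script), input = smiles, stdout = TRUE,
            stderr = FALSE))
  status <- attr(out, "status")
  .assert(is.null(status) || status == 0,
          "RDKit scaffold computation failed (python exit status ",
          status, ")")
  .assert(length(out) == length(smiles),
          "scaffold computation returned an unexpected number of records")
  parts <- strsplit(out, "\t", fixed = TRUE)
  bad <- which(vapply(parts, `[`, "", 1L) == "ERROR")
  if (length(bad))
    stop("unparsable SMILES at position(s) ",
         paste(utils::head(bad, 5), collapse = ", "), ": ",
         paste(utils::head(smiles[bad], 5), collapse = ", "), call. = FALSE)
  keys <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else "", "")
  keys[keys == ""] <- acyclicScaffoldKey()
  keys
}

#' Scaffold-grouped 70/10/20 split
#'
#' Partitions compounds into train/valid/test sets such that all compounds
#' sharing a scaffold key land in the same set. Greedy assignment: scaffold
#' groups are sorted by size (largest first, ties shuffled by `seed`) and
#' each group goes to the set with the largest remaining deficit relative
#' to its target count — deterministic for a fixed seed and as close to the
#' target proportions as the group sizes allow.
#'
#' @param compounds `data.frame` with columns `compound_id` and
#'   `scaffold_key` (assign keys first, e.g. with [murckoKey()] or
#'   synthetic keys).
#' @param ratios target proportions for train/valid/test (sum to 1).
#' @param seed integer seed (shuffles equal-size groups).
#' @return a [SplitAssignment-class].
#' @examples
#' cmp <- data.frame(compound_id = sprintf("c%02d", 1:20),
#'                   scaffold_key = rep(sprintf("s%d", 1:10), each = 2))
#' sp <- scaffoldSplit(cmp, ratios = c(0.7, 0.1, 0.2), seed = 1)
#' table(splitAssignment(sp))
#' @export
scaffoldSplit <- function(compounds, ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  .assert(is.data.frame(compounds) &&
          all(c("compound_id", "scaffold_key") %in% colnames(compounds)),
          "'compounds' needs columns 'compound_id' and 'scaffold_key'")
  .assert(!anyDuplicated(compounds$compound_id),
          "'compound_id' must be unique")
  key <- as.character(compounds$scaffold_key)
  .assert(!anyNA(key) && all(nzchar(key)),
          "all compounds need a non-empty scaffold key; ",
          "use murckoKey() or assign synthetic keys first")
  .assert(length(ratios) == 3 && abs(sum(ratios) - 1) < 1e-8,
          "'ratios' must be three proportions summing to 1")
  n <- nrow(compounds)
  groups <- split(as.character(compounds$compound_id), key)
  sizes <- lengths(groups)
  if (length(groups) == 1L)
    warning("a single scaffold covers all compounds; ",
            "degenerate split: everything assigned to train")
  ord <- withSeed(seed, order(-sizes, sample.int(length(groups))))
  targets <- ratios * n
  counts <- c(train = 0, valid = 0, test = 0)
  labels <- c("train", "valid", "test")
  res <- vector("list", length(groups))
  for (g in ord) {
    deficit <- targets - counts
    dest <- labels[which.max(deficit)]
    members <- groups[[g]]
    res[[g]] <- stats::setNames(rep(dest, length(members)), members)
    counts[dest] <- counts[dest] + length(members)
  }
  asn <- unlist(res)
  asn <- asn[as.character(compounds$compound_id)]
  new("SplitAssignment", assignment = asn, ratios = as.numeric(ratios),
      seed = as.integer(seed))
}

#' The compound-to-set assignment vector
#'
#' @param x a [SplitAssignment-class].
#' @return named character vector: compound identifier to
#'   `train`/`valid`/`test`.
#' @export
splitAssignment <- function(x) {
  .assert(is(x, "SplitAssignment"), "'x' must be a SplitAssignment")
  x@assignment
}

#' Compounds belonging to one or more split sets
#'
#' @param x a [SplitAssignment-class].
#' @param sets subset of `c("train", "valid", "test")`.
#' @return character vector of compound identifiers.
#' @export
compoundsInSplit <- function(x, sets) {
  .assert(is(x, "SplitAssignment"), "'x' must be a SplitAssignment")
  .assert(all(sets %in% c("train", "valid", "test")), "unknown split set")
  names(x@assignment)[x@assignment %in% sets]
}

#' @export
setMethod("show", "SplitAssignment", function(object) {
  tab <- table(factor(object@assignment,
                      levels = c("train", "valid", "test")))
  prop <- tab / sum(tab)
  cat(sprintf(
    "SplitAssignment: %d compounds (train %.3f, valid %.3f, test %.3f; targets %.2f/%.2f/%.2f)\n",
    sum(tab), prop[1], prop[2], prop[3],
    object@ratios[1], object@ratios[2], object@ratios[3]))
})

#' Write a split assignment to a two-column CSV
#'
#' @param x a [SplitAssignment-class].
#' @param path output file path (columns `compound_id`, `split`).
#' @return `path`, invisibly.
#' @export
writeSplitAssignment <- function(x, path) {
  data.table::fwrite(
    data.table::data.table(compound_id = names(splitAssignment(x)),
                           split = unname(splitAssignment(x))), path)
  invisible(path)
}
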