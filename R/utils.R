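#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the caller's
#' RNG state afterwards, so seeded package functions never clobber a user's
#' random stream.
#'
#' @param seed single integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# scalar type checks used by validity methods and argument checking
.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

.is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

.assert <- function(ok, ...) {
  if (!isTRUE(ok)) stop(..., call. = FALSE)
  invisible(TRUE)
}

#' Aggregate matrix rows by group
#'
#' Collapses the rows of a numeric matrix to one row per group, taking the
#' per-column median or mean. Used to turn replicate-level features (raw
#' Cell Painting profiles or their learned embeddings) into compound-level
#' features before mechanism-of-action clustering or bioactivity modelling.
#'
#' @param x numeric matrix.
#' @param groups grouping vector, one entry per row of `x`.
#' @param method `"median"` (default) or `"mean"`.
#' @return A matrix with one row per distinct group, in order of first
#'   appearance in `groups`; rownames are the group labels.
#' @examples
#' m <- rbind(c(0, 0), c(2, 2), c(5, 5))
#' rowGroupAggregate(m, c("a", "a", "b"), method = "mean")
#' @export
rowGroupAggregate <- function(x, groups, method = c("median", "mean")) {
  method <- match.arg(method)
  .assert(is.matrix(x) && is.numeric(x), "'x' must be a numeric matrix")
  .assert(length(groups) == nrow(x), "'groups' must have one entry per row")
  groups <- as.character(groups)
  ugroups <- unique(groups)
  d <- ncol(x)
  out <- matrix(NA_real_, length(ugroups), d,
                dimnames = list(ugroups, colnames(x)))
  if (method == "mean") {
    sums <- rowsum(x, group = factor(groups, levels = ugroups))
    out[] <- sums / as.vector(table(factor(groups, levels = ugroups)))
    return(out)
  }
  # median: group rows by replicate count, use closed forms for small counts
  idx <- split(seq_len(nrow(x)), factor(groups, levels = ugroups))
  sizes <- lengths(idx)
  for (r in unique(sizes)) {
    gset <- which(sizes == r)
    rows <- unlist(idx[gset], use.names = FALSE)
    m <- x[rows, , drop = FALSE]
    if (r == 1L) {
      out[gset, ] <- m
    } else if (r == 2L) {
      a <- m[seq(1, nrow(m), 2), , drop = FALSE]
      b <- m[seq(2, nrow(m), 2), , drop = FALSE]
      out[gset, ] <- (a + b) / 2
    } else if (r == 3L) {
      a <- m[seq(1, nrow(m), 3), , drop = FALSE]
      b <- m[seq(2, nrow(m), 3), , drop = FALSE]
      cc <- m[seq(3, nrow(m), 3), , drop = FALSE]
      out[gset, ] <- a + b + cc - pmax(a, b, cc) - pmin(a, b, cc)
    } else if (r == 4L) {
      a <- array(m, dim = c(4L, length(gset), d))
      s <- colSums(a)
      mx <- pmax(a[1, , , drop = TRUE], a[2, , , drop = TRUE],
                 a[3, , , drop = TRUE], a[4, , , drop = TRUE])
      mn <- pmin(a[1, , , drop = TRUE], a[2, , , drop = TRUE],
                 a[3, , , drop = TRUE], a[4, , , drop = TRUE])
      out[gset, ] <- (s - mx - mn) / 2
    } else {
      a <- array(m, dim = c(r, length(gset), d))
      out[gset, ] <- apply(a, c(2, 3), stats::median)
    }
  }
  out
}
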