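#' Replicate-by-feature profile values
#'
#' Returns the profile matrix in analysis orientation: one row per profile
#' (CP replicate or TX sample), one column per feature.
#'
#' @param x a [ProfileMatrix-class].
#' @return numeric matrix, rownames are profile identifiers.
#' @export
setGeneric("profileValues", function(x) standardGeneric("profileValues"))

#' Compound identifier of every profile
#'
#' @param x a [ProfileMatrix-class].
#' @return character vector named by profile identifiers.
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' Modality tag of a profile container
#'
#' @param x a [ProfileMatrix-class].
#' @return `"CP"` or `"TX"`.
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' Collapse Cell Painting replicates to compound level
#'
#' @param x a CP [ProfileMatrix-class].
#' @param method per-feature aggregate, `"median"` (default) or `"mean"`.
#' @return a compound-level [ProfileMatrix-class] (one profile per
#'   compound, profile identifiers equal to compound identifiers).
#' @export
setGeneric("aggregateReplicates",
           function(x, method = c("median", "mean"))
             standardGeneric("aggregateReplicates"))

#' Generate CP-only embeddings from a pretrained model
#'
#' Runs the Cell Painting encoder of a trained model over CP profiles with
#' no input masking. For the contrastive model the projection head is
#' discarded: output width is the encoder output dimension, not the
#' contrastive-space dimension. For the bimodal autoencoder the decoders
#' play no role at embedding time.
#'
#' @param model a trained [CLModel-class] or [BAEModel-class].
#' @param x a CP [ProfileMatrix-class] whose features match training, or a
#'   plain replicate-by-feature matrix.
#' @return embedding matrix (profiles by embedding dimension), rownames
#'   preserved.
#' @export
setGeneric("embedProfiles", function(model, x)
  standardGeneric("embedProfiles"))
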