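#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Container for perturbation-response z-score profiles
#'
#' `PerturbationExperiment` holds an L1000-style matrix of moderated z-scores
#' (features = landmark genes in rows, samples in columns, following the
#' SummarizedExperiment convention) together with per-sample perturbation
#' metadata: the perturbagen identifier, the perturbagen type (small molecule,
#' gene knockdown, or vehicle control), the cell line, an optional perturbagen
#' class (PCL) label, and for knockdowns the targeted gene symbol.
#'
#' Values are expected to lie in a fixed z-score range (by default
#' \[-10, 10\]); out-of-range values are rejected at construction unless the
#' permissive flag is set.
#'
#' @slot zrange numeric(2), the admissible z-score range recorded at load.
#'
#' @seealso [PerturbationExperiment()] for the constructor, [zscores()],
#'   [sampleInfo()], [geneIds()] for accessors.
#' @export
setClass("PerturbationExperiment",
  contains = "SummarizedExperiment",
  slots = c(zrange = "numeric"),
  prototype = prototype(zrange = c(-10, 10))
)

setValidity("PerturbationExperiment", function(object) {
  msg <- character(0)
  if (!"zscore" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'zscore' is missing")
  else {
    m <- SummarizedExperiment::assay(object, "zscore")
    if (!all(is.finite(m)))
      msg <- c(msg, "z-score matrix contains non-finite values")
  }
  cd <- colData(object)
  req <- c("perturbagen_id", "pert_type", "cell_line")
  miss <- setdiff(req, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("missing sample metadata column(s): ",
                         paste(miss, collapse = ", ")))
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids are not unique")
  if (length(object@zrange) != 2L || object@zrange[1] >= object@zrange[2])
    msg <- c(msg, "zrange must be an ordered pair")
  if (length(msg)) msg else TRUE
})

#' Multilayer variational autoencoder for expression profiles
#'
#' Tanh multilayer perceptron encoder mapping a profile to a Gaussian
#' posterior (mean and diagonal covariance) over the top hidden layer, and a
#' mirror-image decoder whose final layer is squashed by tanh and rescaled to
#' the data range. Trained with mean-squared-error reconstruction plus the
#' closed-form Gaussian KL divergence to a standard normal prior.
#'
#' @slot params list of weight matrices and bias vectors for encoder stack,
#'   Gaussian heads, decoder stack and output layer.
#' @slot config list, the resolved [vaeConfig()].
#' @slot trainingLog data.frame with per-epoch train/validation losses.
#' @slot signature integer vector of signature-node indices on the top hidden
#'   layer; empty until [findSignatureNodes()] results are attached.
#' @slot geneIds character, gene identifiers of the training data (output
#'   dimension order).
#'
#' @export
setClass("VAEModel",
  slots = c(params = "list", config = "list", trainingLog = "data.frame",
            signature = "integer", geneIds = "character")
)

#' Supervised vector-quantized variational autoencoder
#'
#' A tanh encoder producing a continuous encoding vector, a label-indexed
#' codebook (embedding space) with one learnable code per perturbagen class,
#' and a decoder reconstructing the profile from the quantized code. During
#' training the encoding is replaced by the code of the sample's own class;
#' at test time by the nearest code in Euclidean distance. Gradients cross
#' the non-differentiable quantization by the straight-through estimator.
#'
#' @slot params list of encoder/decoder weights.
#' @slot codebook numeric matrix, one row per class (Y x D), row names are
#'   class labels.
#' @slot classLabels character, ordered class labels.
#' @slot classCounts integer, training-set class frequencies (the multinomial
#'   used for unconditional ancestral sampling).
#' @slot latentVar numeric matrix Y x D, per-class diagonal variance of
#'   training encodings, used for class-conditional generation.
#' @slot config list, the resolved [svqvaeConfig()].
#' @slot trainingLog data.frame of per-epoch loss components and validation
#'   nearest-code label-match rate.
#' @slot geneIds character, gene identifiers of the training data.
#'
#' @export
setClass("SVQVAEModel",
  slots = c(params = "list", codebook = "matrix", classLabels = "character",
            classCounts = "integer", latentVar = "matrix", config = "list",
            trainingLog = "data.frame", geneIds = "character")
)
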