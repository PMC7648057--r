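#' Construct a PerturbationExperiment
#'
#' @param zscores numeric matrix of z-scores. Either genes x samples (the
#'   stored orientation) or samples x genes; orientation is resolved against
#'   `sampleInfo`: rows matching `nrow(sampleInfo)` with columns not matching
#'   are treated as samples x genes and transposed.
#' @param sampleInfo data.frame (or DataFrame) of per-sample metadata with at
#'   least `perturbagen_id`, `pert_type` (one of `"small_molecule"`,
#'   `"knockdown"`, `"control"`) and `cell_line`; optional `pcl_label` and
#'   `target_gene`. Row names (or a `sample_id` column) give sample ids.
#' @param geneIds character vector of gene symbols / probe ids; defaults to
#'   the matrix dimnames.
#' @param zrange admissible value range; values outside reject construction.
#' @param permissive logical; if TRUE, out-of-range values are allowed
#'   (non-finite values never are).
#'
#' @return A [PerturbationExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(12), nrow = 3,
#'             dimnames = list(paste0("s", 1:3), paste0("g", 1:4)))
#' si <- data.frame(perturbagen_id = "drugA", pert_type = "small_molecule",
#'                  cell_line = "A375", row.names = paste0("s", 1:3))
#' pe <- PerturbationExperiment(m, si)
#' dim(pe)
#' @export
PerturbationExperiment <- function(zscores, sampleInfo, geneIds = NULL,
                                   zrange = c(-10, 10), permissive = FALSE) {
  zscores <- as.matrix(zscores)
  if (!is.numeric(zscores))
    stop("z-score matrix must be numeric")
  sampleInfo <- as.data.frame(sampleInfo)
  if ("sample_id" %in% colnames(sampleInfo)) {
    if (anyDuplicated(sampleInfo$sample_id))
      stop("sample ids must be unique")
    rownames(sampleInfo) <- sampleInfo$sample_id
    sampleInfo$sample_id <- NULL
  }
  n <- nrow(sampleInfo)
  ids <- rownames(sampleInfo)
  # resolve orientation by dimnames when available (handles square matrices)
  if (!is.null(ids) && !is.null(rownames(zscores)) &&
      all(ids %in% rownames(zscores)) &&
      !(!is.null(colnames(zscores)) && all(ids %in% colnames(zscores)))) {
    zscores <- t(zscores)            # was samples x genes
  } else if (nrow(zscores) == n && ncol(zscores) != n) {
    zscores <- t(zscores)
  } else if (ncol(zscores) != n) {
    stop("matrix dimensions do not match the number of metadata rows")
  }
  if (is.null(geneIds)) geneIds <- rownames(zscores)
  if (is.null(geneIds)) geneIds <- paste0("gene", seq_len(nrow(zscores)))
  if (length(geneIds) != nrow(zscores))
    stop("geneIds length does not match the gene dimension")
  if (length(geneIds) < 2L)
    stop("at least two genes are required")
  rownames(zscores) <- geneIds
  if (is.null(rownames(sampleInfo)) ||
      identical(rownames(sampleInfo), as.character(seq_len(n))))
    rownames(sampleInfo) <- paste0("sample", seq_len(n))
  colnames(zscores) <- rownames(sampleInfo)
  if (anyDuplicated(rownames(sampleInfo)))
    stop("sample ids must be unique")
  if (!all(is.finite(zscores)))
    stop("z-score matrix contains non-finite values")
  if (!permissive) {
    bad <- which(zscores < zrange[1] | zscores > zrange[2], arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf(
        "value %.4g at gene '%s', sample '%s' outside range [%g, %g]; use permissive = TRUE to keep",
        zscores[bad[1, 1], bad[1, 2]], rownames(zscores)[bad[1, 1]],
        colnames(zscores)[bad[1, 2]], zrange[1], zrange[2]))
    }
  }
  pt <- as.character(sampleInfo$pert_type)
  okt <- pt %in% c("small_molecule", "knockdown", "control")
  if (!is.null(sampleInfo$pert_type) && !all(okt))
    stop("pert_type must be one of small_molecule, knockdown, control")
  se <- SummarizedExperiment(assays = list(zscore = zscores),
                             colData = DataFrame(sampleInfo))
  new("PerturbationExperiment", se, zrange = as.numeric(zrange))
}

#' @describeIn PerturbationExperiment z-score assay, genes x samples.
#' @param pe A PerturbationExperiment.
#' @export
zscores <- function(pe) SummarizedExperiment::assay(pe, "zscore")

#' @describeIn PerturbationExperiment z-scores as a samples x genes matrix
#'   (the orientation consumed by the models).
#' @export
sampleMatrix <- function(pe) t(SummarizedExperiment::assay(pe, "zscore"))

#' @describeIn PerturbationExperiment per-sample metadata as a data.frame.
#' @export
sampleInfo <- function(pe) as.data.frame(colData(pe))

#' @describeIn PerturbationExperiment gene identifiers in matrix order.
#' @export
geneIds <- function(pe) rownames(pe)

setMethod("show", "PerturbationExperiment", function(object) {
  cat("PerturbationExperiment:", nrow(object), "genes x",
      ncol(object), "samples\n")
  pt <- table(colData(object)$pert_type)
  cat("  pert_type:", paste(names(pt), pt, sep = "=", collapse = ", "), "\n")
  if ("pcl_label" %in% colnames(colData(object))) {
    nl <- sum(!is.na(colData(object)$pcl_label))
    cat("  PCL-labelled samples:", nl, "\n")
  }
  cat("  z-score range limits: [", object@zrange[1], ",",
      object@zrange[2], "]\n")
  invisible(NULL)
})
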