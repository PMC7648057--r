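#' Dataset assembly thresholds and exclusions
#'
#' Captures the filtering rules used to assemble training datasets from a
#' perturbation compendium: a cell line is "major" when it contributes
#' strictly more than `majorCellLineMin` samples of the relevant perturbagen
#' type; a perturbagen class is "major" when at least `majorPclMin` samples
#' were treated with its members; and named outlier perturbagens (by default
#' the proteasome inhibitors bortezomib and MG-132, which form an outlier
#' cloud in principal-component space) are excluded from merged datasets.
#'
#' @param majorCellLineMin integer, cell-line sample threshold (strict `>`).
#' @param majorPclMin integer, PCL sample threshold (`>=`).
#' @param excludePerturbagens character, perturbagen ids to drop where the
#'   role calls for exclusion.
#' @return A list of class `"assemblySpec"`.
#' @export
assemblySpec <- function(majorCellLineMin = 10000L, majorPclMin = 150L,
                         excludePerturbagens = c("bortezomib", "MG-132")) {
  stopifnot(majorCellLineMin > 0, majorPclMin > 0)
  structure(list(majorCellLineMin = as.integer(majorCellLineMin),
                 majorPclMin = as.integer(majorPclMin),
                 excludePerturbagens = as.character(excludePerturbagens)),
            class = "assemblySpec")
}

#' Assemble a modelling dataset from a perturbation compendium
#'
#' Applies the role-specific filtering rules:
#' \describe{
#'   \item{SMP}{small-molecule samples from major cell lines.}
#'   \item{GP}{knockdown samples from major cell lines.}
#'   \item{SMGP}{union of SMP and GP minus the excluded perturbagens.}
#'   \item{SMC}{SMP samples carrying a (non-missing) PCL label.}
#'   \item{SMCNP}{SMC minus the excluded perturbagens.}
#' }
#' Major cell lines are determined per perturbagen type on the input data
#' before any perturbagen exclusion, so exclusion and cell-line filtering
#' commute. Control samples are dropped by the perturbagen-type filter
#' unless `keepControls = TRUE`.
#'
#' The returned object records the number of samples removed by each rule in
#' `metadata(x)$assembly`.
#'
#' @param pe A [PerturbationExperiment-class].
#' @param spec An [assemblySpec()].
#' @param role One of `"SMP"`, `"GP"`, `"SMGP"`, `"SMC"`, `"SMCNP"`.
#' @param keepControls logical; retain vehicle-control samples.
#' @return A filtered [PerturbationExperiment-class].
#' @export
assembleDataset <- function(pe, spec = assemblySpec(),
                            role = c("SMP", "GP", "SMGP", "SMC", "SMCNP"),
                            keepControls = FALSE) {
  role <- match.arg(role)
  meta <- sampleInfo(pe)
  if (!"pert_type" %in% colnames(meta))
    stop("assembly requires pert_type metadata")
  if (role %in% c("SMC", "SMCNP") && !"pcl_label" %in% colnames(meta))
    stop("role ", role, " requires pcl_label metadata")
  removed <- c(pert_type = 0L, minor_cell_line = 0L,
               excluded_perturbagen = 0L, unlabelled = 0L)

  typeKeep <- function(types) {
    ok <- meta$pert_type %in% types
    if (keepControls) ok <- ok | meta$pert_type == "control"
    ok
  }
  majorLines <- function(types) {
    sub <- meta[meta$pert_type %in% types, , drop = FALSE]
    tab <- table(sub$cell_line)
    names(tab)[tab > spec$majorCellLineMin]
  }
  types <- switch(role,
    SMP = , SMC = , SMCNP = "small_molecule",
    GP = "knockdown",
    SMGP = c("small_molecule", "knockdown"))
  keep <- typeKeep(types)
  removed["pert_type"] <- sum(!keep)
  ml <- unique(unlist(lapply(types, function(tp) majorLines(tp))))
  inMajor <- meta$cell_line %in% ml
  removed["minor_cell_line"] <- sum(keep & !inMajor)
  keep <- keep & inMajor
  if (role %in% c("SMGP", "SMCNP")) {
    excl <- meta$perturbagen_id %in% spec$excludePerturbagens
    removed["excluded_perturbagen"] <- sum(keep & excl)
    keep <- keep & !excl
  }
  if (role %in% c("SMC", "SMCNP")) {
    lab <- !is.na(meta$pcl_label)
    removed["unlabelled"] <- sum(keep & !lab)
    keep <- keep & lab
  }
  if (!any(keep))
    stop("assembly for role ", role, " produced an empty dataset")
  out <- pe[, keep]
  metadata(out)$assembly <- list(role = role, spec = spec,
                                 removed = removed,
                                 input_samples = ncol(pe),
                                 output_samples = sum(keep))
  out
}

#' Major perturbagen classes by treated-sample count
#'
#' @param pe A [PerturbationExperiment-class] with `pcl_label` metadata.
#' @param minSamples integer; classes with at least this many treated samples
#'   are returned.
#' @return data.frame with columns `pcl_label` and `n`, sorted by `n`
#'   descending (ties by label).
#' @export
filterMajorPcls <- function(pe, minSamples = 150L) {
  meta <- sampleInfo(pe)
  if (!"pcl_label" %in% colnames(meta))
    stop("pcl_label metadata is required")
  tab <- table(meta$pcl_label[!is.na(meta$pcl_label)])
  out <- data.frame(pcl_label = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[out$n >= minSamples, , drop = FALSE]
  out <- out[order(-out$n, out$pcl_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}
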