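#' Read a GCT (#1.2) expression matrix
#'
#' Parses the text GCT version 1.2 dialect: a `#1.2` header line, a
#' dimensions line, then a table with NAME and Description columns followed
#' by one column per sample. GCT stores genes in rows; sample metadata is not
#' part of GCT 1.2 and is read from a sidecar table (see `metaPath`).
#'
#' @param path path to the `.gct` file.
#' @param metaPath path to a delimited sample-metadata table with a
#'   `sample_id` column (tab- or comma-separated, autodetected). If NULL,
#'   `<path>.meta.tsv` is used when present; otherwise minimal metadata with
#'   `pert_type = "control"` placeholders is synthesized.
#' @param zrange,permissive forwarded to [PerturbationExperiment()].
#' @return A [PerturbationExperiment-class].
#' @export
readGCT <- function(path, metaPath = NULL, zrange = c(-10, 10),
                    permissive = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 2L)
  if (length(lines) < 2L || !grepl("^#1\\.2\\s*$", lines[1]))
    stop("malformed GCT header: expected '#1.2' on line 1 of ", path)
  dims <- suppressWarnings(as.integer(strsplit(lines[2], "\t")[[1]]))
  if (length(dims) < 2L || anyNA(dims[1:2]))
    stop("malformed GCT dimensions line in ", path)
  tab <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (!identical(toupper(colnames(tab)[1]), "NAME"))
    stop("malformed GCT header row: first column must be NAME")
  mat <- as.matrix(tab[, -(1:2), drop = FALSE])
  .checkNumericCells(mat, path)
  storage.mode(mat) <- "double"
  rownames(mat) <- tab[[1]]
  if (nrow(mat) != dims[1] || ncol(mat) != dims[2])
    stop(sprintf("GCT dimensions line says %d x %d but table is %d x %d",
                 dims[1], dims[2], nrow(mat), ncol(mat)))
  meta <- .readSampleMeta(metaPath, path, colnames(mat))
  PerturbationExperiment(mat, meta, geneIds = rownames(mat),
                         zrange = zrange, permissive = permissive)
}

#' Write a GCT (#1.2) file plus sample-metadata sidecar
#'
#' @param pe A [PerturbationExperiment-class].
#' @param path output `.gct` path; metadata is written to `<path>.meta.tsv`.
#' @return `path`, invisibly.
#' @export
writeGCT <- function(pe, path) {
  m <- zscores(pe)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
  tab <- data.frame(NAME = rownames(m), Description = "na",
                    m, check.names = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  .writeSampleMeta(pe, paste0(path, ".meta.tsv"))
  invisible(path)
}

#' Read a delimited expression matrix with metadata sidecar
#'
#' Reads a tab- or comma-delimited numeric table (autodetected; first column
#' = row ids). Orientation (genes x samples vs samples x genes) is resolved
#' against the metadata sample ids.
#'
#' @inheritParams readGCT
#' @return A [PerturbationExperiment-class].
#' @export
readExpressionMatrix <- function(path, metaPath = NULL, zrange = c(-10, 10),
                                 permissive = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .sniffSep(path)
  tab <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1L,
                           check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(tab)
  .checkNumericCells(mat, path)
  storage.mode(mat) <- "double"
  meta <- .readSampleMeta(metaPath, path, NULL)
  ids <- rownames(meta)
  if (all(ids %in% rownames(mat)) && !all(ids %in% colnames(mat)))
    mat <- t(mat[ids, , drop = FALSE])
  else if (all(ids %in% colnames(mat)))
    mat <- mat[, ids, drop = FALSE]
  else
    stop("metadata sample ids do not match matrix dimnames in ", path)
  PerturbationExperiment(mat, meta, geneIds = rownames(mat),
                         zrange = zrange, permissive = permissive)
}

#' Write a delimited (TSV) expression matrix plus metadata sidecar
#'
#' @param pe A [PerturbationExperiment-class].
#' @param path output path; metadata goes to `<path>.meta.tsv`.
#' @export
writeExpressionMatrix <- function(pe, path) {
  m <- zscores(pe)
  tab <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  .writeSampleMeta(pe, paste0(path, ".meta.tsv"))
  invisible(path)
}

#' Read a two-column drug-target truth table
#'
#' Columns: drug id and target gene symbol (header optional, autodetected;
#' tab or comma separated). Duplicate (drug, gene) pairs after whitespace
#' normalization are collapsed; a drug may map to several genes. Drug ids
#' differing only in case or surrounding whitespace are treated as the same
#' perturbagen.
#'
#' @param path file path.
#' @return data.frame with columns `drug_id`, `target_gene`.
#' @export
readDrugTargets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- .sniffSep(path)
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  hasHeader <- any(tolower(first) %in%
                     c("drug_id", "drug", "target_gene", "gene", "target"))
  tab <- utils::read.table(path, sep = sep, header = hasHeader,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("drug-target table needs two columns")
  out <- data.frame(drug_id = trimws(as.character(tab[[1]])),
                    target_gene = trimws(as.character(tab[[2]])),
                    stringsAsFactors = FALSE)
  unique(out)
}

## ---- internal helpers -----------------------------------------------------

.sniffSep <- function(path) {
  l <- readLines(path, n = 1L)
  if (grepl("\t", l)) "\t" else ","
}

.checkNumericCells <- function(mat, path) {
  if (is.numeric(mat)) return(invisible(NULL))
  suppressWarnings(num <- matrix(as.numeric(mat), nrow = nrow(mat)))
  bad <- which(is.na(num) & !is.na(mat), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-numeric cell '%s' at row %d, column %d of %s",
                 mat[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2], path))
}

.readSampleMeta <- function(metaPath, path, sampleIds) {
  if (is.null(metaPath)) {
    cand <- paste0(path, ".meta.tsv")
    if (file.exists(cand)) metaPath <- cand
  }
  if (is.null(metaPath)) {
    if (is.null(sampleIds))
      stop("no metadata sidecar found for ", path,
           " and sample ids cannot be inferred")
    return(data.frame(perturbagen_id = NA_character_,
                      pert_type = "control", cell_line = NA_character_,
                      row.names = sampleIds, stringsAsFactors = FALSE))
  }
  sep <- .sniffSep(metaPath)
  meta <- utils::read.table(metaPath, sep = sep, header = TRUE,
                            stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% colnames(meta))
    stop("metadata table must contain a sample_id column: ", metaPath)
  rownames(meta) <- meta$sample_id
  meta$sample_id <- NULL
  for (col in c("pcl_label", "target_gene"))
    if (col %in% colnames(meta)) meta[[col]][meta[[col]] %in% c("", "NA")] <- NA
  if (!is.null(sampleIds)) {
    miss <- setdiff(sampleIds, rownames(meta))
    if (length(miss))
      stop("metadata missing for sample(s): ",
           paste(utils::head(miss, 3), collapse = ", "))
    meta <- meta[sampleIds, , drop = FALSE]
  }
  meta
}

.writeSampleMeta <- function(pe, path) {
  meta <- sampleInfo(pe)
  out <- data.frame(sample_id = rownames(meta), meta, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
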