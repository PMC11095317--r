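## Readers and writers for the plain-text formats the pipeline exchanges:
## FASTA sequences, pair tables, feature TSVs, expression matrices with a
## cell-type sidecar, PCA model files and stacked-model bundles.

#' Read protein sequences from a FASTA file
#'
#' Identifiers are the first whitespace-delimited token of each header;
#' sequences are sanitized to the canonical 20-letter alphabet.
#'
#' @param path FASTA file.
#' @return a [Biostrings::AAStringSet] of sanitized sequences.
#' @export
readProteinFasta <- function(path) {
  .assert(file.exists(path), "FASTA file not found: %s", path)
  raw <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(raw))
  seqs <- vapply(seq_along(raw),
                 function(i) sanitizeSequence(as.character(raw[[i]]), ids[i]),
                 character(1))
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#' @param seqs a [Biostrings::AAStringSet].
#' @param path output file.
#' @export
writeProteinFasta <- function(seqs, path) {
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a ligand-receptor pair table
#'
#' Tab-separated with header columns `ligand_id`, `receptor_id` and
#' optionally `label`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readPairTable <- function(path) {
  .assert(file.exists(path), "pair table not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assert(all(c("ligand_id", "receptor_id") %in% names(df)),
          "%s: pair table needs ligand_id and receptor_id columns", path)
  df
}

#' Write a ligand-receptor pair table as TSV
#' @param pairs data.frame with `ligand_id`, `receptor_id` and optional
#'   further columns.
#' @param path output file.
#' @export
writePairTable <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an encoded feature matrix as TSV (id column + named features)
#' @param X numeric matrix with protein ids as rownames.
#' @param path output file.
#' @export
writeFeatureTSV <- function(X, path) {
  df <- data.frame(id = rownames(X), X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [writeFeatureTSV()]
#' @param path TSV file with an `id` column.
#' @return numeric matrix with ids as rownames.
#' @export
readFeatureTSV <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  X <- as.matrix(df[, -1L, drop = FALSE])
  rownames(X) <- df$id
  X
}

#' Read an expression matrix plus cell-type sidecar
#'
#' The matrix file is CSV or TSV (by extension), genes x cells with gene
#' ids in the first column and cell ids as header.  The sidecar is a TSV
#' with columns `cell_id` and `cell_type` covering every cell.
#'
#' @param matrixPath dense matrix file (.csv or .tsv).
#' @param typePath cell-type sidecar TSV.
#' @return an [expressionDataset()].
#' @export
readExpressionDataset <- function(matrixPath, typePath) {
  .assert(file.exists(matrixPath), "expression matrix not found: %s",
          matrixPath)
  .assert(file.exists(typePath), "cell-type sidecar not found: %s", typePath)
  sep <- if (grepl("\\.csv$", matrixPath, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(matrixPath, sep = sep, header = TRUE,
                          row.names = 1L, check.names = FALSE)
  M <- as.matrix(df)
  ty <- utils::read.delim(typePath, stringsAsFactors = FALSE)
  .assert(all(c("cell_id", "cell_type") %in% names(ty)),
          "%s: sidecar needs cell_id and cell_type columns", typePath)
  missing <- setdiff(colnames(M), ty$cell_id)
  .assert(length(missing) == 0L, "no cell type for cells: %s",
          paste(utils::head(missing, 5L), collapse = ", "))
  expressionDataset(M, ty$cell_type[match(colnames(M), ty$cell_id)])
}

#' Write an expression matrix plus sidecar
#' @param expr an [expressionDataset()].
#' @param matrixPath,typePath output files (matrix CSV, sidecar TSV).
#' @export
writeExpressionDataset <- function(expr, matrixPath, typePath) {
  M <- .exprMatrix(expr)
  utils::write.csv(data.frame(gene = rownames(M), M, check.names = FALSE),
                   matrixPath, row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(cell_id = colnames(M),
                                cell_type = cellTypes(expr)),
                     typePath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(matrixPath)
}

#' Save a PCA model to a single JSON file
#'
#' Stores the centering vector, component matrix, component standard
#' deviations, `d` and an encoder version tag.
#'
#' @param model a [ProteinPCA-class].
#' @param path output file.
#' @export
savePcaModel <- function(model, path) {
  jsonlite::write_json(
    list(encoder_version = "stackCCC-encoders-1",
         d = model@d, input_dim = nrow(model@rotation),
         center = model@center, sdev = model@sdev,
         rotation = as.numeric(model@rotation)),  # column-major flat
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a PCA model saved by [savePcaModel()]
#' @param path JSON file.
#' @return a [ProteinPCA-class].
#' @export
loadPcaModel <- function(path) {
  .assert(file.exists(path), "PCA model not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rot <- matrix(as.numeric(obj$rotation), nrow = obj$input_dim,
                ncol = obj$d)
  new("ProteinPCA", center = as.numeric(obj$center), rotation = rot,
      sdev = as.numeric(obj$sdev), d = as.integer(obj$d))
}

#' Save a stacked model bundle
#'
#' Writes a directory containing the serialized model plus a JSON
#' manifest (package version, seeds, configuration echo).
#'
#' @param model a [StackedLRIModel-class].
#' @param dir output directory (created if needed).
#' @export
saveStackedModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  jsonlite::write_json(
    list(package = "stackCCC",
         version = as.character(utils::packageVersion("stackCCC")),
         split_seed = model@splitSeed,
         n_basic = length(model@basicIdx), n_meta = length(model@metaIdx),
         config = model@config),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Load a stacked model bundle saved by [saveStackedModel()]
#' @param dir bundle directory.
#' @return a [StackedLRIModel-class].
#' @export
loadStackedModel <- function(dir) {
  path <- file.path(dir, "model.rds")
  .assert(file.exists(path), "model bundle not found in %s", dir)
  readRDS(path)
}

#' Write pair predictions as TSV
#' @param pairs a [PairFeatureSet-class] or data.frame with `ligand_id`
#'   and `receptor_id`.
#' @param probability numeric vector of interaction probabilities.
#' @param path output file.
#' @export
writePredictions <- function(pairs, probability, path) {
  if (methods::is(pairs, "PairFeatureSet")) {
    pairs <- data.frame(ligand_id = pairs@ligandId,
                        receptor_id = pairs@receptorId)
  }
  out <- data.frame(pairs[, c("ligand_id", "receptor_id")],
                    probability = probability,
                    label = as.integer(probability > 0.5))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a CCC result as CSV matrices and edge list
#'
#' Writes `strength.csv`, the three per-method and normalized matrices,
#' and `edges.tsv` into a directory.
#'
#' @param result a [CCCResult-class].
#' @param dir output directory.
#' @export
writeCCCResult <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(M, name) {
    utils::write.csv(data.frame(cell_type = rownames(M), M,
                                check.names = FALSE),
                     file.path(dir, name), row.names = FALSE, quote = FALSE)
  }
  wm(result@strength, "strength.csv")
  for (meth in names(result@raw)) {
    wm(result@raw[[meth]], paste0("score_", meth, ".csv"))
    wm(result@normalized[[meth]], paste0("normalized_", meth, ".csv"))
  }
  utils::write.table(cccEdgeList(result), file.path(dir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(result@lris, file.path(dir, "filtered_lris.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
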