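#' File input/output for embeddings, counts and pairings
#'
#' Embeddings travel as delimited text (first column = cell id, remaining
#' columns numeric) or Matrix Market (.mtx) with row/column id sidecar
#' files; counts travel the same way. The combined artificial-multiomics
#' output is a directory holding each modality's matched matrix plus a
#' provenance table. Cross-file joins are always by cell id, never by row
#' order.
#'
#' @name io
NULL

.delim_for <- function(path) if (grepl("\\.csv$", path)) "," else "\t"

.sidecar <- function(path, kind) sub("\\.mtx$", sprintf(".%s.txt", kind), path)

#' Read an embedding matrix
#'
#' @param path A `.tsv`/`.txt`/`.csv` file (header, first column cell ids)
#'   or a `.mtx` file with `<name>.rows.txt` / `<name>.cols.txt` id
#'   sidecars.
#' @param batch_col Optional name of a column holding batch labels (text
#'   input only).
#' @param modality Modality name to record.
#' @return An [embedding_set()]; the on-disk cell order is preserved.
#' @export
read_embeddings <- function(path, batch_col = NULL, modality = "modality") {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    storage.mode(m) <- "double" # pattern-format MTX reads as logical
    rows <- readLines(.sidecar(path, "rows"))
    cols <- readLines(.sidecar(path, "cols"))
    if (length(rows) != nrow(m)) {
      stop_format("%s: row id sidecar has %d entries for %d rows", path, length(rows), nrow(m))
    }
    if (length(cols) != ncol(m)) {
      stop_format("%s: column id sidecar has %d entries for %d columns", path, length(cols), ncol(m))
    }
    dimnames(m) <- list(rows, cols)
    return(embedding_set(m, cell_ids = rows, modality = modality))
  }
  df <- utils::read.table(path, header = TRUE, sep = .delim_for(path),
                          check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop_format("%s: duplicate cell ids", path)
  batch <- NULL
  if (!is.null(batch_col)) {
    if (!batch_col %in% names(df)) stop_format("%s: no column '%s'", path, batch_col)
    batch <- df[[batch_col]]
    df[[batch_col]] <- NULL
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop_format("%s: non-numeric embedding entries", path)
  rownames(m) <- ids
  embedding_set(m, cell_ids = ids, batch = batch, modality = modality)
}

#' Write an embedding matrix as delimited text
#'
#' @param es An [embedding_set()].
#' @param path Output `.tsv` or `.csv` path.
#' @export
write_embeddings <- function(es, path) {
  if (!inherits(es, "embedding_set")) stop_value("es must be an embedding_set")
  df <- data.frame(cell_id = es$cell_ids, es$matrix, check.names = FALSE)
  utils::write.table(df, path, sep = .delim_for(path), quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix
#'
#' @param path `.mtx` (with id sidecars, cells x features) or delimited
#'   text (first column cell ids).
#' @param kind Count model: "rna", "atac" or "epitope".
#' @return A [count_set()]; entries must be non-negative integers.
#' @export
read_counts <- function(path, kind = c("rna", "atac", "epitope")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop_format("file not found: %s", path)
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    storage.mode(m) <- "double" # pattern-format MTX reads as logical
    rows <- readLines(.sidecar(path, "rows"))
    cols <- readLines(.sidecar(path, "cols"))
    if (length(rows) != nrow(m) || length(cols) != ncol(m)) {
      stop_format("%s: id sidecar lengths do not match the matrix", path)
    }
    dimnames(m) <- list(rows, cols)
  } else {
    df <- utils::read.table(path, header = TRUE, sep = .delim_for(path),
                            check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
  }
  if (any(m < 0) || any(m != round(m))) {
    stop_format("%s: counts must be non-negative integers", path)
  }
  count_set(m, feature_ids = colnames(m), kind = kind)
}

#' Write a count matrix as Matrix Market with id sidecars
#'
#' @param cs A [count_set()].
#' @param path Output `.mtx` path; `.rows.txt` / `.cols.txt` sidecars are
#'   written alongside.
#' @export
write_counts <- function(cs, path) {
  if (!inherits(cs, "count_set")) stop_value("cs must be a count_set")
  Matrix::writeMM(Matrix::Matrix(cs$matrix, sparse = TRUE), path)
  writeLines(rownames(cs$matrix) %||% sprintf("cell_%d", seq_len(nrow(cs$matrix))),
             .sidecar(path, "rows"))
  writeLines(cs$feature_ids, .sidecar(path, "cols"))
  invisible(path)
}

#' Write / read a pairing table
#'
#' The pairing table is delimited text with the matched ids, the
#' similarity, and (when present) the chunk id; a small JSON header file
#' records epsilon and the unpaired ids so a read round-trip restores the
#' full result.
#'
#' @param result A `pairing_result`.
#' @param path Output `.tsv` path.
#' @export
write_pairing <- function(result, path) {
  if (!inherits(result, "pairing_result")) stop_value("result must be a pairing_result")
  utils::write.table(result$pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- list(epsilon = result$epsilon, total_weight = result$total_weight,
               unpaired_source = as.list(result$unpaired_source),
               unpaired_target = as.list(result$unpaired_target))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pairing
#' @export
read_pairing <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = NA)
  if (nrow(df) == 0) {
    df <- data.frame(source_id = character(0), target_id = character(0),
                     similarity = numeric(0), stringsAsFactors = FALSE)
  }
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    res <- .pairing_result(df, unlist(meta$unpaired_source) %||% character(0),
                           unlist(meta$unpaired_target) %||% character(0), meta$epsilon)
  } else {
    res <- .pairing_result(df, character(0), character(0), NA_real_)
  }
  res
}

#' Assemble and write an artificial multiomics dataset
#'
#' For each matched pair, pulls the source modality's profile and the
#' target modality's profile into one artificial cell and writes the
#' combined dataset to a directory: per-modality count matrices (MTX) or
#' embeddings (TSV) indexed by artificial cell id, plus a provenance table
#' with the contributing ids and the match similarity.
#'
#' @param result A `pairing_result`.
#' @param source_data,target_data [count_set()] or [embedding_set()]
#'   objects holding the profiles of the source/target cells (ids must
#'   cover the paired ids).
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_paired_dataset <- function(result, source_data, target_data, dir) {
  if (!inherits(result, "pairing_result")) stop_value("result must be a pairing_result")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pairs <- result$pairs
  art_ids <- if (nrow(pairs) > 0) sprintf("artificial_%05d", seq_len(nrow(pairs))) else character(0)
  prov <- data.frame(artificial_id = art_ids,
                     source_id = pairs$source_id, target_id = pairs$target_id,
                     similarity = pairs$similarity)
  utils::write.table(prov, file.path(dir, "provenance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  dump_side <- function(data, ids, stem) {
    if (inherits(data, "count_set")) {
      if (!all(ids %in% rownames(data$matrix))) stop_value("paired id missing from %s data", stem)
      sub <- data$matrix[ids, , drop = FALSE]
      rownames(sub) <- art_ids
      write_counts(count_set(sub, feature_ids = data$feature_ids, kind = data$kind),
                   file.path(dir, paste0(stem, ".mtx")))
    } else if (inherits(data, "embedding_set")) {
      if (!all(ids %in% data$cell_ids)) stop_value("paired id missing from %s data", stem)
      sub <- data$matrix[ids, , drop = FALSE]
      rownames(sub) <- art_ids
      write_embeddings(embedding_set(sub, cell_ids = art_ids, modality = data$modality),
                       file.path(dir, paste0(stem, ".tsv")))
    } else {
      stop_value("%s data must be a count_set or embedding_set", stem)
    }
  }
  if (nrow(pairs) > 0) {
    dump_side(source_data, pairs$source_id, "source")
    dump_side(target_data, pairs$target_id, "target")
  }
  write_pairing(result, file.path(dir, "pairing.tsv"))
  invisible(dir)
}
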