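# Compound signature library: a genes x signatures matrix of
# replicate-collapsed z-scores plus per-signature metadata.

META_COLS <- c("signature_id", "compound_id", "pert_type", "cell_line",
               "dose", "time_h", "qc_pass", "high_quality")

#' Compound signature library
#'
#' Bundles a gene-by-signature matrix of replicate-collapsed expression
#' z-scores (level-5 style profiles) with per-signature metadata. All
#' signatures share one gene universe (the matrix rows) and signature ids
#' are unique.
#'
#' @param z numeric matrix, rows named by gene id, columns named by
#'   signature id.
#' @param meta data.frame with columns `signature_id`, `compound_id`,
#'   `pert_type` (`"compound"` or `"genetic"`), `cell_line`, `dose`,
#'   `time_h` (positive hours), `qc_pass`, `high_quality` (logical).
#' @return an object of class `signature_library`.
#' @export
signature_library <- function(z, meta) {
  z <- as.matrix(z)
  .assert(is.numeric(z), "z must be a numeric matrix")
  .assert(!is.null(rownames(z)) && !anyDuplicated(rownames(z)),
          "z rows must be uniquely named by gene id")
  .assert(!is.null(colnames(z)) && !anyDuplicated(colnames(z)),
          "z columns must be uniquely named by signature id")
  .assert(is.data.frame(meta), "meta must be a data.frame")
  .assert(all(META_COLS %in% names(meta)),
          paste("meta missing columns:",
                paste(setdiff(META_COLS, names(meta)), collapse = ", ")))
  meta$signature_id <- as.character(meta$signature_id)
  .assert(!anyDuplicated(meta$signature_id), "duplicate signature ids in meta")
  .assert(setequal(meta$signature_id, colnames(z)),
          "meta and matrix must describe the same signatures")
  meta <- meta[match(colnames(z), meta$signature_id), , drop = FALSE]
  rownames(meta) <- NULL
  .assert(all(meta$pert_type %in% c("compound", "genetic")),
          "pert_type must be 'compound' or 'genetic'")
  .assert(is.numeric(meta$time_h) && all(meta$time_h > 0),
          "time_h must be positive")
  .assert(is.logical(meta$qc_pass) && is.logical(meta$high_quality),
          "qc_pass and high_quality must be logical")
  structure(list(z = z, meta = meta), class = "signature_library")
}

#' @export
print.signature_library <- function(x, ...) {
  cat("Signature library: ", ncol(x$z), " signatures (",
      length(unique(x$meta$compound_id)), " perturbagens) over ",
      nrow(x$z), " genes\n", sep = "")
  invisible(x)
}

#' Subset a signature library by signature id
#'
#' @param library a [signature_library()].
#' @param signature_ids character vector of signature ids to keep.
#' @return a [signature_library()] restricted to the requested signatures.
#' @export
subset_library <- function(library, signature_ids) {
  .assert(inherits(library, "signature_library"), "not a signature_library")
  signature_ids <- as.character(signature_ids)
  missing <- setdiff(signature_ids, colnames(library$z))
  .assert(length(missing) == 0L,
          paste("unknown signature ids:", paste(utils::head(missing, 3L), collapse = ", ")))
  signature_library(library$z[, signature_ids, drop = FALSE],
                    library$meta[match(signature_ids, library$meta$signature_id), ,
                                 drop = FALSE])
}

#' Read / write a signature library
#'
#' The matrix file is wide tab-separated text with a leading `gene_id`
#' column and one column per signature; the metadata file is tab-separated
#' with the columns documented in [signature_library()].
#'
#' @param matrix_path path to the signature matrix file.
#' @param meta_path path to the metadata file.
#' @return `read_library` returns a [signature_library()].
#' @export
read_library <- function(matrix_path, meta_path) {
  wide <- utils::read.delim(matrix_path, stringsAsFactors = FALSE,
                            check.names = FALSE)
  .assert("gene_id" %in% names(wide), "matrix file needs a gene_id column")
  z <- as.matrix(wide[, setdiff(names(wide), "gene_id"), drop = FALSE])
  rownames(z) <- as.character(wide$gene_id)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  meta$qc_pass <- as.logical(meta$qc_pass)
  meta$high_quality <- as.logical(meta$high_quality)
  signature_library(z, meta)
}

#' @rdname read_library
#' @param library a [signature_library()].
#' @export
write_library <- function(library, matrix_path, meta_path) {
  .assert(inherits(library, "signature_library"), "not a signature_library")
  wide <- data.frame(gene_id = rownames(library$z), library$z,
                     check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(wide, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(library$meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(matrix_path)
}
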