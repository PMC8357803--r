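# TWAS post-processing: feature validation, per-gene collapsing,
# transcriptome-wide significance filtering and top-N query-set construction.

#' Two-sided normal tail probability of a TWAS z-score
#'
#' Converts an association z-score to the two-sided p-value
#' `p = 2 * Phi(-|z|)` under the standard normal model used by TWAS
#' summary statistics.
#'
#' @param z numeric vector of finite z-scores.
#' @return numeric vector of p-values in `(0, 1]`.
#' @examples
#' z_to_p(0.47)   # ~0.64
#' z_to_p(-4.85)  # ~1.23e-6
#' @export
z_to_p <- function(z) {
  .assert(is.numeric(z) && length(z) >= 1L, "z must be numeric")
  .assert(all(is.finite(z)), "z must be finite")
  2 * stats::pnorm(-abs(z))
}

#' Validate a table of TWAS features
#'
#' Checks a per-feature TWAS result table (one row per gene x SNP-weight
#' panel): recomputes missing p-values from z, rejects records whose supplied
#' p disagrees with `z_to_p(z)` beyond a relative tolerance (a corruption
#' guard), and enforces `cv_r2` in `[0, 1]`.
#'
#' @param df data.frame with columns `gene_id`, `panel_id`, `z` and
#'   optionally `phenotype`, `p`, `cv_r2`, `model_significant`.
#' @param tol maximum relative disagreement between a supplied p and the one
#'   implied by z before the record is rejected.
#' @return the validated data.frame with `p` filled in.
#' @export
twas_features <- function(df, tol = 0.01) {
  .assert(is.data.frame(df), "df must be a data.frame")
  need <- c("gene_id", "panel_id", "z")
  .assert(all(need %in% names(df)),
          paste("missing required columns:",
                paste(setdiff(need, names(df)), collapse = ", ")))
  if (nrow(df) == 0L) {
    if (!"p" %in% names(df)) df$p <- numeric(0)
    return(df)
  }
  df$gene_id <- as.character(df$gene_id)
  df$panel_id <- as.character(df$panel_id)
  df$z <- as.numeric(df$z)
  .assert(all(is.finite(df$z)), "non-finite z-scores in feature table")
  implied <- z_to_p(df$z)
  if (!"p" %in% names(df)) df$p <- NA_real_
  df$p <- as.numeric(df$p)
  missing_p <- is.na(df$p)
  df$p[missing_p] <- implied[missing_p]
  bad <- !missing_p & abs(df$p - implied) > tol * pmax(df$p, .Machine$double.xmin)
  if (any(bad)) {
    stop("supplied p inconsistent with z beyond ", tol * 100, "% for ",
         sum(bad), " feature(s), e.g. ",
         paste(utils::head(paste0(df$gene_id[bad], "/", df$panel_id[bad]), 3L),
               collapse = ", "), call. = FALSE)
  }
  .assert(all(df$p > 0 & df$p <= 1), "p must lie in (0, 1]")
  if ("cv_r2" %in% names(df)) {
    cv <- df$cv_r2[!is.na(df$cv_r2)]
    .assert(all(cv >= 0 & cv <= 1), "cv_r2 must lie in [0, 1]")
  }
  df
}

#' Read a TWAS feature table
#'
#' Tab-separated, one row per (gene, panel) feature with header
#' `phenotype gene_id panel_id z p cv_r2 model_significant`.
#'
#' @param path file path.
#' @return validated feature data.frame (see [twas_features()]).
#' @export
read_twas <- function(path) {
  twas_features(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Disease expression signature
#'
#' Container for one phenotype's imputed expression profile: a signed
#' z-score per gene (positive = upregulated in cases) and, optionally, the
#' SNP-weight panel each retained feature came from.
#'
#' @param phenotype_id phenotype label, e.g. `"TRD"`.
#' @param z named numeric vector of z-scores; names are gene ids and must be
#'   unique.
#' @param panel optional named character vector (same names as `z`) recording
#'   the retained panel per gene.
#' @return an object of class `disease_signature`.
#' @export
disease_signature <- function(phenotype_id, z, panel = NULL) {
  .assert(is.character(phenotype_id) && length(phenotype_id) == 1L,
          "phenotype_id must be a single string")
  .assert(is.numeric(z), "z must be numeric")
  .assert(!is.null(names(z)) || length(z) == 0L, "z must be named by gene id")
  .assert(!anyDuplicated(names(z)), "duplicate gene ids in signature")
  .assert(all(is.finite(z)), "non-finite z in signature")
  if (!is.null(panel)) {
    .assert(setequal(names(panel), names(z)),
            "panel must cover exactly the signature's genes")
    panel <- panel[names(z)]
  }
  structure(list(phenotype_id = phenotype_id, z = z, panel = panel),
            class = "disease_signature")
}

#' @export
print.disease_signature <- function(x, ...) {
  cat("Disease signature '", x$phenotype_id, "': ", length(x$z),
      " genes (", sum(x$z > 0), " up, ", sum(x$z < 0), " down)\n", sep = "")
  invisible(x)
}

#' Collapse multi-tissue TWAS features to one feature per gene
#'
#' When a gene has features from several SNP-weight panels, the feature with
#' the highest cross-validation R-squared of its expression model is
#' retained; exact ties are broken by lexicographically smallest panel id so
#' the result is data-independent.
#'
#' @param features validated feature data.frame (one phenotype).
#' @param phenotype_id optional phenotype label; defaults to the table's
#'   `phenotype` column.
#' @return a [disease_signature()] with one entry per distinct gene.
#' @export
collapse_features <- function(features, phenotype_id = NULL) {
  features <- twas_features(features)
  if (is.null(phenotype_id)) {
    phenotype_id <- if ("phenotype" %in% names(features) && nrow(features) > 0L) {
      unique(as.character(features$phenotype))
    } else {
      "unknown"
    }
  }
  .assert(length(phenotype_id) == 1L,
          "features span multiple phenotypes; collapse one phenotype at a time")
  if (nrow(features) == 0L) {
    warning("empty feature table; returning empty signature")
    return(disease_signature(phenotype_id, stats::setNames(numeric(0), character(0))))
  }
  .assert("cv_r2" %in% names(features) && !any(is.na(features$cv_r2)),
          "cv_r2 is required for every feature when collapsing")
  o <- order(features$gene_id, -features$cv_r2, features$panel_id)
  f <- features[o, , drop = FALSE]
  keep <- f[!duplicated(f$gene_id), , drop = FALSE]
  disease_signature(phenotype_id,
                    stats::setNames(keep$z, keep$gene_id),
                    stats::setNames(keep$panel_id, keep$gene_id))
}

#' Transcriptome-wide significance filter
#'
#' Retains features with `p < alpha`, preserving input order. The default
#' threshold is the transcriptome-wide significance level 1.37e-6.
#'
#' @param features feature data.frame with a `p` column.
#' @param alpha significance level in (0, 1).
#' @return the filtered data.frame.
#' @export
significance_filter <- function(features, alpha = 1.37e-6) {
  .assert(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha <= 1,
          "alpha must lie in (0, 1]")
  .assert(is.data.frame(features) && "p" %in% names(features),
          "features must carry a p column")
  features[features$p < alpha, , drop = FALSE]
}

#' Build a top-N up/down query set from a disease signature
#'
#' Selects the `n` genes with largest `|z|` (ties broken by gene id), then
#' partitions them by sign of z into up- and down-regulated sets. Genes with
#' z exactly 0 carry no direction and are excluded with a warning. If the
#' signature holds fewer than `n` genes, all are used.
#'
#' @param signature a [disease_signature()].
#' @param n positive integer, requested total number of genes.
#' @return an object of class `query_set` with elements `up`, `down`,
#'   `n_requested`.
#' @export
make_query_set <- function(signature, n) {
  .assert(inherits(signature, "disease_signature"), "signature must be a disease_signature")
  .assert(length(signature$z) > 0L, "signature is empty")
  .assert(is.numeric(n) && length(n) == 1L && is.finite(n) && n >= 1,
          "n must be a positive integer")
  n <- as.integer(n)
  z <- signature$z
  o <- order(-abs(z), names(z))
  sel <- z[o[seq_len(min(n, length(z)))]]
  if (any(sel == 0)) {
    warning(sum(sel == 0), " selected gene(s) with z = 0 excluded from query set")
    sel <- sel[sel != 0]
  }
  structure(list(up = names(sel)[sel > 0],
                 down = names(sel)[sel < 0],
                 n_requested = n),
            class = "query_set")
}

#' @export
print.query_set <- function(x, ...) {
  cat("Query set: ", length(x$up), " up / ", length(x$down), " down (n = ",
      x$n_requested, ")\n", sep = "")
  invisible(x)
}

#' Map gene symbols to numeric gene ids through a static lookup table
#'
#' A file-based replacement for live annotation queries: every input symbol
#' lands in exactly one of `mapped` / `unmapped`, duplicates are looked up
#' once, and unmapped symbols are reported rather than silently dropped.
#'
#' @param symbols character vector of gene symbols.
#' @param mapping named character vector (names = symbols, values = ids), as
#'   returned by [read_gene_map()].
#' @return list with `mapped` (named character vector) and `unmapped`
#'   (character vector).
#' @export
map_symbols <- function(symbols, mapping) {
  .assert(is.character(mapping) && length(mapping) > 0L && !is.null(names(mapping)),
          "mapping must be a non-empty named character vector")
  .assert(!anyDuplicated(names(mapping)),
          "mapping must be a function: duplicate symbols in table")
  symbols <- unique(as.character(symbols))
  hit <- symbols %in% names(mapping)
  list(mapped = mapping[symbols[hit]], unmapped = symbols[!hit])
}

#' Read a two-column symbol-to-id mapping table
#'
#' @param path tab-separated file with columns `symbol` and `gene_id`.
#' @return named character vector suitable for [map_symbols()].
#' @export
read_gene_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assert(all(c("symbol", "gene_id") %in% names(df)),
          "gene map needs columns symbol, gene_id")
  stats::setNames(as.character(df$gene_id), as.character(df$symbol))
}

#' Write / read a disease signature as a tab-separated table
#'
#' Columns `gene_id`, `z` and (when available) `panel`.
#'
#' @param signature a [disease_signature()].
#' @param path file path.
#' @return `read_signature` returns a [disease_signature()].
#' @export
write_signature <- function(signature, path) {
  .assert(inherits(signature, "disease_signature"), "not a disease_signature")
  df <- data.frame(gene_id = names(signature$z), z = unname(signature$z),
                   stringsAsFactors = FALSE)
  if (!is.null(signature$panel)) df$panel <- unname(signature$panel)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_signature
#' @param phenotype_id phenotype label to attach on read.
#' @export
read_signature <- function(path, phenotype_id = "unknown") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assert(all(c("gene_id", "z") %in% names(df)),
          "signature file needs columns gene_id, z")
  panel <- if ("panel" %in% names(df)) {
    stats::setNames(as.character(df$panel), df$gene_id)
  }
  disease_signature(phenotype_id, stats::setNames(df$z, df$gene_id), panel)
}
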