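# Reversal ranking: score screened compounds for dissimilarity to the
# disease signature with signed KS, Spearman and Pearson statistics over
# all genes and nested top-N subsets, aggregate by two-level rank
# averaging, and attach permutation p-values from pooled shuffled-signature
# nulls.

#' Ranking configuration
#'
#' @param n_perm number of disease-signature permutations (default 100).
#' @param sizes strictly increasing top-N gene-set sizes.
#' @param rng_seed base seed for the permutation stream.
#' @return a list of class `rank_config`.
#' @export
rank_config <- function(n_perm = 100L,
                        sizes = c(25L, 50L, 100L, 150L, 250L),
                        rng_seed = 1L) {
  .assert(is.numeric(n_perm) && n_perm >= 1, "n_perm must be at least 1")
  .assert(is.numeric(sizes) && length(sizes) >= 1 && all(diff(sizes) > 0),
          "sizes must be strictly increasing")
  structure(list(n_perm = as.integer(n_perm),
                 sizes = as.integer(sizes),
                 rng_seed = as.integer(rng_seed)),
            class = "rank_config")
}

# Signed two-sample KS statistic: maximal ECDF gap of signature values
# among disease-downregulated genes minus disease-upregulated genes,
# evaluated at the location of largest absolute gap. Negative when the
# upregulated genes sit at stochastically lower signature values, i.e. when
# the compound reverses the disease direction.
ks_signed <- function(up_vals, down_vals) {
  n1 <- length(up_vals)
  n2 <- length(down_vals)
  .assert(n1 >= 1L && n2 >= 1L, "signed KS needs values on both sides")
  ks_batch(matrix(c(up_vals, down_vals), ncol = 1L), n1, n2)
}

# Column-wise signed KS over a (n1 + n2) x B value matrix whose first n1
# rows hold the up-gene values. The ECDF-difference increments are fixed
# across columns, so each column costs one order() plus vector arithmetic.
ks_batch <- function(V, n1, n2) {
  inc <- c(rep(-1 / n1, n1), rep(1 / n2, n2))
  n <- n1 + n2
  B <- ncol(V)
  out <- numeric(B)
  for (j in seq_len(B)) {
    v <- V[, j]
    o <- order(v)
    d <- cumsum(inc[o])
    vo <- v[o]
    at_boundary <- c(vo[-1L] != vo[-n], TRUE)  # collapse ties
    d <- d[at_boundary]
    dmax <- max(d)
    dmin <- min(d)
    out[j] <- if (abs(dmax) >= abs(dmin)) dmax else dmin
  }
  out
}

#' Dissimilarity score of one signature by one method
#'
#' Pearson/Spearman: correlation between disease and signature z over the
#' shared (sub)universe. KS: signed two-sample KS statistic comparing the
#' signature's z among disease-upregulated versus disease-downregulated
#' genes of the subset. All three are negative for reversal.
#'
#' @param disease a [disease_signature()].
#' @param signature_z named numeric vector of compound signature z-scores.
#' @param method one of `"pearson"`, `"spearman"`, `"ks"`.
#' @param subset optional character vector of gene ids restricting the
#'   comparison; `NULL` uses all shared genes.
#' @return a score in `[-1, 1]`.
#' @export
method_score <- function(disease, signature_z,
                         method = c("pearson", "spearman", "ks"),
                         subset = NULL) {
  method <- match.arg(method)
  genes <- intersect(names(disease$z), names(signature_z))
  if (!is.null(subset)) genes <- intersect(genes, subset)
  .assert(length(genes) >= 3L, "insufficient overlap between disease and signature")
  dz <- disease$z[genes]
  sz <- signature_z[genes]
  if (method == "ks") {
    up <- dz > 0
    down <- dz < 0
    .assert(any(up) && any(down),
            "signed KS needs at least one up- and one down-regulated gene")
    ks_signed(sz[up], sz[down])
  } else {
    stats::cor(dz, sz, method = method)
  }
}

# Top-n gene indices of a disease z vector (by |z|, gene-id tie-break,
# zero-z genes excluded), relative to the vector's own ordering.
top_subset_idx <- function(dz, n) {
  o <- order(-abs(dz), names(dz))
  sel <- o[seq_len(min(n, length(dz)))]
  sel[dz[sel] != 0]
}

# Scoring context: everything about the signature matrix that permutations
# can reuse (per-column global ranks feed the all-genes Spearman).
make_rank_ctx <- function(Z) {
  list(Z = Z,
       rank_all = apply(Z, 2L, rank),
       n_sig = ncol(Z),
       ids = colnames(Z))
}

# Long score table for one disease vector: methods ks / spearman / pearson,
# evaluated on all genes ("ALL") and on each nested top-N subset.
scores_for_disease <- function(dz, ctx, sizes) {
  Z <- ctx$Z
  ids <- ctx$ids
  ks_col <- function(up_idx, down_idx) {
    ks_batch(Z[c(up_idx, down_idx), , drop = FALSE],
             length(up_idx), length(down_idx))
  }
  rows <- list()
  add <- function(method, size, score) {
    rows[[length(rows) + 1L]] <<- data.frame(signature_id = ids,
                                             method = method, size = size,
                                             score = score,
                                             stringsAsFactors = FALSE)
  }
  up_all <- which(dz > 0)
  down_all <- which(dz < 0)
  .assert(length(up_all) > 0L && length(down_all) > 0L,
          "disease signature must contain both up- and down-regulated genes")
  add("pearson_all", "ALL", as.vector(stats::cor(dz, Z)))
  add("spearman_all", "ALL", as.vector(stats::cor(rank(dz), ctx$rank_all)))
  add("ks", "ALL", ks_col(up_all, down_all))
  for (n in sizes) {
    idx <- top_subset_idx(dz, n)
    lab <- as.character(n)
    add("pearson_top", lab, as.vector(stats::cor(dz[idx], Z[idx, , drop = FALSE])))
    add("spearman_top", lab,
        as.vector(stats::cor(dz[idx], Z[idx, , drop = FALSE], method = "spearman")))
    up_idx <- idx[dz[idx] > 0]
    down_idx <- idx[dz[idx] < 0]
    .assert(length(up_idx) > 0L && length(down_idx) > 0L,
            paste0("top-", n, " subset is single-signed; signed KS undefined"))
    add("ks", lab, ks_col(up_idx, down_idx))
  }
  do.call(rbind, rows)
}

#' Two-level rank aggregation of method scores
#'
#' Within every (method, gene-set size) cell, signatures are ranked
#' ascending by score so rank 1 is the strongest reversal (most negative);
#' ties receive average ranks. Ranks are then averaged over gene-set sizes
#' within each method, and the per-method averages are averaged into the
#' overall rank.
#'
#' @param scores long data.frame with columns `signature_id`, `method`,
#'   `size`, `score`; every signature must be scored in every (method,
#'   size) cell.
#' @return data.frame with one row per signature: per-method average ranks
#'   (`rank_<method>` columns), `overall_rank`, sorted by `overall_rank`.
#' @export
aggregate_ranks <- function(scores) {
  .assert(all(c("signature_id", "method", "size", "score") %in% names(scores)),
          "scores must carry signature_id, method, size, score")
  ids <- unique(scores$signature_id)
  .assert(length(ids) >= 2L, "ranking needs at least two signatures")
  cell <- paste(scores$method, scores$size, sep = "|")
  counts <- table(scores$signature_id, cell)
  if (any(counts != 1L)) {
    holes <- which(counts != 1L, arr.ind = TRUE)
    stop("incomplete scoring design: ",
         paste(utils::head(paste0(rownames(counts)[holes[, 1L]], " x ",
                                  colnames(counts)[holes[, 2L]]), 5L),
               collapse = ", "), call. = FALSE)
  }
  scores$rank <- stats::ave(scores$score, cell,
                            FUN = function(s) rank(s, ties.method = "average"))
  per_cell_mean <- function(df) {
    tapply(df$rank, df$signature_id, mean)[ids]
  }
  methods <- sort(unique(scores$method))
  per_method <- vapply(methods,
                       function(m) per_cell_mean(scores[scores$method == m, ]),
                       numeric(length(ids)))
  per_method <- matrix(per_method, nrow = length(ids),
                       dimnames = list(ids, methods))
  out <- data.frame(signature_id = ids, stringsAsFactors = FALSE)
  for (m in methods) out[[paste0("rank_", m)]] <- per_method[, m]
  out$overall_rank <- rowMeans(per_method)
  out <- out[order(out$overall_rank, out$signature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Permutation p-values for aggregate reversal ranks
#'
#' For each of `cfg$n_perm` permutations, the disease z-scores are shuffled
#' across gene ids, the full score-rank-aggregate pipeline is re-run on the
#' same signatures, and every signature's null overall rank is recorded.
#' Null ranks are pooled across all signatures and each observed overall
#' rank is assigned `perm_p = (k + 1)/(K + 1)` with `k` the number of
#' pooled null ranks at or below it.
#'
#' @param disease a [disease_signature()].
#' @param library a [signature_library()] (or its subset) holding the
#'   signatures named in `observed`.
#' @param observed output of [aggregate_ranks()] on the same inputs.
#' @param cfg a [rank_config()].
#' @return `observed` with a `perm_p` column added.
#' @export
permutation_p <- function(disease, library, observed, cfg = rank_config()) {
  Z <- library$z[, observed$signature_id, drop = FALSE]
  genes <- intersect(names(disease$z), rownames(Z))
  dz <- disease$z[genes]
  ctx <- make_rank_ctx(Z[genes, , drop = FALSE])
  null_ranks <- matrix(NA_real_, nrow(observed), cfg$n_perm)
  for (b in seq_len(cfg$n_perm)) {
    dz_perm <- dz
    dz_perm[] <- with_seed(derive_seed(cfg$rng_seed, b),
                           dz[sample.int(length(dz))])
    agg <- aggregate_ranks(scores_for_disease(dz_perm, ctx, cfg$sizes))
    null_ranks[, b] <- agg$overall_rank[match(observed$signature_id,
                                              agg$signature_id)]
  }
  pooled <- sort(as.vector(null_ranks))
  K <- length(pooled)
  observed$perm_p <- (findInterval(observed$overall_rank, pooled) + 1) / (K + 1)
  observed
}

#' Rank compounds for signature reversal
#'
#' Runs the scoring, aggregation and permutation stages on a set of
#' signatures: signed KS, Spearman and Pearson dissimilarity over all genes
#' and the nested top-N subsets, two-level rank averaging (rank 1 =
#' strongest reversal), and pooled-permutation p-values.
#'
#' @param disease a [disease_signature()].
#' @param library a [signature_library()].
#' @param signature_ids signatures to rank (default: all in the library).
#' @param cfg a [rank_config()].
#' @return data.frame sorted by `overall_rank` with per-method average
#'   ranks, `overall_rank`, `perm_p`, `compound_id` and
#'   `compound_best_rank` (the minimum overall rank among the compound's
#'   signatures; every signature row is preserved).
#' @export
rank_compounds <- function(disease, library, signature_ids = NULL,
                           cfg = rank_config()) {
  .assert(inherits(disease, "disease_signature"), "disease must be a disease_signature")
  .assert(inherits(library, "signature_library"), "library must be a signature_library")
  if (is.null(signature_ids)) signature_ids <- colnames(library$z)
  lib <- subset_library(library, signature_ids)
  genes <- intersect(names(disease$z), rownames(lib$z))
  .assert(length(genes) >= 3L, "insufficient gene overlap with the library")
  dz <- disease$z[genes]
  ctx <- make_rank_ctx(lib$z[genes, , drop = FALSE])
  observed <- aggregate_ranks(scores_for_disease(dz, ctx, cfg$sizes))
  observed <- permutation_p(disease, lib, observed, cfg)
  observed$compound_id <- lib$meta$compound_id[match(observed$signature_id,
                                                     lib$meta$signature_id)]
  best <- tapply(observed$overall_rank, observed$compound_id, min)
  observed$compound_best_rank <- as.numeric(best[observed$compound_id])
  observed
}
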