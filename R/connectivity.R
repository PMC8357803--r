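# Connectivity screening: weighted Kolmogorov-Smirnov enrichment of disease
# query gene sets in compound signatures, score normalization, random-query
# empirical p values, FDR control and signature selection criteria.

#' Screening configuration
#'
#' @param ks_weight_exponent nonnegative weight exponent on `|z|` at hit
#'   positions; 1 weights hits by signature z magnitude, 0 recovers the
#'   classic unweighted KS statistic.
#' @param null_queries number of random query sets in the empirical null
#'   (at least 100).
#' @param fdr_threshold FDR threshold for candidate selection, in (0, 1).
#' @param exclusion_list compound ids excluded a priori (e.g. existing
#'   antidepressants/antipsychotics, toxic compounds).
#' @param rng_seed base seed; every random draw in the screen derives from
#'   it via a per-signature counter.
#' @param grouping `"cell_line"` to normalize scores within cell-line x
#'   perturbagen-type groups, `"global"` for one group (small libraries).
#' @return a list of class `screen_config`.
#' @export
screen_config <- function(ks_weight_exponent = 1,
                          null_queries = 1000L,
                          fdr_threshold = 0.10,
                          exclusion_list = character(0),
                          rng_seed = 1L,
                          grouping = c("cell_line", "global")) {
  .assert(is.numeric(ks_weight_exponent) && ks_weight_exponent >= 0,
          "ks_weight_exponent must be nonnegative")
  .assert(is.numeric(null_queries) && null_queries >= 100,
          "null_queries must be at least 100")
  .assert(is.numeric(fdr_threshold) && fdr_threshold > 0 && fdr_threshold < 1,
          "fdr_threshold must lie in (0, 1)")
  structure(list(ks_weight_exponent = ks_weight_exponent,
                 null_queries = as.integer(null_queries),
                 fdr_threshold = fdr_threshold,
                 exclusion_list = as.character(exclusion_list),
                 rng_seed = as.integer(rng_seed),
                 grouping = match.arg(grouping)),
            class = "screen_config")
}

# ---- weighted KS enrichment ------------------------------------------------

# Core running-sum extremum given sorted hit positions `pos` (ranks in the
# signature ordered by decreasing z) and the weight vector `a` = |z|^exponent
# over the full ordered universe. Hits add a[pos]/sum(a[pos]); each miss
# subtracts 1/(N - k). Returns the signed running-sum value of maximal
# absolute magnitude. Local maxima occur just after hits, local minima just
# before hits, so only O(k) candidates need evaluation.
es_core <- function(pos, a, N) {
  k <- length(pos)
  M <- N - k
  w <- a[pos]
  sw <- sum(w)
  .assert(sw > 0, "all hit weights are zero; cannot weight the running sum")
  W <- cumsum(w) / sw
  after <- W - (pos - seq_len(k)) / M
  before <- after - w / sw
  mx <- max(after)
  mn <- min(before)
  if (abs(mx) >= abs(mn)) mx else mn
}

# Vectorized es_core over B queries: Pm is a k x B matrix of column-sorted
# hit positions sharing the weight vector a. `penalty` is the miss-penalty
# term (Pm - i)/(N - k); it depends only on the positions and can be
# precomputed when the same queries are scored against many signatures.
es_batch <- function(Pm, a, N, penalty = (Pm - seq_len(nrow(Pm))) / (N - nrow(Pm))) {
  k <- nrow(Pm)
  B <- ncol(Pm)
  A <- matrix(a[Pm], k, B)
  SW <- .colSums(A, k, B)
  .assert(all(SW > 0), "all hit weights are zero in a null query")
  SWr <- rep(SW, each = k)
  after <- col_cumsum(A) / SWr - penalty
  before <- after - A / SWr
  mx <- col_max(after)
  mn <- col_min(before)
  ifelse(abs(mx) >= abs(mn), mx, mn)
}

# Deterministic ordering of a signature: decreasing z, gene id breaking ties.
signature_order <- function(z, genes = names(z)) {
  order(-z, genes)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Ranks the signature's gene universe by decreasing z, walks the ranked
#' list accumulating `|z|^exponent / sum(|z|^exponent over hits)` at members
#' of `gene_set` and `-1/(number of misses)` elsewhere, and returns the
#' running-sum value of maximal absolute magnitude (signed). Positive scores
#' mean the set concentrates among upregulated genes of the signature,
#' negative among downregulated ones.
#'
#' @param gene_set character vector of gene ids (must intersect the
#'   signature universe and not cover it entirely).
#' @param signature_z named numeric vector of signature z-scores over the
#'   gene universe.
#' @param exponent nonnegative weight exponent (0 = unweighted KS).
#' @return a single score in `[-1, 1]`.
#' @export
weighted_es <- function(gene_set, signature_z, exponent = 1) {
  .assert(is.numeric(signature_z) && !is.null(names(signature_z)),
          "signature_z must be a named numeric vector")
  genes <- names(signature_z)
  hits <- unique(as.character(gene_set))
  hits <- hits[hits %in% genes]
  .assert(length(hits) > 0L, "gene set does not overlap the signature universe")
  .assert(length(hits) < length(genes),
          "gene set covers the whole universe; miss penalty undefined")
  ord <- signature_order(signature_z, genes)
  a <- abs(signature_z[ord])^exponent
  pos <- sort(match(hits, genes[ord]))
  es_core(pos, a, length(genes))
}

# Drop query genes absent from the universe; reject if < 50% survive.
prune_query <- function(query, genes) {
  up <- intersect(query$up, genes)
  down <- intersect(query$down, genes)
  n_in <- length(query$up) + length(query$down)
  n_kept <- length(up) + length(down)
  if (n_kept < n_in) {
    warning(n_in - n_kept, " query gene(s) absent from the signature universe dropped")
  }
  .assert(n_in > 0L, "query has no genes")
  .assert(n_kept >= 0.5 * n_in,
          "query rejected: fewer than 50% of its genes are in the signature universe")
  list(up = up, down = down)
}

# Combine up/down enrichment into one connectivity score: opposite-signed
# components average to (es_up - es_down)/2, same-signed components cancel
# to 0; a one-sided query passes through (down negated).
combine_es <- function(es_up, es_down) {
  if (is.na(es_up)) return(-es_down)
  if (is.na(es_down)) return(es_up)
  if (sign(es_up) != sign(es_down)) (es_up - es_down) / 2 else 0
}

#' Connectivity score of a disease query against one compound signature
#'
#' Computes [weighted_es()] for the up- and down-regulated query sets and
#' combines them: when the two enrichments have opposite signs the score is
#' `(ES_up - ES_down)/2`, otherwise 0; one-sided queries use the single
#' set's enrichment (negated for the down set). Positive scores mean the
#' signature mimics the disease profile, negative that it reverses it.
#'
#' @param query a `query_set` (see [make_query_set()]).
#' @param signature_z named numeric vector of signature z-scores.
#' @param exponent weight exponent, see [weighted_es()].
#' @return a score in `[-1, 1]`.
#' @export
connectivity_score <- function(query, signature_z, exponent = 1) {
  .assert(length(query$up) + length(query$down) > 0L,
          "query has neither up nor down genes")
  q <- prune_query(query, names(signature_z))
  es_up <- if (length(q$up)) weighted_es(q$up, signature_z, exponent) else NA_real_
  es_down <- if (length(q$down)) weighted_es(q$down, signature_z, exponent) else NA_real_
  .assert(!(is.na(es_up) && is.na(es_down)), "query empty after pruning")
  combine_es(es_up, es_down)
}

# ---- normalization, empirical p, FDR ---------------------------------------

#' Normalize connectivity scores within groups
#'
#' Within each group (typically cell line x perturbagen type), positive raw
#' scores are divided by the mean of the group's positive scores and
#' negative raw scores by the absolute mean of the group's negative scores,
#' so scores become comparable across experimental contexts. Signs are
#' preserved; zeros stay zero; a group lacking one sign class leaves that
#' class untouched.
#'
#' @param scores numeric vector of raw connectivity scores.
#' @param groups vector (same length) assigning each score to one group;
#'   defaults to a single global group.
#' @return numeric vector of normalized scores, same order as input.
#' @export
normalize_scores <- function(scores, groups = rep("all", length(scores))) {
  .assert(is.numeric(scores), "scores must be numeric")
  .assert(length(groups) == length(scores),
          "groups must assign every score to exactly one group")
  out <- scores
  for (g in split(seq_along(scores), as.character(groups))) {
    s <- scores[g]
    pos <- s > 0
    neg <- s < 0
    if (any(pos)) out[g][pos] <- s[pos] / mean(s[pos])
    if (any(neg)) out[g][neg] <- s[neg] / abs(mean(s[neg]))
  }
  out
}

# Draw B random queries of matched sizes as positions in the ranked
# universe (uniform draws without replacement), column-sorted.
sample_positions <- function(N, k_up, k_down, B) {
  Pu <- matrix(0L, k_up, B)
  Pd <- matrix(0L, k_down, B)
  ktot <- k_up + k_down
  for (b in seq_len(B)) {
    s <- sample.int(N, ktot)
    if (k_up) Pu[, b] <- sort.int(s[seq_len(k_up)])
    if (k_down) Pd[, b] <- sort.int(s[k_up + seq_len(k_down)])
  }
  list(up = Pu, down = Pd)
}

# Null connectivity scores for one signature: random queries of matched
# sizes scored against the same (pre-ordered) weight vector.
null_connectivity <- function(a, N, k_up, k_down, B) {
  P <- sample_positions(N, k_up, k_down, B)
  es_up <- if (k_up) es_batch(P$up, a, N) else rep(NA_real_, B)
  es_down <- if (k_down) es_batch(P$down, a, N) else rep(NA_real_, B)
  if (k_up == 0L) return(-es_down)
  if (k_down == 0L) return(es_up)
  ifelse(sign(es_up) != sign(es_down), (es_up - es_down) / 2, 0)
}

#' Empirical p-value of a connectivity score from random queries
#'
#' Builds a null distribution by scoring `cfg$null_queries` random query
#' sets of the same up/down sizes (uniform draws from the signature's gene
#' universe, seeded from `cfg$rng_seed`) against the same signature, and
#' returns the two-sided estimate `(k + 1)/(n + 1)` where `k` counts null
#' scores at least as extreme in absolute value as the observed one.
#'
#' @param observed observed connectivity score.
#' @param query the `query_set` that produced it (sizes are matched after
#'   pruning to the universe).
#' @param signature_z named numeric signature z-score vector.
#' @param cfg a [screen_config()].
#' @return p-value in `(0, 1]`.
#' @export
empirical_p <- function(observed, query, signature_z, cfg = screen_config()) {
  q <- suppressWarnings(prune_query(query, names(signature_z)))
  ord <- signature_order(signature_z)
  a <- abs(signature_z[ord])^cfg$ks_weight_exponent
  B <- cfg$null_queries
  nulls <- with_seed(cfg$rng_seed,
                     null_connectivity(a, length(signature_z),
                                       length(q$up), length(q$down), B))
  (sum(abs(nulls) >= abs(observed)) + 1) / (B + 1)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values with input order preserved; input p-values must lie in
#' (0, 1].
#'
#' @param p_values numeric vector of p-values.
#' @return numeric vector of q-values in (0, 1].
#' @export
fdr_adjust <- function(p_values) {
  .assert(is.numeric(p_values), "p_values must be numeric")
  if (length(p_values) == 0L) return(numeric(0))
  .assert(all(is.finite(p_values) & p_values > 0 & p_values <= 1),
          "p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

# ---- screening orchestration -----------------------------------------------

#' Score a query set against every signature in a library
#'
#' For each signature: raw weighted-KS connectivity score, group-normalized
#' score, empirical p from matched random queries, and BH q-values across
#' the library. One seeded panel of `cfg$null_queries` random queries of
#' matched up/down sizes is drawn per call and scored against every
#' signature, so empirical p-values across signatures share a common,
#' reproducible null panel.
#'
#' @param query a `query_set`.
#' @param library a [signature_library()].
#' @param cfg a [screen_config()].
#' @return data.frame with columns `signature_id`, `compound_id`,
#'   `raw_score`, `norm_score`, `p_value`, `fdr_q`.
#' @export
screen_library <- function(query, library, cfg = screen_config()) {
  .assert(inherits(library, "signature_library"), "library must be a signature_library")
  Z <- library$z
  genes <- rownames(Z)
  q <- prune_query(query, genes)
  k_up <- length(q$up)
  k_down <- length(q$down)
  .assert(k_up + k_down > 0L, "query empty after pruning to the library universe")
  N <- length(genes)
  n_sig <- ncol(Z)
  raw <- numeric(n_sig)
  pval <- numeric(n_sig)
  B <- cfg$null_queries
  gene_rank <- rank(genes, ties.method = "first")  # numeric lexicographic key
  up_rows <- match(q$up, genes)
  down_rows <- match(q$down, genes)
  P <- with_seed(derive_seed(cfg$rng_seed, 0L),
                 sample_positions(N, k_up, k_down, B))
  pen_up <- if (k_up) (P$up - seq_len(k_up)) / (N - k_up)
  pen_down <- if (k_down) (P$down - seq_len(k_down)) / (N - k_down)
  for (j in seq_len(n_sig)) {
    zj <- Z[, j]
    ord <- order(-zj, gene_rank)
    inv <- integer(N)
    inv[ord] <- seq_len(N)
    a <- abs(zj[ord])^cfg$ks_weight_exponent
    es_up <- if (k_up) es_core(sort.int(inv[up_rows]), a, N) else NA_real_
    es_down <- if (k_down) es_core(sort.int(inv[down_rows]), a, N) else NA_real_
    raw[j] <- combine_es(es_up, es_down)
    null_up <- if (k_up) es_batch(P$up, a, N, pen_up) else rep(NA_real_, B)
    null_down <- if (k_down) es_batch(P$down, a, N, pen_down) else rep(NA_real_, B)
    nulls <- if (k_up == 0L) {
      -null_down
    } else if (k_down == 0L) {
      null_up
    } else {
      ifelse(sign(null_up) != sign(null_down), (null_up - null_down) / 2, 0)
    }
    pval[j] <- (sum(abs(nulls) >= abs(raw[j])) + 1) / (B + 1)
  }
  groups <- if (cfg$grouping == "cell_line") {
    paste(library$meta$cell_line, library$meta$pert_type, sep = ":")
  } else {
    rep("all", n_sig)
  }
  data.frame(signature_id = colnames(Z),
             compound_id = library$meta$compound_id,
             raw_score = raw,
             norm_score = normalize_scores(raw, groups),
             p_value = pval,
             fdr_q = fdr_adjust(pval),
             stringsAsFactors = FALSE)
}

# Similarity of a candidate alternative signature to the failing one:
# same cell line dominates, then same dose, then same exposure time.
meta_similarity <- function(target, candidates) {
  4L * (candidates$cell_line == target$cell_line) +
    2L * (candidates$dose == target$dose) +
    1L * (candidates$time_h == target$time_h)
}

#' Apply the five signature-selection criteria
#'
#' Retains signatures that (1) reverse the disease profile
#' (`norm_score < 0`), (2) reach `fdr_q < cfg$fdr_threshold`, (3) belong to
#' a compound perturbagen, (4) are not on the exclusion list, and (5) pass
#' library quality control. A signature failing only criterion 5 is
#' substituted by the QC-passing signature(s) of the same compound with the
#' most similar metadata (same cell line, then dose, then exposure time),
#' preferring those flagged high-quality; equally similar alternatives are
#' all retained.
#'
#' @param results screening results as from [screen_library()] (needs
#'   `signature_id`, `norm_score`, `fdr_q`).
#' @param meta signature metadata (the library's `meta` data.frame).
#' @param cfg a [screen_config()].
#' @return character vector of retained signature ids; substitutions are
#'   recorded in the `"substitutions"` attribute (data.frame with columns
#'   `failed_id`, `alternative_id`).
#' @export
apply_selection_criteria <- function(results, meta, cfg = screen_config()) {
  .assert(all(c("signature_id", "norm_score", "fdr_q") %in% names(results)),
          "results must carry signature_id, norm_score, fdr_q")
  m <- meta[match(results$signature_id, meta$signature_id), , drop = FALSE]
  .assert(!any(is.na(m$signature_id)), "results and meta are not joinable")
  c1 <- results$norm_score < 0
  c2 <- results$fdr_q < cfg$fdr_threshold
  c3 <- m$pert_type == "compound"
  c4 <- !(m$compound_id %in% cfg$exclusion_list)
  c5 <- m$qc_pass
  keep <- c1 & c2 & c3 & c4 & c5
  retained <- results$signature_id[keep]
  subs <- data.frame(failed_id = character(0), alternative_id = character(0),
                     stringsAsFactors = FALSE)
  needs_sub <- which(c1 & c2 & c3 & c4 & !c5)
  for (i in needs_sub) {
    target <- m[i, ]
    cand <- meta[meta$compound_id == target$compound_id &
                   meta$qc_pass &
                   meta$pert_type == "compound" &
                   meta$signature_id != target$signature_id, , drop = FALSE]
    if (nrow(cand) == 0L) next
    sim <- meta_similarity(target, cand)
    cand <- cand[sim == max(sim), , drop = FALSE]
    if (any(cand$high_quality)) cand <- cand[cand$high_quality, , drop = FALSE]
    subs <- rbind(subs, data.frame(failed_id = target$signature_id,
                                   alternative_id = cand$signature_id,
                                   stringsAsFactors = FALSE))
    retained <- c(retained, cand$signature_id)
  }
  retained <- unique(retained)
  attr(retained, "substitutions") <- subs
  retained
}
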