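# End-to-end orchestration: top-N query construction, connectivity screen
# across query sizes, the five selection criteria, and reversal ranking
# with permutation significance.

#' Screen a signature library and rank compounds for reversal
#'
#' Runs the full repurposing pipeline for one disease signature:
#' \enumerate{
#'   \item builds top-N up/down query sets for each size in `sizes`;
#'   \item screens every library signature with the weighted-KS
#'     connectivity score, group normalization, random-query empirical p
#'     and BH FDR, once per query size;
#'   \item applies the five selection criteria per size (negative
#'     normalized score, FDR below threshold, compound perturbagen, not
#'     excluded, QC-passing with alternative-signature substitution) and
#'     unions the per-size candidate sets;
#'   \item ranks signatures for reversal (signed KS, Spearman, Pearson over
#'     all genes and nested subsets, two-level rank averaging) and attaches
#'     pooled-permutation p-values.
#' }
#'
#' By default the ranking stage covers every structurally eligible
#' signature (compound perturbagen, not excluded, QC-passing) rather than
#' only the screened candidates: permutation rank significance is
#' calibrated against the library background, and ranks computed within a
#' small pre-selected set of strong reversers carry no signal of their
#' own. Set `rank_scope = "screened"` to rank only the screened set.
#'
#' @param disease a [disease_signature()].
#' @param library a [signature_library()].
#' @param sizes top-N query-set sizes.
#' @param screen_cfg a [screen_config()].
#' @param rank_cfg a [rank_config()]; defaults to `sizes` and the screen's
#'   seed.
#' @param rank_scope `"eligible"` (default) or `"screened"`.
#' @return list with elements `screen` (per-size screening results, long
#'   data.frame with a `query_n` column), `screened_ids` (signature ids
#'   passing the selection criteria at any size), `screened_compounds`,
#'   `ranking` (per-signature ranking with `perm_p`, `compound_best_rank`
#'   and a logical `screened` column), and `queries`.
#' @export
repurpose_pipeline <- function(disease, library,
                               sizes = c(25L, 50L, 100L, 150L, 250L),
                               screen_cfg = screen_config(),
                               rank_cfg = NULL,
                               rank_scope = c("eligible", "screened")) {
  rank_scope <- match.arg(rank_scope)
  if (is.null(rank_cfg)) {
    rank_cfg <- rank_config(sizes = sizes,
                            rng_seed = derive_seed(screen_cfg$rng_seed, 777L))
  }
  queries <- lapply(sizes, function(n) make_query_set(disease, n))
  names(queries) <- as.character(sizes)

  screens <- vector("list", length(sizes))
  screened_ids <- character(0)
  for (s in seq_along(sizes)) {
    cfg_s <- screen_cfg
    cfg_s$rng_seed <- derive_seed(screen_cfg$rng_seed, 1000L + s)
    res <- screen_library(queries[[s]], library, cfg_s)
    res$query_n <- sizes[s]
    screens[[s]] <- res
    screened_ids <- union(screened_ids,
                          apply_selection_criteria(res, library$meta, cfg_s))
  }
  screen_tab <- do.call(rbind, screens)

  meta <- library$meta
  eligible <- meta$signature_id[meta$pert_type == "compound" &
                                  !(meta$compound_id %in% screen_cfg$exclusion_list) &
                                  meta$qc_pass]
  rank_ids <- if (rank_scope == "eligible") eligible else screened_ids
  .assert(length(rank_ids) >= 2L, "fewer than two signatures to rank")
  ranking <- rank_compounds(disease, library, rank_ids, rank_cfg)
  screened_compounds <- unique(meta$compound_id[meta$signature_id %in% screened_ids])
  ranking$screened <- ranking$signature_id %in% screened_ids |
    ranking$compound_id %in% screened_compounds

  list(screen = screen_tab,
       screened_ids = screened_ids,
       screened_compounds = screened_compounds,
       ranking = ranking,
       queries = queries)
}
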