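# Synthetic-data generators with planted ground truth: disease signatures,
# compound libraries with known reversers, multi-tissue TWAS tables,
# prescription cohorts and 2x2 cohorts. All generators are pure functions
# of their parameters and seed, and leave the caller's RNG state untouched.

#' Specification of a synthetic compound-signature library
#'
#' Defaults describe the reference recovery setting used throughout the
#' package's tests: 200 compounds profiled in duplicate across cell lines,
#' five planted reversers mixing the standardized disease signature at
#' strength 0.8 with independent noise of SD 0.5, and a small fraction of
#' QC failures that never silences every replicate of a reverser.
#'
#' @param n_compounds number of distinct compounds.
#' @param replicates_per_compound replicate signatures per compound, cycled
#'   across `cell_lines`.
#' @param n_reversers compounds anti-correlated with the disease signature.
#' @param reversal_strength mixing weight of the (negated) standardized
#'   disease signature in a reverser, in `[0, 1]`.
#' @param n_concordant compounds positively correlated with the disease.
#' @param noise_sd SD of the independent noise added to every signature.
#' @param cell_lines cell line labels.
#' @param frac_qc_fail fraction of signatures flagged as failing QC.
#' @param rng_seed integer seed.
#' @param universe_drop_frac fraction of disease genes absent from the
#'   library universe (exercises the missing-gene path).
#' @return a list of class `library_spec`.
#' @export
library_spec <- function(n_compounds = 200L,
                         replicates_per_compound = 2L,
                         n_reversers = 5L,
                         reversal_strength = 0.8,
                         n_concordant = 0L,
                         noise_sd = 0.5,
                         cell_lines = c("A375", "MCF7", "PC3"),
                         frac_qc_fail = 0.05,
                         rng_seed = 1L,
                         universe_drop_frac = 0) {
  .assert(n_compounds >= 1 && replicates_per_compound >= 1,
          "need at least one compound and one replicate")
  .assert(n_reversers >= 0 && n_concordant >= 0 &&
            n_reversers + n_concordant <= n_compounds,
          "n_reversers + n_concordant must not exceed n_compounds")
  .assert(reversal_strength >= 0 && reversal_strength <= 1,
          "reversal_strength must lie in [0, 1]")
  .assert(noise_sd > 0, "noise_sd must be positive")
  .assert(frac_qc_fail >= 0 && frac_qc_fail <= 1, "frac_qc_fail must lie in [0, 1]")
  .assert(universe_drop_frac >= 0 && universe_drop_frac < 1,
          "universe_drop_frac must lie in [0, 1)")
  structure(list(n_compounds = as.integer(n_compounds),
                 replicates_per_compound = as.integer(replicates_per_compound),
                 n_reversers = as.integer(n_reversers),
                 reversal_strength = reversal_strength,
                 n_concordant = as.integer(n_concordant),
                 noise_sd = noise_sd,
                 cell_lines = as.character(cell_lines),
                 frac_qc_fail = frac_qc_fail,
                 rng_seed = as.integer(rng_seed),
                 universe_drop_frac = universe_drop_frac),
            class = "library_spec")
}

#' Specification of a synthetic prescription cohort
#'
#' @param n_subjects cohort size.
#' @param frac_trd fraction of subjects constructed to satisfy the
#'   two-switch TRD rule.
#' @param frac_near_miss fraction violating exactly one criterion (a 41-day
#'   episode, a 99-day gap, or a single switch).
#' @param rng_seed integer seed.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 500L, frac_trd = 0.3,
                        frac_near_miss = 0.3, rng_seed = 1L) {
  .assert(n_subjects >= 1, "n_subjects must be positive")
  .assert(frac_trd >= 0 && frac_near_miss >= 0 && frac_trd + frac_near_miss <= 1,
          "frac_trd + frac_near_miss must not exceed 1")
  structure(list(n_subjects = as.integer(n_subjects), frac_trd = frac_trd,
                 frac_near_miss = frac_near_miss, rng_seed = as.integer(rng_seed)),
            class = "cohort_spec")
}

#' Generate a disease expression signature
#'
#' Null genes draw `z ~ N(0, 1)`; causal genes draw
#' `z ~ N(0, sqrt(1 + effect_sd^2))`, giving a minority of large-effect
#' genes over a standard-normal background, as in TWAS summary statistics.
#'
#' @param n_genes number of genes (ids `g000001`, ...).
#' @param n_causal number of large-effect genes.
#' @param effect_sd additional SD of causal effects.
#' @param seed integer seed.
#' @param phenotype_id phenotype label.
#' @return a [disease_signature()].
#' @export
gen_disease_signature <- function(n_genes, n_causal, effect_sd = 3,
                                  seed = 1L, phenotype_id = "synthetic") {
  .assert(n_causal <= n_genes, "n_causal must not exceed n_genes")
  .assert(effect_sd > 0, "effect_sd must be positive")
  genes <- sprintf("g%06d", seq_len(n_genes))
  z <- with_seed(seed, {
    causal <- sample.int(n_genes, n_causal)
    zz <- stats::rnorm(n_genes)
    zz[causal] <- stats::rnorm(n_causal, sd = sqrt(1 + effect_sd^2))
    zz
  })
  disease_signature(phenotype_id, stats::setNames(z, genes))
}

#' Generate a compound-signature library with planted reversers
#'
#' Reverser compounds mix the negated standardized disease signature at
#' `reversal_strength` with independent `N(0, noise_sd^2)` noise (expected
#' Pearson correlation with the disease
#' `-rho / sqrt(rho^2 + noise_sd^2)`); concordant compounds are the
#' positive analogue; null compounds are pure `N(0, 1)` noise. Each
#' compound is emitted `replicates_per_compound` times across cell lines
#' with independent noise. A fraction of signatures is flagged as failing
#' QC, but never all replicates of a reverser; when QC failures are
#' requested and no reverser replicate failed by chance, one reverser
#' replicate is flagged so the alternative-signature substitution path is
#' always exercised.
#'
#' @param disease a [disease_signature()] defining the gene universe.
#' @param spec a [library_spec()].
#' @return list with `library` (a [signature_library()]) and `truth`
#'   (named character vector compound_id -> `"reverser"`, `"concordant"`
#'   or `"null"`).
#' @export
gen_library <- function(disease, spec = library_spec()) {
  .assert(inherits(spec, "library_spec"), "spec must be a library_spec")
  genes <- names(disease$z)
  n_cpd <- spec$n_compounds
  reps <- spec$replicates_per_compound
  with_seed(spec$rng_seed, {
    if (spec$universe_drop_frac > 0) {
      keep <- sort(sample.int(length(genes),
                              round((1 - spec$universe_drop_frac) * length(genes))))
      genes <- genes[keep]
    }
    n_genes <- length(genes)
    dz <- disease$z[genes]
    d_std <- (dz - mean(dz)) / stats::sd(dz)
    cpd_ids <- sprintf("cpd%04d", seq_len(n_cpd))
    roles <- rep("null", n_cpd)
    special <- sample.int(n_cpd, spec$n_reversers + spec$n_concordant)
    roles[special[seq_len(spec$n_reversers)]] <- "reverser"
    if (spec$n_concordant > 0) {
      roles[special[spec$n_reversers + seq_len(spec$n_concordant)]] <- "concordant"
    }
    n_sig <- n_cpd * reps
    sig_cpd <- rep(cpd_ids, each = reps)
    sig_role <- rep(roles, each = reps)
    sig_rep <- rep(seq_len(reps), times = n_cpd)
    cell <- spec$cell_lines[(sig_rep - 1L) %% length(spec$cell_lines) + 1L]
    sig_ids <- paste0(sig_cpd, "_", cell, "_r", sig_rep)
    Z <- matrix(stats::rnorm(n_genes * n_sig), n_genes, n_sig,
                dimnames = list(genes, sig_ids))
    mixed <- sig_role != "null"
    if (any(mixed)) {
      Z[, mixed] <- Z[, mixed] * spec$noise_sd
      signs <- ifelse(sig_role[mixed] == "reverser", -1, 1)
      Z[, mixed] <- Z[, mixed] +
        outer(d_std, signs * spec$reversal_strength)
    }
    qc_pass <- stats::runif(n_sig) >= spec$frac_qc_fail
    for (cpd in cpd_ids[roles == "reverser"]) {
      idx <- which(sig_cpd == cpd)
      if (!any(qc_pass[idx])) qc_pass[idx[1L]] <- TRUE
    }
    if (spec$frac_qc_fail > 0 && spec$n_reversers > 0 && reps >= 2L &&
        all(qc_pass[sig_role == "reverser"])) {
      qc_pass[which(sig_role == "reverser")[1L]] <- FALSE
    }
    high_quality <- qc_pass & stats::runif(n_sig) < 0.5
    meta <- data.frame(signature_id = sig_ids,
                       compound_id = sig_cpd,
                       pert_type = "compound",
                       cell_line = cell,
                       dose = sample(c("0.1 uM", "1 uM", "10 uM"), n_sig,
                                     replace = TRUE),
                       time_h = sample(c(6, 24), n_sig, replace = TRUE),
                       qc_pass = qc_pass,
                       high_quality = high_quality,
                       stringsAsFactors = FALSE)
    list(library = signature_library(Z, meta),
         truth = stats::setNames(roles, cpd_ids))
  })
}

#' Generate a multi-tissue TWAS feature table
#'
#' Every gene receives features in a random non-empty subset of the panels;
#' per-panel z-scores jitter the disease z, cross-validation R-squared is
#' drawn uniformly, and exactly one panel per gene (the maximal-cv carrier)
#' keeps the disease z unchanged, so [collapse_features()] recovers the
#' disease signature exactly.
#'
#' @param disease a [disease_signature()].
#' @param panels character vector of panel names (at least one).
#' @param seed integer seed.
#' @param jitter_sd SD of the z jitter on non-carrier panels.
#' @return a validated feature data.frame (see [twas_features()]).
#' @export
gen_twas_table <- function(disease, panels, seed = 1L, jitter_sd = 0.5) {
  .assert(length(panels) >= 1L, "need at least one panel")
  genes <- names(disease$z)
  with_seed(seed, {
    rows <- lapply(seq_along(genes), function(i) {
      k <- sample.int(length(panels), 1L)
      pan <- sort(sample(panels, k))
      cv <- stats::runif(k, 0.01, 0.6)
      carrier <- sample.int(k, 1L)
      cv[carrier] <- max(cv) + stats::runif(1L, 0.01, 0.1)
      z <- disease$z[i] + stats::rnorm(k, sd = jitter_sd)
      z[carrier] <- disease$z[i]
      data.frame(phenotype = disease$phenotype_id, gene_id = genes[i],
                 panel_id = pan, z = z, cv_r2 = pmin(cv, 1),
                 model_significant = TRUE, stringsAsFactors = FALSE)
    })
    twas_features(do.call(rbind, rows))
  })
}

# One qualifying episode: prescriptions on start, start+28, start+56.
.episode_rx <- function(person, drug, start) {
  data.frame(person_id = person, drug = drug,
             issue_date = start + c(0L, 28L, 56L),
             stringsAsFactors = FALSE)
}

#' Generate a prescription cohort with known TRD labels
#'
#' TRD subjects receive three qualifying episodes (56-day span each) of
#' distinct antidepressants with inter-episode gaps of at most 98 days.
#' Near-miss subjects violate exactly one criterion: a 41-day episode
#' (one day short of qualifying), a 99-day gap (one day too long), or only
#' a single switch. Remaining subjects receive zero or one episode.
#'
#' @param spec a [cohort_spec()].
#' @return list with `prescriptions` (data.frame `person_id`, `drug`,
#'   `issue_date`) and `truth` (named logical vector person_id -> intended
#'   TRD label).
#' @export
gen_prescriptions <- function(spec = cohort_spec()) {
  .assert(inherits(spec, "cohort_spec"), "spec must be a cohort_spec")
  drugs <- c("citalopram", "fluoxetine", "sertraline",
             "venlafaxine", "mirtazapine", "amitriptyline")
  n <- spec$n_subjects
  n_trd <- round(spec$frac_trd * n)
  n_miss <- round(spec$frac_near_miss * n)
  with_seed(spec$rng_seed, {
    ids <- sprintf("p%05d", seq_len(n))
    kind <- rep("other", n)
    kind[seq_len(n_trd)] <- "trd"
    if (n_miss > 0) kind[n_trd + seq_len(n_miss)] <- "near_miss"
    kind <- sample(kind)
    rx <- list()
    truth <- stats::setNames(rep(FALSE, n), ids)
    for (i in seq_len(n)) {
      origin <- as.Date("2015-01-01") + sample.int(365L, 1L)
      dd <- sample(drugs, 3L)
      if (kind[i] == "trd") {
        g1 <- sample.int(98L, 1L)
        g2 <- sample.int(98L, 1L)
        e1 <- .episode_rx(ids[i], dd[1L], origin)
        e2 <- .episode_rx(ids[i], dd[2L], origin + 56L + g1)
        e3 <- .episode_rx(ids[i], dd[3L], origin + 112L + g1 + g2)
        rx[[length(rx) + 1L]] <- rbind(e1, e2, e3)
        truth[i] <- TRUE
      } else if (kind[i] == "near_miss") {
        mode <- sample(c("short_episode", "long_gap", "one_switch"), 1L)
        if (mode == "short_episode") {
          # middle episode spans only 41 days -> non-qualifying; the
          # flanking qualifying episodes end up > 98 days apart
          e1 <- .episode_rx(ids[i], dd[1L], origin)
          e2 <- data.frame(person_id = ids[i], drug = dd[2L],
                           issue_date = origin + 84L + c(0L, 41L),
                           stringsAsFactors = FALSE)
          e3 <- .episode_rx(ids[i], dd[3L], origin + 160L)
          rx[[length(rx) + 1L]] <- rbind(e1, e2, e3)
        } else if (mode == "long_gap") {
          e1 <- .episode_rx(ids[i], dd[1L], origin)
          e2 <- .episode_rx(ids[i], dd[2L], origin + 56L + 99L)
          e3 <- .episode_rx(ids[i], dd[3L], origin + 112L + 99L +
                              sample.int(98L, 1L))
          rx[[length(rx) + 1L]] <- rbind(e1, e2, e3)
        } else {
          e1 <- .episode_rx(ids[i], dd[1L], origin)
          e2 <- .episode_rx(ids[i], dd[2L], origin + 56L + sample.int(98L, 1L))
          rx[[length(rx) + 1L]] <- rbind(e1, e2)
        }
      } else {
        n_ep <- sample(0:1, 1L)
        if (n_ep == 1L) {
          rx[[length(rx) + 1L]] <- .episode_rx(ids[i], dd[1L], origin)
        } else {
          rx[[length(rx) + 1L]] <- data.frame(person_id = ids[i], drug = dd[1L],
                                              issue_date = origin,
                                              stringsAsFactors = FALSE)
        }
      }
    }
    list(prescriptions = do.call(rbind, rx), truth = truth)
  })
}

#' Generate a 2x2 subtype-by-TRD table from a logistic model
#'
#' Exposure (subtype membership) is Bernoulli(`exposure_frac`); the outcome
#' is Bernoulli with `logit(p) = logit(baseline_risk) +
#' log(or_true) * exposure`.
#'
#' @param n cohort size.
#' @param baseline_risk outcome probability among the unexposed, in (0, 1).
#' @param or_true true odds ratio.
#' @param exposure_frac exposure probability, in \[0, 1\].
#' @param seed integer seed.
#' @return list with cells `a` (exposed case), `b` (exposed control),
#'   `c` (unexposed case), `d` (unexposed control).
#' @export
gen_fourfold <- function(n, baseline_risk, or_true, exposure_frac, seed = 1L) {
  .assert(baseline_risk > 0 && baseline_risk < 1, "baseline_risk must lie in (0, 1)")
  .assert(or_true > 0, "or_true must be positive")
  .assert(exposure_frac >= 0 && exposure_frac <= 1, "exposure_frac must lie in [0, 1]")
  with_seed(seed, {
    exposed <- stats::runif(n) < exposure_frac
    logit_p <- stats::qlogis(baseline_risk) + log(or_true) * exposed
    case <- stats::runif(n) < stats::plogis(logit_p)
    list(a = sum(exposed & case), b = sum(exposed & !case),
         c = sum(!exposed & case), d = sum(!exposed & !case))
  })
}
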