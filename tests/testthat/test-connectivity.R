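# Connectivity screening: weighted-KS enrichment, score combination,
# normalization, empirical p-values, FDR and the selection criteria.

test_that("weighted_es reproduces hand-derived running-sum extrema", {
  z <- toy_signature_z()
  expect_equal(weighted_es(c("g1", "g2"), z), 1.0)
  expect_equal(weighted_es(c("g9", "g10"), z), -1.0)
  expect_equal(weighted_es(c("g4", "g5"), z), 0.625)
  expect_error(weighted_es(c("absent"), z), "overlap")
  expect_error(weighted_es(names(z), z), "universe")
})

test_that("weighted_es agrees exactly with the brute-force oracle", {
  set.seed(19)
  for (rep in 1:200) {
    n <- sample(8:50, 1)
    z <- setNames(round(rnorm(n), 3), sprintf("G%03d", seq_len(n)))
    k <- sample.int(min(10, n - 1), 1)
    gs <- sample(names(z), k)
    expo <- sample(c(0, 0.5, 1, 2), 1)
    # agreement to numerical precision (summation order differs)
    expect_matches_oracle(weighted_es(gs, z, expo), oracle_es(gs, z, expo))
  }
})

test_that("unweighted enrichment of random sets is centred at zero", {
  set.seed(23)
  z <- setNames(rnorm(60), sprintf("G%03d", 1:60))
  draws <- replicate(2000, weighted_es(sample(names(z), 8), z, exponent = 0))
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws)), 3 * se)
})

test_that("connectivity_score combines up/down enrichment by the sign rule", {
  z <- toy_signature_z()
  # perfect reversal: up genes at the bottom, down genes at the top
  expect_equal(connectivity_score(toy_query(c("g9", "g10"), c("g1", "g2")), z), -1.0)
  # perfect mimicry
  expect_equal(connectivity_score(toy_query(c("g1", "g2"), c("g9", "g10")), z), 1.0)
  # same-sign components null out
  expect_equal(connectivity_score(toy_query(c("g1", "g2"), c("g3", "g4")), z), 0)
  # one-sided queries pass through (down negated)
  expect_equal(connectivity_score(toy_query(c("g1", "g2"), character(0)), z),
               weighted_es(c("g1", "g2"), z))
  expect_equal(connectivity_score(toy_query(character(0), c("g1", "g2")), z),
               -weighted_es(c("g1", "g2"), z))
})

test_that("swapping up and down query sets negates the connectivity score", {
  set.seed(29)
  for (rep in 1:20) {
    z <- setNames(rnorm(40), sprintf("G%03d", 1:40))
    gs <- sample(names(z), 12)
    q <- toy_query(gs[1:5], gs[6:12])
    swapped <- toy_query(q$down, q$up)
    expect_equal(connectivity_score(q, z), -connectivity_score(swapped, z))
  }
})

test_that("query genes outside the universe are dropped, rejecting below 50%", {
  z <- toy_signature_z()
  q <- toy_query(c("g1", "g2", "x1"), c("g9", "x2"))  # 3/5 known
  expect_warning(s <- connectivity_score(q, z), "absent")
  q_bad <- toy_query(c("g1", "x1", "x2"), c("x3", "x4", "x5"))  # 1/6 known
  expect_error(suppressWarnings(connectivity_score(q_bad, z)), "50%")
})

test_that("normalize_scores divides by same-signed group means", {
  expect_equal(normalize_scores(c(2, 4, -3)), c(2 / 3, 4 / 3, -1))
  expect_equal(normalize_scores(c(1, 3)), c(0.5, 1.5))
  expect_equal(normalize_scores(c(-2, -2), groups = c("a", "b")), c(-1, -1))
  expect_equal(normalize_scores(c(0, 2, 4)), c(0, 2 / 3, 4 / 3))  # zero stays
})

test_that("normalized same-signed scores average to +/-1 within every group", {
  set.seed(31)
  for (rep in 1:30) {
    n <- sample(5:60, 1)
    scores <- rnorm(n)
    groups <- sample(letters[1:4], n, replace = TRUE)
    ns <- normalize_scores(scores, groups)
    expect_equal(sign(ns), sign(scores))
    for (g in unique(groups)) {
      s <- ns[groups == g]
      if (any(s > 0)) expect_equal(mean(s[s > 0]), 1, tolerance = 1e-12)
      if (any(s < 0)) expect_equal(mean(s[s < 0]), -1, tolerance = 1e-12)
    }
  }
})

test_that("empirical_p follows the (k+1)/(n+1) convention", {
  set.seed(37)
  z <- setNames(rnorm(100), sprintf("G%03d", 1:100))
  q <- toy_query(sample(names(z), 5), sample(setdiff(names(z), ""), 5))
  cfg <- screen_config(null_queries = 199, rng_seed = 4)
  # a score more extreme than any achievable null (|score| <= 1)
  expect_equal(empirical_p(1.5, q, z, cfg), 1 / 200)
  # a zero score is never more extreme than any null
  expect_equal(empirical_p(0, q, z, cfg), 1)
  # reproducible under the same config
  obs <- connectivity_score(q, z)
  expect_identical(empirical_p(obs, q, z, cfg), empirical_p(obs, q, z, cfg))
})

test_that("fdr_adjust matches a hand-rolled step-up BH", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(fdr_adjust(0.2), 0.2)
  expect_equal(fdr_adjust(c(1, 1)), c(1, 1))
  expect_error(fdr_adjust(c(0.5, 0)), "0, 1")
  set.seed(41)
  for (rep in 1:20) {
    p <- runif(sample(2:50, 1))
    expect_equal(fdr_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("selection criteria retain negative, significant, clean compound signatures", {
  z <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(sprintf("G%02d", 1:20), paste0("s", 1:6)))
  lib <- toy_library(z, compound_id = c("c1", "c2", "c3", "c4", "c5", "c5"),
                     pert_type = c(rep("compound", 4), "compound", "compound"),
                     qc_pass = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE))
  res <- data.frame(signature_id = paste0("s", 1:6),
                    norm_score = c(-1.2, -1.2, 1.1, -1.2, -1.2, 0.4),
                    fdr_q = c(0.05, 0.20, 0.05, 0.05, 0.05, 0.5))
  cfg <- screen_config(exclusion_list = "c4")
  kept <- apply_selection_criteria(res, lib$meta, cfg)
  # s1 passes everything; s2 fails FDR; s3 is positively connected;
  # s4 is excluded; s5 fails QC only -> substituted by s6 (same compound)
  expect_setequal(as.character(kept), c("s1", "s6"))
  subs <- attr(kept, "substitutions")
  expect_equal(subs$failed_id, "s5")
  expect_equal(subs$alternative_id, "s6")
})

test_that("QC substitution prefers metadata similarity then high quality, keeping ties", {
  z <- matrix(rnorm(10 * 5), 10, 5,
              dimnames = list(sprintf("G%02d", 1:10), paste0("s", 1:5)))
  lib <- toy_library(z, compound_id = "c1",
                     cell_line = c("A375", "A375", "A375", "MCF7", "A375"),
                     dose = c("10 uM", "10 uM", "10 uM", "10 uM", "1 uM"),
                     qc_pass = c(FALSE, TRUE, TRUE, TRUE, TRUE),
                     high_quality = c(FALSE, FALSE, FALSE, TRUE, FALSE))
  res <- data.frame(signature_id = "s1", norm_score = -2, fdr_q = 0.01)
  kept <- apply_selection_criteria(res, lib$meta, screen_config())
  # s2 and s3 tie on (cell line, dose); s4 is high quality but a different
  # cell line; s5 matches cell line but not dose
  expect_setequal(as.character(kept), c("s2", "s3"))

  # genetic perturbagens are never selected even with a reversing score
  lib2 <- toy_library(z[, 1:2], compound_id = c("g1", "c2"),
                      pert_type = c("genetic", "compound"))
  res2 <- data.frame(signature_id = c("s1", "s2"), norm_score = c(-2, -2),
                     fdr_q = c(0.01, 0.01))
  expect_equal(as.character(apply_selection_criteria(res2, lib2$meta, screen_config())),
               "s2")
})

test_that("screen_library produces coherent scores, p-values and q-values", {
  dis <- gen_disease_signature(300, 30, 3, seed = 8)
  gl <- gen_library(dis, library_spec(n_compounds = 15, replicates_per_compound = 1,
                                      n_reversers = 2, rng_seed = 9))
  q <- make_query_set(dis, 50)
  cfg <- screen_config(null_queries = 200, rng_seed = 10, grouping = "global")
  res <- screen_library(q, gl$library, cfg)
  expect_equal(nrow(res), 15L)
  expect_true(all(abs(res$raw_score) <= 1))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_true(all(res$fdr_q > 0 & res$fdr_q <= 1))
  # normalization preserves signs
  expect_equal(sign(res$norm_score), sign(res$raw_score))
  # planted reversers carry the most negative normalized scores
  rev_ids <- res$signature_id[res$compound_id %in%
                                names(gl$truth)[gl$truth == "reverser"]]
  expect_true(max(res$norm_score[res$signature_id %in% rev_ids]) <
                min(res$norm_score[!res$signature_id %in% rev_ids &
                                     res$norm_score < 0]))
  # raw score equals the standalone connectivity_score for one signature
  j <- res$signature_id[1]
  expect_equal(res$raw_score[1],
               connectivity_score(q, gl$library$z[, j]))
})
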