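# TWAS post-processing: z-to-p conversion, feature collapsing,
# significance filtering, query-set construction and symbol mapping.

test_that("z_to_p reproduces reference TWAS z/p pairs at their reported precision", {
  # rows whose printed z (2 d.p.) and p are arithmetically consistent
  expect_equal(z_to_p(0.47), 0.64, tolerance = 0.015)
  expect_equal(z_to_p(-4.85), 1.23e-6, tolerance = 0.015)
  expect_equal(z_to_p(4.67), 3.02e-6, tolerance = 0.015)
  expect_equal(z_to_p(4.05), 5.11e-5, tolerance = 0.015)
  # rows limited by the 2 d.p. rounding of z (dp/p ~ z * dz): printed
  # precision bound only
  expect_equal(z_to_p(-4.63), 3.58e-6, tolerance = 0.025)
  expect_equal(z_to_p(4.83), 1.34e-6, tolerance = 0.025)
  expect_equal(z_to_p(3.57), 3.64e-4, tolerance = 0.025)
})

test_that("z_to_p is exact against an erfc evaluation, symmetric and monotone", {
  z <- seq(0, 8, by = 0.25)
  expect_equal(z_to_p(z), pracma::erfc(z / sqrt(2)), tolerance = 1e-10)
  expect_identical(z_to_p(3.2), z_to_p(-3.2))
  expect_identical(z_to_p(0), 1)
  expect_true(all(diff(z_to_p(z)) < 0))
  expect_error(z_to_p(NA_real_), "finite")
  expect_error(z_to_p(Inf), "finite")
})

test_that("twas_features fills missing p from z and rejects inconsistent p", {
  df <- data.frame(gene_id = c("a", "b"), panel_id = c("p1", "p1"),
                   z = c(1.5, -2), p = c(NA, NA))
  out <- twas_features(df)
  expect_equal(out$p, 2 * pnorm(-abs(df$z)))

  bad <- data.frame(gene_id = "a", panel_id = "p1", z = 1.5, p = 0.5)
  expect_error(twas_features(bad), "inconsistent")
  ok <- data.frame(gene_id = "a", panel_id = "p1", z = 1.5,
                   p = 2 * pnorm(-1.5) * 1.005)  # within 1% guard
  expect_silent(twas_features(ok))
})

test_that("collapse_features keeps the max-CV feature per gene with a lexicographic tie rule", {
  f <- data.frame(phenotype = "TRD",
                  gene_id = c("G", "G", "H"),
                  panel_id = c("panelA", "panelB", "panelC"),
                  z = c(2.1, 1.7, -1.0),
                  cv_r2 = c(0.05, 0.12, 0.3))
  sig <- collapse_features(f)
  expect_equal(unname(sig$z["G"]), 1.7)
  expect_equal(unname(sig$panel["G"]), "panelB")
  expect_equal(length(sig$z), 2L)

  tie <- data.frame(phenotype = "TRD", gene_id = "G",
                    panel_id = c("panelB", "panelA"), z = c(1, 2),
                    cv_r2 = c(0.2, 0.2))
  expect_equal(unname(collapse_features(tie)$panel["G"]), "panelA")

  single <- data.frame(phenotype = "TRD", gene_id = c("x", "y"),
                       panel_id = "p", z = c(1, 2), cv_r2 = c(0.1, 0.2))
  expect_equal(collapse_features(single)$z, c(x = 1, y = 2))

  expect_warning(collapse_features(f[0, ]), "empty")
  f$cv_r2[1] <- NA
  expect_error(collapse_features(f), "cv_r2")
})

test_that("collapse_features conserves the distinct gene count on random tables", {
  set.seed(7)
  for (rep in 1:10) {
    n_gene <- sample(5:40, 1)
    genes <- sprintf("g%03d", sample.int(500, n_gene))
    f <- do.call(rbind, lapply(genes, function(g) {
      k <- sample.int(4, 1)
      data.frame(phenotype = "x", gene_id = g,
                 panel_id = sample(paste0("p", 1:6), k),
                 z = rnorm(k), cv_r2 = runif(k))
    }))
    f <- f[sample.int(nrow(f)), ]
    sig <- collapse_features(f)
    expect_setequal(names(sig$z), genes)
    # retained cv_r2 is the per-gene maximum
    best <- tapply(f$cv_r2, f$gene_id, max)
    retained <- f[paste(f$gene_id, f$panel_id) %in%
                    paste(names(sig$panel), sig$panel), ]
    expect_equal(tapply(retained$cv_r2, retained$gene_id, max)[names(best)], best)
  }
})

test_that("significance_filter applies the transcriptome-wide threshold", {
  f <- data.frame(gene_id = c("a", "b", "c"), panel_id = "p",
                  z = c(-4.85, 4.79, 4.05),
                  p = c(1.23e-6, 1.65e-6, 5.11e-5))
  kept <- significance_filter(f)  # default alpha = 1.37e-6
  expect_equal(kept$gene_id, "a")
  expect_equal(nrow(significance_filter(f, alpha = 1)), 3L)
  expect_equal(nrow(significance_filter(f[0, ], alpha = 0.5)), 0L)
  expect_error(significance_filter(f, alpha = 0), "alpha")
  expect_error(significance_filter(f, alpha = 1.5), "alpha")
})

test_that("make_query_set selects top-|z| genes and splits them by sign", {
  sig <- disease_signature("x", c(gA = 3, gB = -2, gC = 1))
  q <- make_query_set(sig, 2)
  expect_equal(q$up, "gA")
  expect_equal(q$down, "gB")

  q_all <- make_query_set(sig, 10)
  expect_setequal(c(q_all$up, q_all$down), c("gA", "gB", "gC"))

  tie <- disease_signature("x", c(gB = -3, gA = 3))
  q1 <- make_query_set(tie, 1)  # |z| tie broken by gene id
  expect_equal(q1$up, "gA")
  expect_equal(q1$down, character(0))

  withzero <- disease_signature("x", c(gA = 2, gB = 0))
  expect_warning(q0 <- make_query_set(withzero, 2), "z = 0")
  expect_equal(c(q0$up, q0$down), "gA")

  expect_error(make_query_set(sig, 0), "positive")
})

test_that("query sets nest monotonically as n grows", {
  set.seed(11)
  sig <- gen_disease_signature(400, 30, 3, seed = 5)
  sizes <- c(10, 25, 60, 120, 400)
  qs <- lapply(sizes, function(n) make_query_set(sig, n))
  for (i in seq_len(length(qs) - 1)) {
    expect_true(all(qs[[i]]$up %in% qs[[i + 1]]$up))
    expect_true(all(qs[[i]]$down %in% qs[[i + 1]]$down))
  }
  # disjointness and size bound
  for (q in qs) {
    expect_length(intersect(q$up, q$down), 0)
    expect_lte(length(q$up) + length(q$down), q$n_requested)
  }
})

test_that("map_symbols partitions symbols into mapped and unmapped", {
  tab <- c(S1 = "111")
  out <- map_symbols(c("S1", "S2"), tab)
  expect_equal(out$mapped, c(S1 = "111"))
  expect_equal(out$unmapped, "S2")

  empty <- map_symbols(character(0), tab)
  expect_length(empty$mapped, 0)
  expect_length(empty$unmapped, 0)

  dup <- map_symbols(c("S2", "S2", "S1"), tab)
  expect_equal(dup$unmapped, "S2")  # deduplicated, reported once
  expect_error(map_symbols("S1", character(0)), "non-empty")
})

test_that("signature and TWAS tables round-trip through their file formats", {
  sig <- gen_disease_signature(50, 5, 3, seed = 2, phenotype_id = "TRD")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature(sig, path)
  back <- read_signature(path, "TRD")
  expect_equal(back$z, sig$z)

  tw <- gen_twas_table(sig, c("brain", "blood"), seed = 3)
  tw_path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(tw, tw_path, sep = "\t", quote = FALSE, row.names = FALSE)
  back_tw <- read_twas(tw_path)
  expect_equal(back_tw$z, tw$z)
  expect_equal(collapse_features(back_tw)$z[names(sig$z)], sig$z)
})
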