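# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use literal, unoptimized formulations so they share no code
# with the implementation they check.

# Literal weighted-KS running sum: walk the ranked list one gene at a time.
oracle_es <- function(gene_set, z, exponent = 1) {
  genes <- names(z)
  ord <- order(-z, genes)
  ranked <- genes[ord]
  zr <- z[ord]
  hit <- ranked %in% gene_set
  n_miss <- sum(!hit)
  w <- unname(abs(zr)^exponent)
  denom <- sum(w[hit])
  running <- 0
  best_max <- -Inf
  best_min <- Inf
  for (i in seq_along(ranked)) {
    running <- running + if (hit[i]) w[i] / denom else -1 / n_miss
    best_max <- max(best_max, running)
    best_min <- min(best_min, running)
  }
  # on an exact magnitude tie the positive extremum is reported
  out <- if (abs(best_max) >= abs(best_min)) best_max else best_min
  structure(out, extrema = c(best_max, best_min))
}

# TRUE when the two running-sum extrema tie in magnitude, in which case the
# sign convention is decided at machine precision and only |value| is
# comparable across independent implementations.
oracle_tied <- function(oracle_value, tol = 1e-9) {
  ex <- attr(oracle_value, "extrema")
  isTRUE(all.equal(abs(ex[1]), abs(ex[2]), tolerance = tol))
}

# Compare an implementation value against an extremum-style oracle value:
# signed equality normally, magnitude equality on a magnitude tie.
expect_matches_oracle <- function(value, oracle_value, tolerance = 1e-12) {
  if (oracle_tied(oracle_value)) {
    expect_equal(abs(value), abs(as.numeric(oracle_value)), tolerance = tolerance)
  } else {
    expect_equal(value, as.numeric(oracle_value), tolerance = tolerance)
  }
}

# Literal Benjamini-Hochberg step-up: q_i = min over j with p_(j) >= p_(i)
# of p_(j) * m / j, computed from the sorted vector.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  running_min <- Inf
  for (j in m:1) {
    running_min <- min(running_min, ps[j] * m / j)
    q[o[j]] <- min(running_min, 1)
  }
  q
}

# Literal signed two-sample KS: evaluate both ECDFs at every pooled point.
oracle_ks_signed <- function(up_vals, down_vals) {
  pts <- sort(unique(c(up_vals, down_vals)))
  gap <- vapply(pts, function(t) {
    mean(down_vals <= t) - mean(up_vals <= t)
  }, numeric(1))
  gmax <- max(gap)
  gmin <- min(gap)
  out <- if (abs(gmax) >= abs(gmin)) gmax else gmin
  structure(out, extrema = c(gmax, gmin))
}

# Tiny deterministic ten-gene signature used by several worked examples.
toy_signature_z <- function() {
  stats::setNames(c(5, 4, 3, 2, 1, -1, -2, -3, -4, -5), paste0("g", 1:10))
}

toy_query <- function(up, down, n = length(up) + length(down)) {
  structure(list(up = up, down = down, n_requested = as.integer(n)),
            class = "query_set")
}

# Minimal signature library: z matrix plus metadata defaulting to
# QC-passing compound signatures in one cell line.
toy_library <- function(z, compound_id = colnames(z),
                        cell_line = "A375", pert_type = "compound",
                        qc_pass = TRUE, high_quality = FALSE,
                        dose = "10 uM", time_h = 24) {
  n <- ncol(z)
  meta <- data.frame(signature_id = colnames(z),
                     compound_id = rep_len(compound_id, n),
                     pert_type = rep_len(pert_type, n),
                     cell_line = rep_len(cell_line, n),
                     dose = rep_len(dose, n),
                     time_h = rep_len(time_h, n),
                     qc_pass = rep_len(qc_pass, n),
                     high_quality = rep_len(high_quality, n),
                     stringsAsFactors = FALSE)
  signature_library(z, meta)
}
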