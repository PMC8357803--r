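# EHR phenotyping: antidepressant treatment episodes from prescription
# records, the two-switch treatment-resistance rule, and 2x2 odds-ratio
# association of depression subtypes with TRD.

#' Read prescription records
#'
#' Comma-separated `person_id,drug,issue_date` with ISO-8601 dates.
#' Rows with unparsable dates are rejected with a warning and reported in
#' the `"rejected"` attribute.
#'
#' @param path file path.
#' @return data.frame with columns `person_id`, `drug`, `issue_date`
#'   (`Date`).
#' @export
read_prescriptions <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .assert(all(c("person_id", "drug", "issue_date") %in% names(df)),
          "prescriptions need columns person_id, drug, issue_date")
  parsed <- as.Date(as.character(df$issue_date), format = "%Y-%m-%d")
  bad <- is.na(parsed)
  if (any(bad)) {
    warning(sum(bad), " prescription row(s) with unparsable dates rejected")
  }
  out <- df[!bad, , drop = FALSE]
  out$issue_date <- parsed[!bad]
  attr(out, "rejected") <- df[bad, , drop = FALSE]
  out
}

#' Build per-drug treatment episodes from prescriptions
#'
#' Within each person and drug, consecutive prescriptions at most
#' `gap_days` apart (14 weeks by default, the continuity bound) merge into
#' one episode; a longer gap starts a new episode. Episode duration is the
#' span from first to last issue date (dosage coverage is unavailable in
#' issue-date records), and an episode qualifies when it lasts at least 42
#' days (six consecutive weeks).
#'
#' @param prescriptions data.frame with `person_id`, `drug`, `issue_date`
#'   (coercible to `Date`).
#' @param gap_days maximum within-episode gap between consecutive
#'   prescriptions, in days.
#' @param coverage_days optional per-prescription nominal coverage added to
#'   the last issue date of each episode (0 = span only).
#' @return data.frame with one row per episode: `person_id`, `drug`,
#'   `start_date`, `end_date`, `n_prescriptions`, `duration_days`,
#'   `qualifying`.
#' @export
build_episodes <- function(prescriptions, gap_days = 98L, coverage_days = 0L) {
  .assert(is.data.frame(prescriptions) &&
            all(c("person_id", "drug", "issue_date") %in% names(prescriptions)),
          "prescriptions need columns person_id, drug, issue_date")
  .assert(all(nzchar(as.character(prescriptions$drug))), "drug names must be non-empty")
  rx <- prescriptions
  rx$issue_date <- as.Date(rx$issue_date)
  bad <- is.na(rx$issue_date)
  if (any(bad)) {
    warning(sum(bad), " prescription row(s) with unparsable dates rejected")
    rx <- rx[!bad, , drop = FALSE]
  }
  rx <- rx[order(rx$person_id, rx$drug, rx$issue_date), , drop = FALSE]
  out <- list()
  for (grp in split(rx, list(rx$person_id, rx$drug), drop = TRUE)) {
    d <- grp$issue_date
    new_ep <- c(TRUE, diff(as.integer(d)) > gap_days)
    ep_id <- cumsum(new_ep)
    starts <- tapply(as.integer(d), ep_id, min)
    ends <- tapply(as.integer(d), ep_id, max)
    n_rx <- tapply(ep_id, ep_id, length)
    out[[length(out) + 1L]] <- data.frame(
      person_id = grp$person_id[1L],
      drug = grp$drug[1L],
      start_date = as.Date(starts, origin = "1970-01-01"),
      end_date = as.Date(ends + coverage_days, origin = "1970-01-01"),
      n_prescriptions = as.integer(n_rx),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(person_id = character(0), drug = character(0),
                      start_date = as.Date(character(0)),
                      end_date = as.Date(character(0)),
                      n_prescriptions = integer(0),
                      duration_days = integer(0), qualifying = logical(0)))
  }
  ep <- do.call(rbind, out)
  ep$duration_days <- as.integer(ep$end_date - ep$start_date)
  ep$qualifying <- ep$duration_days >= 42L
  ep <- ep[order(ep$person_id, ep$start_date, ep$drug), , drop = FALSE]
  rownames(ep) <- NULL
  ep
}

#' Classify treatment-resistant depression for one person
#'
#' Scans qualifying episodes (at least six weeks of continuous
#' prescriptions of one drug) in time order. A switch is counted whenever
#' the next qualifying episode uses a different drug and starts at most
#' `gap_days` after the previous qualifying episode ended; two or more
#' switches define TRD. Overlapping qualifying episodes of different drugs
#' count as an immediate switch and are flagged as co-prescription.
#' Non-qualifying episodes never contribute switches but their elapsed time
#' still separates episodes.
#'
#' @param episodes episode data.frame for a single person (see
#'   [build_episodes()]).
#' @param gap_days maximum between-episode gap for a switch, in days.
#' @return list with `person_id`, `n_switches`, `is_trd`,
#'   `n_qualifying_episodes`, `co_prescription`, `episode_chain`.
#' @export
classify_trd <- function(episodes, gap_days = 98L) {
  .assert(is.data.frame(episodes), "episodes must be a data.frame")
  .assert(length(unique(episodes$person_id)) <= 1L,
          "classify_trd expects episodes of a single person")
  person <- if (nrow(episodes)) episodes$person_id[1L] else NA_character_
  q <- episodes[episodes$qualifying, , drop = FALSE]
  q <- q[order(q$start_date, q$end_date, q$drug), , drop = FALSE]
  n_switch <- 0L
  co_rx <- FALSE
  if (nrow(q) >= 2L) {
    for (i in 2L:nrow(q)) {
      gap <- as.integer(q$start_date[i] - q$end_date[i - 1L])
      if (q$drug[i] != q$drug[i - 1L] && gap <= gap_days) {
        n_switch <- n_switch + 1L
        if (gap < 0L) co_rx <- TRUE
      }
    }
  }
  list(person_id = person,
       n_switches = n_switch,
       is_trd = n_switch >= 2L,
       n_qualifying_episodes = nrow(q),
       co_prescription = co_rx,
       episode_chain = q)
}

#' Classify a whole cohort
#'
#' @param prescriptions prescription data.frame (see [build_episodes()]).
#' @param gap_days switch/continuity bound in days.
#' @return data.frame with one row per person: `person_id`, `n_switches`,
#'   `is_trd`, `n_qualifying_episodes`.
#' @export
classify_cohort <- function(prescriptions, gap_days = 98L) {
  ep <- build_episodes(prescriptions, gap_days = gap_days)
  persons <- unique(as.character(prescriptions$person_id))
  rows <- lapply(persons, function(p) {
    st <- classify_trd(ep[ep$person_id == p, , drop = FALSE], gap_days)
    data.frame(person_id = p, n_switches = st$n_switches, is_trd = st$is_trd,
               n_qualifying_episodes = st$n_qualifying_episodes,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Odds ratio with Wald confidence interval from a 2x2 table
#'
#' `OR = ad/bc` with the Haldane-Anscombe 0.5 continuity correction applied
#' to every cell when any cell is zero; the 95% CI is
#' `exp(log OR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))` and the p-value is
#' the two-sided Wald test of `log OR = 0`.
#'
#' @param a,b,c,d cell counts: `a` = subtype & TRD, `b` = subtype &
#'   non-TRD, `c` = no-subtype & TRD, `d` = no-subtype & non-TRD.
#' @return list with `or`, `ci_low`, `ci_high`, `p`.
#' @export
odds_ratio <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  .assert(all(is.finite(cells)) && all(cells >= 0), "cell counts must be nonnegative")
  degenerate <- (a == 0 && b == 0) || (c == 0 && d == 0) ||
    (a == 0 && c == 0) || (b == 0 && d == 0)
  .assert(!degenerate, "degenerate table: an empty row or column")
  if (any(cells == 0)) cells <- cells + 0.5
  lor <- log(cells["a"]) + log(cells["d"]) - log(cells["b"]) - log(cells["c"])
  se <- sqrt(sum(1 / cells))
  z <- stats::qnorm(0.975)
  list(or = unname(exp(lor)),
       ci_low = unname(exp(lor - z * se)),
       ci_high = unname(exp(lor + z * se)),
       p = unname(2 * stats::pnorm(-abs(lor) / se)))
}

#' Bonferroni selection of subtype-TRD associations
#'
#' Selects subtypes with `p < 0.05/m`, separating risk associations
#' (OR > 1) from protective ones (OR < 1).
#'
#' @param associations data.frame with columns `subtype`, `p` and `or`.
#' @param m number of tests corrected for (at least `nrow(associations)`).
#' @return the input with logical columns `selected_risk` and
#'   `selected_protective` added.
#' @export
bonferroni_select <- function(associations, m) {
  .assert(is.data.frame(associations) || nrow(associations) == 0L,
          "associations must be a data.frame")
  if (is.null(associations) || nrow(associations) == 0L) {
    return(data.frame(subtype = character(0), p = numeric(0), or = numeric(0),
                      selected_risk = logical(0),
                      selected_protective = logical(0)))
  }
  .assert(all(c("subtype", "p", "or") %in% names(associations)),
          "associations need columns subtype, p, or")
  .assert(m >= nrow(associations), "m must be at least the number of tests")
  thr <- 0.05 / m
  associations$selected_risk <- associations$p < thr & associations$or > 1
  associations$selected_protective <- associations$p < thr & associations$or < 1
  associations
}
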