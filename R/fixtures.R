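#' Published contingency and count tables used as worked examples
#'
#' Returns, bit-exact, the 2x2 marker-by-response and marker-by-T-stage
#' contingency tables and the response counts of the study population the
#' package models (group 1: n = 96 with HER2; group 2: the n = 43 subset with
#' the full marker panel). These serve as fixed inputs for the diagnostic
#' metric and Fisher-test worked examples.
#'
#' @return named list of integer matrices (`her2_response_g1`,
#'   `cd44_response_g2`, `her2_tstage_g1`, `cd44_tstage_g2`) and count vectors
#'   (`response_g1`, `response_g2`).
#' @export
fixture_tables <- function() {
  list(
    her2_response_g1 = matrix(c(1L, 17L, 19L, 57L), nrow = 2, byrow = TRUE,
                              dimnames = list(her2 = c("positive", "negative"),
                                              response = c("pCR", "non-pCR"))),
    cd44_response_g2 = matrix(c(8L, 19L, 1L, 15L), nrow = 2, byrow = TRUE,
                              dimnames = list(cd44 = c("positive", "negative"),
                                              response = c("pCR", "non-pCR"))),
    her2_tstage_g1 = matrix(c(0L, 18L, 11L, 65L), nrow = 2, byrow = TRUE,
                            dimnames = list(her2 = c("positive", "negative"),
                                            ct = c("T1-2", "T3-4a"))),
    cd44_tstage_g2 = matrix(c(1L, 15L, 5L, 22L), nrow = 2, byrow = TRUE,
                            dimnames = list(cd44 = c("negative", "positive"),
                                            ct = c("T1-2", "T3-4a"))),
    response_g1 = c(pCR = 21L, `non-pCR` = 75L),
    response_g2 = c(pCR = 9L, `non-pCR` = 34L)
  )
}

# expand a stratum definition (named values + count) into rows
expand_stratum <- function(count, ...) {
  vals <- list(...)
  as.data.frame(lapply(vals, rep, times = count), stringsAsFactors = FALSE)
}

# deterministically assign a categorical column within a subset of rows,
# by row order, to match marginal counts
assign_counts <- function(n, counts, levels) {
  stopifnot(sum(counts) == n)
  rep(levels, times = counts)
}

#' Synthetic per-patient cohort tables matching the published margins
#'
#' Reconstructs a per-patient clinical table consistent with every printed
#' marginal and two-way table of the study population (response counts,
#' Mandard grade distribution, HER2/CD44 by response and by clinical T-stage,
#' histology, N-stage, chemotherapy cycles, sex). Cross-classifications that
#' were never printed are filled deterministically by row order; the table is
#' therefore *synthetic* — one cohort among those compatible with the
#' published counts, not patient-level source data.
#'
#' @param group 1 (n = 96, HER2 only) or 2 (n = 43, full marker panel).
#' @return data.frame with one row per patient and the standard clinical
#'   column dictionary (`id`, `sex`, `age`, `histology`, `ct_stage`,
#'   `cn_stage`, `chemo_cycles`, `mandard`, marker columns).
#' @export
fixture_cohort <- function(group = 1) {
  group <- match.arg(as.character(group), c("1", "2"))
  if (group == "1") df <- fixture_cohort_g1() else df <- fixture_cohort_g2()
  df$response <- NULL  # response is derived from `mandard` by the reader
  df$id <- sprintf("P%03d", seq_len(nrow(df)))
  rownames(df) <- NULL
  df[, c("id", "sex", "age", "histology", "ct_stage", "cn_stage",
         "chemo_cycles", "mandard", "her2", "cd44", "hif1a_nucleus",
         "hif1a_cytosol", "ptch1", "shh")]
}

fixture_cohort_g1 <- function() {
  # strata pinned by the printed HER2 x response and HER2 x T-stage tables:
  # all 18 HER2-positives are T3-4a; the 11 T1-2 tumors are HER2-negative
  # (6 pCR + 5 non-pCR, matching the response x T-stage margin)
  strata <- rbind(
    expand_stratum(6,  response = "pCR",     her2 = "negative", ct_stage = "T1-2"),
    expand_stratum(13, response = "pCR",     her2 = "negative", ct_stage = "T3-4a"),
    expand_stratum(1,  response = "pCR",     her2 = "positive", ct_stage = "T3-4a"),
    expand_stratum(1,  response = "pCR",     her2 = "missing",  ct_stage = "T3-4a"),
    expand_stratum(5,  response = "non-pCR", her2 = "negative", ct_stage = "T1-2"),
    expand_stratum(52, response = "non-pCR", her2 = "negative", ct_stage = "T3-4a"),
    expand_stratum(17, response = "non-pCR", her2 = "positive", ct_stage = "T3-4a"),
    expand_stratum(1,  response = "non-pCR", her2 = "missing",  ct_stage = "T3-4a")
  )
  pcr <- strata$response == "pCR"
  n1 <- sum(pcr); n0 <- sum(!pcr)
  strata$histology[pcr] <- assign_counts(n1, c(16, 5), c("adenocarcinoma", "squamous"))
  strata$histology[!pcr] <- assign_counts(n0, c(72, 3), c("adenocarcinoma", "squamous"))
  strata$cn_stage[pcr] <- assign_counts(n1, c(19, 2), c("N0-1", "N2-3"))
  strata$cn_stage[!pcr] <- assign_counts(n0, c(49, 26), c("N0-1", "N2-3"))
  strata$chemo_cycles[pcr] <- assign_counts(n1, c(4, 17), c(4L, 5L))
  strata$chemo_cycles[!pcr] <- assign_counts(n0, c(14, 61), c(4L, 5L))
  strata$sex[pcr] <- assign_counts(n1, c(14, 7), c("male", "female"))
  strata$sex[!pcr] <- assign_counts(n0, c(64, 11), c("male", "female"))
  strata$mandard[pcr] <- 1L
  strata$mandard[!pcr] <- assign_counts(n0, c(24, 33, 16, 2), 2:5)
  strata$age <- ifelse(pcr, 65L, 63L)
  strata$cd44 <- strata$hif1a_nucleus <- strata$hif1a_cytosol <- ""
  strata$ptch1 <- strata$shh <- ""
  strata
}

fixture_cohort_g2 <- function() {
  # CD44 x response and CD44 x T-stage pin the joint response/CD44/T strata;
  # the single CD44-negative/T1-2 patient is a non-responder
  strata <- rbind(
    expand_stratum(1,  response = "pCR",     cd44 = "negative", ct_stage = "T3-4a"),
    expand_stratum(3,  response = "pCR",     cd44 = "positive", ct_stage = "T1-2"),
    expand_stratum(5,  response = "pCR",     cd44 = "positive", ct_stage = "T3-4a"),
    expand_stratum(1,  response = "non-pCR", cd44 = "negative", ct_stage = "T1-2"),
    expand_stratum(14, response = "non-pCR", cd44 = "negative", ct_stage = "T3-4a"),
    expand_stratum(2,  response = "non-pCR", cd44 = "positive", ct_stage = "T1-2"),
    expand_stratum(17, response = "non-pCR", cd44 = "positive", ct_stage = "T3-4a")
  )
  pcr <- strata$response == "pCR"
  n1 <- sum(pcr); n0 <- sum(!pcr)
  # HER2: pCR 8 negative + 1 missing; non-pCR 26 negative + 8 positive, with
  # all HER2+/CD44+ double positives (6) being non-responders
  strata$her2[pcr] <- assign_counts(n1, c(1, 8), c("missing", "negative"))
  nonpos <- !pcr & strata$cd44 == "positive"
  nonneg <- !pcr & strata$cd44 == "negative"
  strata$her2[nonpos] <- assign_counts(sum(nonpos), c(6, 13), c("positive", "negative"))
  strata$her2[nonneg] <- assign_counts(sum(nonneg), c(2, 13), c("positive", "negative"))
  strata$hif1a_nucleus[pcr] <- assign_counts(n1, c(8, 1), c("negative", "positive"))
  strata$hif1a_nucleus[!pcr] <- assign_counts(n0, c(31, 3), c("negative", "positive"))
  strata$hif1a_cytosol[pcr] <- assign_counts(n1, c(2, 7), c("negative", "positive"))
  strata$hif1a_cytosol[!pcr] <- assign_counts(n0, c(13, 21), c("negative", "positive"))
  strata$ptch1[pcr] <- assign_counts(n1, c(2, 7), c("negative", "positive"))
  strata$ptch1[!pcr] <- assign_counts(n0, c(4, 30), c("negative", "positive"))
  strata$shh[pcr] <- assign_counts(n1, c(0, 9), c("negative", "positive"))
  strata$shh[!pcr] <- assign_counts(n0, c(3, 31), c("negative", "positive"))
  strata$histology[pcr] <- assign_counts(n1, c(8, 1), c("adenocarcinoma", "squamous"))
  strata$histology[!pcr] <- "adenocarcinoma"
  strata$cn_stage[pcr] <- assign_counts(n1, c(8, 1), c("N0-1", "N2-3"))
  strata$cn_stage[!pcr] <- assign_counts(n0, c(22, 12), c("N0-1", "N2-3"))
  strata$chemo_cycles[pcr] <- assign_counts(n1, c(2, 7), c(4L, 5L))
  strata$chemo_cycles[!pcr] <- assign_counts(n0, c(8, 26), c(4L, 5L))
  strata$sex[pcr] <- assign_counts(n1, c(7, 2), c("male", "female"))
  strata$sex[!pcr] <- assign_counts(n0, c(29, 5), c("male", "female"))
  strata$mandard[pcr] <- 1L
  strata$mandard[!pcr] <- assign_counts(n0, c(12, 17, 4, 1), 2:5)
  strata$age <- ifelse(pcr, 65L, 63L)
  strata
}
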