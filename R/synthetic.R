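# Synthetic trauma cohorts. The generator emulates the structural features
# the validation layer cares about - ISS-group composition, per-region
# injury patterns, and a manual-vs-automatic disagreement model - from a
# small curated GM code catalogue that is closed under the shipped
# conversion and AIS fixture tables. Clinical realism beyond region and
# severity structure is a non-goal.

#' Curated ICD-10-GM code catalogue used by the cohort generator
#'
#' Roughly thirty injury codes spanning all six ISS body regions and AIS
#' severities 1-5, each with a singleton severity set in the shipped AIS
#' fixture so that ground-truth scores are exactly recoverable. The
#' severity-5 head entry pairs the subdural-haematoma code `S06.5` with the
#' detail code `S06.74!` (unconsciousness beyond 24 hours without return),
#' exercising the conditional seventh-character policy path.
#'
#' @return Data frame with columns `gm_code`, `detail_code` (`NA` for
#'   most rows), `region` (1-6) and `severity` (1-5).
#' @export
gm_catalogue <- function() {
  df <- read.table(header = TRUE, stringsAsFactors = FALSE, text = '
gm_code detail_code region severity
S00.0   NA 1 1
S06.0   NA 1 2
S02.0   NA 1 3
S06.1   NA 1 3
S06.5   NA 1 4
S06.5   S06.74! 1 5
S00.5   NA 2 1
S02.2   NA 2 1
S02.4   NA 2 2
S02.6   NA 2 2
S04.0   NA 2 3
S20.2   NA 3 1
S22.03  NA 3 2
S22.4   NA 3 3
S27.2   NA 3 4
S25.0   NA 3 5
S30.1   NA 4 1
S36.0   NA 4 2
S36.1   NA 4 3
S36.5   NA 4 4
S35.0   NA 4 5
S60.0   NA 5 1
S52.5   NA 5 2
S72.0   NA 5 3
S72.1   NA 5 3
S78.1   NA 5 4
S38.1   NA 5 5
T14.0   NA 6 1
T20.2   NA 6 2
T24.3   NA 6 3
T31.4   NA 6 4
T31.7   NA 6 5')
  df$detail_code[df$detail_code == "NA"] <- NA_character_
  df
}

# proposal severity weights per target ISS group (rows) and severity 1-5
# (columns); rejection sampling corrects any proposal bias exactly
SEVERITY_TILT <- matrix(c(
  0.60, 0.40, 0.00, 0.00, 0.00,
  0.30, 0.40, 0.30, 0.00, 0.00,
  0.15, 0.30, 0.35, 0.20, 0.00,
  0.05, 0.20, 0.30, 0.35, 0.10,
  0.00, 0.10, 0.25, 0.40, 0.25,
  0.00, 0.00, 0.10, 0.35, 0.55), nrow = 6, byrow = TRUE)

#' Configuration for the synthetic cohort generators
#'
#' Defaults reproduce the structure of the validation cohort the package's
#' statistics are designed for: 640 patients split over the six ISS groups
#' in proportions (219, 122, 155, 114, 13, 17)/640, and a
#' manual-vs-automatic disagreement model in which a score is reproduced
#' exactly with probability `p_exact` and otherwise shifted by a rounded
#' normal with standard deviation `shift_sd`, clamped to the ISS range.
#' The disagreement defaults (`p_exact = 0.296`, `shift_sd = 24`) were
#' calibrated once by simulation so that the linear weighted kappa of the
#' resulting 6-group cross-tabulation lands near 0.47 at n = 640, and are
#' frozen.
#'
#' @param n_patients Number of patients, default 640.
#' @param seed Integer seed (`NULL` leaves the RNG state alone).
#' @param group_weights Probabilities over ISS groups 1-6 (sum to 1).
#' @param p_region Marginal probability that any given body region is
#'   injured, default 0.35.
#' @param extra_codes_lambda Poisson mean of additional lower-severity
#'   codes emitted per patient, default 0.5.
#' @param p_exact,shift_sd Disagreement model parameters (see above).
#' @param max_tries Rejection-sampling cap per patient.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(n_patients = 640L, seed = NULL,
                             group_weights = c(219, 122, 155, 114, 13, 17) / 640,
                             p_region = 0.35,
                             extra_codes_lambda = 0.5,
                             p_exact = 0.296, shift_sd = 24,
                             max_tries = 10000L) {
  if (!(is.numeric(n_patients) && length(n_patients) == 1L && n_patients >= 0))
    stop("generator_config(): n_patients must be a non-negative integer")
  if (length(group_weights) != 6L || any(group_weights < 0) ||
      abs(sum(group_weights) - 1) > 1e-8)
    stop("generator_config(): group_weights must be 6 non-negative values summing to 1")
  if (!(p_region > 0 && p_region <= 1))
    stop("generator_config(): p_region must be in (0, 1]")
  if (!(p_exact >= 0 && p_exact <= 1) || shift_sd < 0)
    stop("generator_config(): invalid disagreement model parameters")
  structure(list(n_patients = as.integer(n_patients), seed = seed,
                 group_weights = group_weights, p_region = p_region,
                 extra_codes_lambda = extra_codes_lambda,
                 p_exact = p_exact, shift_sd = shift_sd,
                 max_tries = as.integer(max_tries)),
            class = "generator_config")
}

#' Generate a synthetic cohort of GM code lists with ground truth
#'
#' Per patient: a target ISS group is drawn from the configured mix, a
#' per-region AIS profile is rejection-sampled to land in that group
#' (regions injured independently with probability `p_region`, severities
#' from a group-tilted proposal restricted to the catalogue's support),
#' and GM codes realising the profile are emitted from the catalogue,
#' optionally with extra same-region lower-severity codes that cannot
#' change the per-region maxima. Deterministic under the config seed.
#'
#' @param config A `generator_config`.
#' @return A list of class `synthetic_cohort`: `codes` (data frame
#'   `patient_id`, `icd_code`) and `truth` (one row per patient with the
#'   six true region maxima, `true_iss` and `true_group`).
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  cat_df <- gm_catalogue()
  support <- lapply(1:6, function(r) sort(unique(cat_df$severity[cat_df$region == r])))
  n <- config$n_patients
  codes <- list(); truth <- list()
  for (i in seq_len(n)) {
    pid <- sprintf("P%05d", i)
    g <- sample.int(6L, 1L, prob = config$group_weights)
    profile <- NULL
    for (try in seq_len(config$max_tries)) {
      injured <- stats::runif(6) < config$p_region
      v <- integer(6)
      for (r in which(injured)) {
        w <- SEVERITY_TILT[g, support[[r]]]
        if (sum(w) <= 0) w <- rep(1, length(support[[r]]))
        v[r] <- if (length(support[[r]]) == 1L) support[[r]] else
          sample(support[[r]], 1L, prob = w)
      }
      iss <- sum(sort(v, decreasing = TRUE)[1:3]^2)
      if (iss_group(iss) == g) { profile <- v; break }
    }
    if (is.null(profile))
      stop(sprintf("generate_cohort(): could not realise ISS group %d within max_tries", g))
    pat_codes <- character()
    for (r in which(profile > 0L)) {
      cand <- which(cat_df$region == r & cat_df$severity == profile[r])
      row <- if (length(cand) == 1L) cand else sample(cand, 1L)
      pat_codes <- c(pat_codes, cat_df$gm_code[row])
      if (!is.na(cat_df$detail_code[row]))
        pat_codes <- c(pat_codes, cat_df$detail_code[row])
    }
    n_extra <- stats::rpois(1L, config$extra_codes_lambda)
    injured_regions <- which(profile > 0L)
    if (n_extra > 0L && length(injured_regions)) {
      for (j in seq_len(n_extra)) {
        r <- if (length(injured_regions) == 1L) injured_regions else
          sample(injured_regions, 1L)
        cand <- which(cat_df$region == r & cat_df$severity <= profile[r] &
                        is.na(cat_df$detail_code))
        if (!length(cand)) next
        row <- if (length(cand) == 1L) cand else sample(cand, 1L)
        pat_codes <- c(pat_codes, cat_df$gm_code[row])
      }
    }
    iss <- sum(sort(profile, decreasing = TRUE)[1:3]^2)
    if (length(pat_codes))
      codes[[length(codes) + 1L]] <- data.frame(
        patient_id = pid, icd_code = pat_codes, stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      patient_id = pid,
      t(stats::setNames(profile, paste0("ais_", REGION_NAMES))),
      true_iss = iss, true_group = g, stringsAsFactors = FALSE)
  }
  structure(
    list(codes = if (length(codes)) do.call(rbind, codes) else
           data.frame(patient_id = character(), icd_code = character(),
                      stringsAsFactors = FALSE),
         truth = if (length(truth)) do.call(rbind, truth) else
           data.frame(patient_id = character(), stringsAsFactors = FALSE)),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d patient(s), %d code(s)\n",
              nrow(x$truth), nrow(x$codes)))
  invisible(x)
}

#' Generate paired manual/automatic ISS scores
#'
#' Manual scores are drawn from the configured ISS-group mix (uniform
#' integer within each group's range); automatic scores reproduce the
#' manual score exactly with probability `p_exact` and are otherwise
#' shifted by a rounded zero-mean normal with SD `shift_sd`, clamped to
#' `[0, 75]`.
#'
#' @param config A `generator_config`.
#' @return Data frame with columns `patient_id`, `manual_iss`, `auto_iss`.
#' @export
generate_paired_scores <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_patients
  upper <- c(8L, 15L, 24L, 40L, 49L, 75L)
  g <- sample.int(6L, n, replace = TRUE, prob = config$group_weights)
  manual <- ISS_GROUP_LOWER[g] +
    floor(stats::runif(n) * (upper[g] - ISS_GROUP_LOWER[g] + 1L))
  shift <- ifelse(stats::runif(n) < config$p_exact, 0,
                  round(stats::rnorm(n, 0, config$shift_sd)))
  auto <- pmin(75L, pmax(0L, manual + as.integer(shift)))
  data.frame(patient_id = sprintf("P%05d", seq_len(n)),
             manual_iss = as.integer(manual), auto_iss = as.integer(auto),
             stringsAsFactors = FALSE)
}

#' The published 6x6 ISS-group cross-tabulation
#'
#' The embedded cross-tabulation of 640 trauma patients' automatically
#' versus manually calculated ISS groups that anchors the package's
#' agreement statistics (overall linear weighted kappa 0.47).
#'
#' @return 6x6 integer matrix, rows = manual group, columns = automatic
#'   group, with group-range dimnames.
#' @export
#' @examples
#' sum(reference_crosstab())  # 640
reference_crosstab <- function() {
  df <- utils::read.delim(icd2iss_fixture("reference_crosstab.tsv"),
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L])
  storage.mode(m) <- "integer"
  dimnames(m) <- list(manual = df$manual, auto = ISS_GROUP_LABELS)
  m
}

#' Group-level paired scores reconstructed from the embedded cross-tabulation
#'
#' Expands the 6x6 matrix into one pair per patient, with each score set to
#' its group's lower bound (0, 9, 16, 25, 41, 50). Only the group identity
#' is meaningful: cross-tabulating the result reproduces the matrix
#' cell-for-cell, and group-level statistics (weighted kappa) are exact,
#' but the scores themselves are representatives, not patient data.
#'
#' @return Data frame with columns `patient_id`, `manual_iss`, `auto_iss`
#'   (640 rows).
#' @export
reference_crosstab_pairs <- function() {
  tab <- reference_crosstab()
  # expand row by row so output order is deterministic
  idx <- which(tab > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  manual <- rep(ISS_GROUP_LOWER[idx[, 1L]], times = tab[idx])
  auto <- rep(ISS_GROUP_LOWER[idx[, 2L]], times = tab[idx])
  data.frame(patient_id = sprintf("T%04d", seq_along(manual)),
             manual_iss = manual, auto_iss = auto, stringsAsFactors = FALSE)
}
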