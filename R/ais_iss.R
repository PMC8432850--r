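# GEM-style AIS lookup and ISS computation. The two-step crosswalk used by
# ICDPIC-style tools (ICD-10-CM -> ICD-9-CM -> AIS) is collapsed here into
# one prefix table whose rows may carry several candidate severities; the
# GEMmin/GEMmax choice over that candidate set preserves the observable
# behaviour of the two-step mapping.

#' Load an AIS lookup table
#'
#' Each row maps a dotless ICD-10-CM code prefix to a non-empty set of
#' candidate AIS severities (1-6, or 9 for "unknown severity") and one of
#' the six ISS body regions. Lookup is longest-prefix, so rows keyed on a
#' full code (including the information character, e.g. `S065X6`) override
#' subcategory stems (`S065`).
#'
#' @param path TSV file with columns `cm_prefix`, `severities`
#'   (comma-joined integers) and `region` (1-6).
#' @return An `ais_table` data frame with a parsed `severity_set`
#'   list-column.
#' @export
load_ais_table <- function(path) {
  df <- read_tsv_strict(path, c("cm_prefix", "severities", "region"))
  df$cm_prefix <- toupper(gsub(".", "", df$cm_prefix, fixed = TRUE))
  df$region <- suppressWarnings(as.integer(df$region))
  if (nrow(df)) {
    if (anyDuplicated(df$cm_prefix))
      stop("load_ais_table(): duplicate cm_prefix row(s)")
    if (any(is.na(df$region) | df$region < 1L | df$region > 6L))
      stop("load_ais_table(): region must be an integer 1-6")
    sets <- lapply(strsplit(df$severities, ","), function(s) {
      v <- suppressWarnings(as.integer(trimws(s)))
      if (!length(v) || anyNA(v) || !all(v %in% c(1:6, 9L)))
        stop("load_ais_table(): severities must be a non-empty comma-joined subset of {1..6, 9}")
      sort(unique(v))
    })
    df$severity_set <- I(sets)
  } else {
    df$severity_set <- I(list())
  }
  class(df) <- c("ais_table", "data.frame")
  df
}

#' Look up AIS severity and body region for a CM code
#'
#' Longest-prefix match of the code's dotless significant characters
#' against the table. When a row carries several candidate severities -
#' one CM diagnosis translating to multiple legacy diagnoses with
#' different AIS - the `gemmax` mode takes the highest and `gemmin` the
#' lowest, mirroring the GEM crosswalk's max/min choice. Severity 9
#' (unknown) never competes with known severities; it is returned only
#' when it is a row's sole entry.
#'
#' @param code A `cm_code` or code string (any chapter; non-injury codes
#'   simply miss).
#' @param table An `ais_table` from [load_ais_table()].
#' @param mode `"gemmax"` (default) or `"gemmin"`.
#' @return A list `(severity, region, cm_prefix)`, or `NULL` on a miss.
#' @export
#' @examples
#' ais <- load_ais_table(icd2iss_fixture("ais_table.tsv"))
#' lookup_ais("S06.5X0A", ais, "gemmax")  # severity 4, region 1
lookup_ais <- function(code, table, mode = c("gemmax", "gemmin")) {
  mode <- match.arg(mode)
  if (is.character(code)) code <- parse_cm(code, profile = "any")
  stopifnot(is_cm_code(code), inherits(table, "ais_table"))
  sig <- cm_sig(code)
  hits <- which(startsWith(sig, table$cm_prefix))
  if (!length(hits)) return(NULL)
  row <- hits[which.max(nchar(table$cm_prefix[hits]))]
  sev <- table$severity_set[[row]]
  known <- sev[sev != 9L]
  severity <- if (length(known)) {
    if (mode == "gemmax") max(known) else min(known)
  } else 9L
  list(severity = severity, region = table$region[row],
       cm_prefix = table$cm_prefix[row])
}

#' Per-region maximum AIS profile
#'
#' Reduces a patient's lookup hits to the highest AIS in each of the six
#' body regions. Severity-9 (unknown) hits never enter the maxima; they
#' raise the `unknown_severity_present` flag instead.
#'
#' @param hits List of lookup results (as returned by [lookup_ais()]), or a
#'   data frame with columns `severity` and `region`.
#' @return A `region_profile`: list with `max_ais` (named integer vector of
#'   length 6, 0 = no injury recorded) and `flags`.
#' @export
region_profile <- function(hits) {
  if (is.data.frame(hits)) {
    sev <- as.integer(hits$severity); reg <- as.integer(hits$region)
  } else {
    hits <- Filter(Negate(is.null), hits)
    sev <- vapply(hits, `[[`, integer(1), "severity")
    reg <- vapply(hits, `[[`, integer(1), "region")
  }
  stopifnot(all(sev %in% c(1:6, 9L)), all(reg %in% 1:6))
  flags <- character()
  if (any(sev == 9L)) flags <- "unknown_severity_present"
  keep <- sev != 9L
  max_ais <- integer(6)
  for (i in seq_along(sev[keep]))
    max_ais[reg[keep][i]] <- max(max_ais[reg[keep][i]], sev[keep][i])
  names(max_ais) <- REGION_NAMES
  structure(list(max_ais = max_ais, flags = flags), class = "region_profile")
}

#' ISS group of a score
#'
#' Bins an Injury Severity Score into the six analysis groups:
#' group 1 = ISS 0-8, 2 = 9-15, 3 = 16-24, 4 = 25-40, 5 = 41-49,
#' 6 = 50-75. The bins partition 0-75.
#'
#' @param iss Integer vector of scores in 0-75.
#' @return Integer vector of group labels 1-6.
#' @export
#' @examples
#' iss_group(c(0, 16, 24, 25, 75))
iss_group <- function(iss) {
  iss <- as.numeric(iss)
  if (anyNA(iss) || any(iss < 0 | iss > 75) || any(iss != floor(iss)))
    stop("iss_group(): scores must be integers in [0, 75]")
  findInterval(iss, c(0, 9, 16, 25, 41, 50))
}

ISS_GROUP_LABELS <- c("0-8", "9-15", "16-24", "25-40", "41-49", "50-75")
ISS_GROUP_LOWER <- c(0L, 9L, 16L, 25L, 41L, 50L)

#' Compute the Injury Severity Score from a region profile
#'
#' The ISS is the sum of squares of the AIS in the three most severely
#' injured body regions. By the standard convention any region with the
#' maximal AIS of 6 sets the ISS to 75 outright; this cap can be switched
#' off, in which case the 6 simply enters the sum of squares.
#'
#' @param profile A `region_profile` or an integer vector of 6 per-region
#'   maxima (values 0-6).
#' @param cap_on_ais6 Apply the AIS-6 cap (default `TRUE`).
#' @return An `iss_result`: list with `iss` (0-75), `contributing_regions`
#'   (indices of the up-to-3 regions used; lexicographically smallest
#'   subset achieving the score), `group` (1-6) and `flags`.
#' @export
#' @examples
#' compute_iss(c(4, 0, 3, 2, 0, 0))  # 16 + 9 + 4 = 29
compute_iss <- function(profile, cap_on_ais6 = TRUE) {
  flags <- character()
  if (inherits(profile, "region_profile")) {
    flags <- profile$flags
    v <- profile$max_ais
  } else v <- as.integer(profile)
  if (length(v) != 6L || anyNA(v) || any(v < 0L | v > 6L))
    stop("compute_iss(): profile must be 6 per-region AIS maxima in 0-6")
  ord <- order(-v, seq_along(v))
  top <- ord[1:3]
  contributing <- top[v[top] > 0L]
  if (cap_on_ais6 && any(v == 6L)) {
    iss <- 75L
    flags <- union(flags, "ais6_cap")
  } else {
    iss <- sum(v[top]^2L)
  }
  structure(list(iss = iss,
                 contributing_regions = contributing,
                 group = iss_group(iss),
                 flags = flags),
            class = "iss_result")
}

#' @export
print.iss_result <- function(x, ...) {
  cat(sprintf("<ISS> %d (group %d, %s)%s\n", x$iss, x$group,
              ISS_GROUP_LABELS[x$group],
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Score a converted cohort: per-region AIS maxima and ISS per patient
#'
#' @param cm A `cm_conversion` from [convert_cohort()], or a data frame
#'   with columns `patient_id` and `cm_code`.
#' @param ais_table An `ais_table`.
#' @param mode GEM disambiguation, `"gemmax"` (default) or `"gemmin"`.
#' @param cap_on_ais6 Apply the AIS-6 cap (default `TRUE`).
#' @return Data frame with one row per patient: `patient_id`, the six
#'   `ais_*` region maxima, `iss`, `iss_group` and `flags` (`;`-joined).
#'   Patients none of whose codes match the table get `NA` scores and the
#'   `no_mappable_injury` flag.
#' @export
score_cohort <- function(cm, ais_table, mode = c("gemmax", "gemmin"),
                         cap_on_ais6 = TRUE) {
  mode <- match.arg(mode)
  df <- if (inherits(cm, "cm_conversion")) cm$conversions else cm
  if (!all(c("patient_id", "cm_code") %in% names(df)))
    stop("score_cohort(): input needs columns 'patient_id' and 'cm_code'")
  df <- df[order(df$patient_id), , drop = FALSE]
  pids <- unique(df$patient_id)
  out <- vector("list", length(pids))
  for (k in seq_along(pids)) {
    codes <- df$cm_code[df$patient_id == pids[k]]
    hits <- lapply(codes, function(cc) {
      parsed <- tryCatch(parse_cm(cc, profile = "any"), error = function(e) NULL)
      if (is.null(parsed)) NULL else lookup_ais(parsed, ais_table, mode)
    })
    n_miss <- sum(vapply(hits, is.null, logical(1)))
    hits <- Filter(Negate(is.null), hits)
    if (!length(hits)) {
      out[[k]] <- data.frame(
        patient_id = pids[k],
        t(stats::setNames(rep(NA_integer_, 6), paste0("ais_", REGION_NAMES))),
        iss = NA_integer_, iss_group = NA_integer_,
        flags = "no_mappable_injury", stringsAsFactors = FALSE)
      next
    }
    prof <- region_profile(hits)
    res <- compute_iss(prof, cap_on_ais6 = cap_on_ais6)
    flags <- res$flags
    if (n_miss > 0L) flags <- union(flags, "unmapped_codes_present")
    out[[k]] <- data.frame(
      patient_id = pids[k],
      t(stats::setNames(prof$max_ais, paste0("ais_", REGION_NAMES))),
      iss = res$iss, iss_group = res$group,
      flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
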