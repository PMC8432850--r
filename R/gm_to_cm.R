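# GM -> CM transformation: recode rules, seventh-character policies and
# detail-code handling. All tables are plain TSV so the shipped fixtures can
# be swapped for a site's full review output without touching code.

read_tsv_strict <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("table file not found: '%s'", path))
  df <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE, na.strings = NULL)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(sprintf("'%s' is missing required column(s): %s",
                 path, paste(missing, collapse = ", ")))
  df
}

#' Load a GM-to-CM recode rules table
#'
#' The rules externalise the manual review of subcategory differences
#' between ICD-10-GM and ICD-10-CM (e.g. GM `S22.03`, fracture of the
#' fifth/sixth thoracic vertebra, must become CM `S22.05` because CM's
#' `S22.03` codes the third thoracic vertebra). Each row substitutes a
#' dotless GM prefix with a CM stem; [apply_recode()] uses longest-prefix
#' matching, so a rule for `S2203` also recodes the more specific `S22.030`.
#'
#' @param path TSV file with columns `gm_pattern`, `cm_target`, `note`.
#' @return A `recode_rules` data frame.
#' @export
load_recode_rules <- function(path) {
  df <- read_tsv_strict(path, c("gm_pattern", "cm_target", "note"))
  df$gm_pattern <- toupper(gsub(".", "", df$gm_pattern, fixed = TRUE))
  df$cm_target <- toupper(gsub(".", "", df$cm_target, fixed = TRUE))
  if (nrow(df)) {
    if (any(!nzchar(df$gm_pattern)))
      stop("load_recode_rules(): empty gm_pattern")
    if (anyDuplicated(df$gm_pattern))
      stop(sprintf("load_recode_rules(): duplicate gm_pattern(s): %s",
                   paste(unique(df$gm_pattern[duplicated(df$gm_pattern)]),
                         collapse = ", ")))
    bad <- !grepl("^[A-Z][0-9]{2}[0-9A-Z]{0,3}$", df$gm_pattern) |
           !grepl("^[A-Z][0-9]{2}[0-9A-Z]{0,3}$", df$cm_target)
    if (any(bad))
      stop(sprintf("load_recode_rules(): malformed code(s) in rows: %s",
                   paste(which(bad), collapse = ", ")))
  }
  class(df) <- c("recode_rules", "data.frame")
  df
}

#' Apply the recode rules to one GM code
#'
#' Finds the longest rule prefix matching the code's dotless significant
#' characters, substitutes the CM target for the matched prefix and keeps
#' the remaining tail. Codes matching no rule are returned unchanged.
#'
#' @param code A `gm_code` or code string.
#' @param rules A `recode_rules` table from [load_recode_rules()].
#' @return The (possibly recoded) `gm_code`; the fired rule's pattern is
#'   attached as attribute `"rule_fired"` (`NULL` when no rule matched).
#' @export
#' @examples
#' rules <- load_recode_rules(icd2iss_fixture("recode_rules.tsv"))
#' format(apply_recode("S22.03", rules))  # "S22.05"
apply_recode <- function(code, rules) {
  if (is.character(code)) code <- parse_gm(code)
  stopifnot(is_gm_code(code), inherits(rules, "recode_rules"))
  sig <- gm_sig(code)
  hit <- rules$gm_pattern[startsWith(sig, rules$gm_pattern)]
  if (!length(hit)) return(code)
  pat <- hit[which.max(nchar(hit))]
  target <- rules$cm_target[rules$gm_pattern == pat]
  new_sig <- paste0(target, substring(sig, nchar(pat) + 1L))
  out <- parse_gm(paste0(substr(new_sig, 1L, 3L),
                         if (nchar(new_sig) > 3L) ".", substring(new_sig, 4L)))
  out$is_detail <- code$is_detail
  out$incomplete <- code$incomplete
  out$raw <- code$raw
  attr(out, "rule_fired") <- pat
  out
}

#' Load a seventh-character policy table
#'
#' The CM information character ("digit number seven" counting the dot)
#' carries subcategory-specific meaning, so the value to emit when
#' converting a GM code must be chosen per CM subcategory. A policy row
#' with an empty `condition` is the subcategory's unconditional fallback;
#' rows with a condition tag fire only when a patient's detail-code
#' annotations carry that tag (e.g. `loc_gt24h_no_return` selecting the
#' severity-relevant unconsciousness value for subdural haemorrhage).
#'
#' @param path TSV file with columns `cm_subcategory`, `condition`, `value`.
#' @return A `seventh_policies` data frame.
#' @export
load_seventh_policies <- function(path) {
  df <- read_tsv_strict(path, c("cm_subcategory", "condition", "value"))
  df$cm_subcategory <- toupper(gsub(".", "", df$cm_subcategory, fixed = TRUE))
  df$value <- toupper(df$value)
  if (nrow(df)) {
    if (any(!grepl("^[0-9A-Z]$", df$value)))
      stop("load_seventh_policies(): value must be a single alphanumeric character")
    key <- paste(df$cm_subcategory, df$condition)
    if (anyDuplicated(key))
      stop("load_seventh_policies(): duplicate (cm_subcategory, condition) row(s)")
    fallbacks <- table(df$cm_subcategory[!nzchar(df$condition)])
    subcats <- unique(df$cm_subcategory)
    no_fb <- setdiff(subcats, names(fallbacks))
    if (length(no_fb))
      stop(sprintf("load_seventh_policies(): subcategories without an unconditional fallback: %s",
                   paste(no_fb, collapse = ", ")))
  }
  class(df) <- c("seventh_policies", "data.frame")
  df
}

#' Load a detail-code interpretation table
#'
#' Maps `"!"`-suffixed GM detail-code prefixes to enumerated interpretation
#' tags (e.g. the `S06.7-!` family to unconsciousness-duration classes).
#' Interpretation is table-driven because GM names the mechanism but the
#' clinical correspondence belongs in data, not code.
#'
#' @param path TSV file with columns `gm_prefix`, `interpretation`.
#' @return A `detail_map` data frame.
#' @export
load_detail_map <- function(path) {
  df <- read_tsv_strict(path, c("gm_prefix", "interpretation"))
  df$gm_prefix <- toupper(gsub(".", "", df$gm_prefix, fixed = TRUE))
  if (anyDuplicated(df$gm_prefix))
    stop("load_detail_map(): duplicate gm_prefix row(s)")
  class(df) <- c("detail_map", "data.frame")
  df
}

#' Split a patient's code list into injuries and detail annotations
#'
#' GM marks optional secondary detail codes with `"!"`; they qualify a
#' primary diagnosis (e.g. duration of unconsciousness after intracranial
#' injury) and must not be scored as injuries themselves. Detail codes are
#' removed from the injury list and returned as annotations tagged via the
#' detail map; unrecognised detail codes get the tag `"unknown"`.
#'
#' @param codes List of `gm_code` objects or character vector of raw codes.
#' @param detail_map A `detail_map` from [load_detail_map()].
#' @return A list with elements `injuries` (list of `gm_code`) and
#'   `annotations` (data frame with columns `detail_code`, `interpretation`).
#' @export
collect_details <- function(codes, detail_map) {
  if (is.character(codes)) codes <- lapply(codes, parse_gm)
  stopifnot(inherits(detail_map, "detail_map"))
  is_det <- vapply(codes, function(x) x$is_detail, logical(1))
  details <- codes[is_det]
  interp <- vapply(details, function(d) {
    sig <- gm_sig(d)
    hit <- detail_map$gm_prefix[startsWith(sig, detail_map$gm_prefix)]
    if (!length(hit)) return("unknown")
    detail_map$interpretation[detail_map$gm_prefix == hit[which.max(nchar(hit))]]
  }, character(1))
  list(
    injuries = codes[!is_det],
    annotations = data.frame(
      detail_code = vapply(details, format, character(1)),
      interpretation = interp,
      stringsAsFactors = FALSE))
}

lookup_seventh <- function(stem, policies, annotations = NULL) {
  rows <- policies[policies$cm_subcategory == stem, , drop = FALSE]
  if (!nrow(rows)) return(NULL)
  tags <- if (!is.null(annotations) && nrow(annotations)) annotations$interpretation else character()
  cond <- rows[nzchar(rows$condition) & rows$condition %in% tags, , drop = FALSE]
  if (nrow(cond)) return(list(value = cond$value[1L], condition = cond$condition[1L]))
  fb <- rows[!nzchar(rows$condition), , drop = FALSE]
  list(value = fb$value[1L], condition = "")
}

#' Convert one GM injury code to a canonical CM code
#'
#' The full per-code pipeline: recode-rule substitution, seventh-character
#' policy lookup (conditional policies consult the patient's detail-code
#' annotations), then canonical eight-character normalisation with the
#' configured encounter default. A CM stem with no policy row falls back to
#' the placeholder `'X'` with a warning, so unreviewed stems never abort a
#' run.
#'
#' @param code `gm_code` or code string (a non-detail injury code).
#' @param annotations Data frame of detail annotations for the same patient
#'   (from [collect_details()]), or `NULL`.
#' @param rules,policies Loaded tables.
#' @param encounter_default Encounter character, default `"A"` (initial
#'   encounter; the encounter position never influences severity).
#' @return A canonical `cm_code`; attribute `"rules_fired"` records the
#'   recode pattern and policy condition that fired.
#' @export
#' @examples
#' rules <- load_recode_rules(icd2iss_fixture("recode_rules.tsv"))
#' pol <- load_seventh_policies(icd2iss_fixture("seventh_char_policies.tsv"))
#' format(to_cm("S22.03", NULL, rules, pol))  # "S22.05XA"
to_cm <- function(code, annotations = NULL, rules, policies,
                  encounter_default = "A") {
  if (is.character(code)) code <- parse_gm(code)
  stopifnot(is_gm_code(code))
  if (code$is_detail)
    stop(sprintf("to_cm(): '%s' is a detail code; route it through collect_details()",
                 format(code)))
  rec <- apply_recode(code, rules)
  fired <- attr(rec, "rule_fired")
  sig <- gm_sig(rec)
  category <- substr(sig, 1L, 3L)
  rest <- substring(sig, 4L)
  subclass <- substr(rest, 1L, 2L)
  own_seventh <- if (nchar(rest) >= 3L) substr(rest, 3L, 3L) else NA_character_
  out <- structure(
    list(category = category, subclass = subclass,
         seventh = own_seventh, encounter = NA_character_,
         raw = code$raw),
    class = "cm_code")
  prov <- if (!is.null(fired)) paste0("recode:", fired) else character()
  if (is.na(out$seventh)) {
    pol <- lookup_seventh(paste0(category, subclass), policies, annotations)
    if (is.null(pol)) {
      warning(sprintf("to_cm(): no seventh-character policy for stem '%s%s'; using placeholder 'X'",
                      category, subclass), call. = FALSE)
      seventh <- "X"
    } else {
      seventh <- pol$value
      if (nzchar(pol$condition)) prov <- c(prov, paste0("policy:", pol$condition))
    }
    out <- normalize_cm(out, seventh_default = seventh,
                        encounter_default = encounter_default)
  } else {
    out <- normalize_cm(out, encounter_default = encounter_default)
  }
  attr(out, "rules_fired") <- paste(prov, collapse = ";")
  out
}

#' Convert a cohort of per-patient GM code lists to CM codes
#'
#' Runs [collect_details()] and [to_cm()] patient by patient. Codes outside
#' the S00-T88 injury chapter are format-padded but tagged
#' `unmapped_chapter` with a warning (mixed discharge-code exports must not
#' abort a run); per-row parse failures are channelled into an error report
#' rather than raised.
#'
#' @param records Data frame with columns `patient_id` and the code column
#'   (default name `icd_code`), one row per patient-diagnosis.
#' @param rules,policies,detail_map Loaded tables; defaults are the shipped
#'   fixtures.
#' @param encounter_default Encounter character, default `"A"`.
#' @param code_col Name of the code column.
#' @return A list of class `cm_conversion`: `conversions` (data frame
#'   `patient_id`, `gm_code`, `cm_code`, `rules_fired`, ordered by patient
#'   then input order), `annotations` (per-patient detail annotations) and
#'   `errors` (parse-failure report).
#' @export
convert_cohort <- function(records,
                           rules = load_recode_rules(icd2iss_fixture("recode_rules.tsv")),
                           policies = load_seventh_policies(icd2iss_fixture("seventh_char_policies.tsv")),
                           detail_map = load_detail_map(icd2iss_fixture("detail_interpretations.tsv")),
                           encounter_default = "A",
                           code_col = "icd_code") {
  if (!all(c("patient_id", code_col) %in% names(records)))
    stop(sprintf("convert_cohort(): input needs columns 'patient_id' and '%s'", code_col))
  records <- records[order(records$patient_id), , drop = FALSE]
  conv <- list(); ann <- list(); err <- list()
  for (pid in unique(records$patient_id)) {
    raw_codes <- as.character(records[records$patient_id == pid, code_col])
    parsed <- list(); pid_err <- list()
    for (rc in raw_codes) {
      p <- tryCatch(parse_gm(rc), error = function(e) e)
      if (inherits(p, "error")) {
        pid_err[[length(pid_err) + 1L]] <-
          data.frame(patient_id = pid, icd_code = rc,
                     error = conditionMessage(p), stringsAsFactors = FALSE)
      } else parsed[[length(parsed) + 1L]] <- p
    }
    det <- collect_details(parsed, detail_map)
    if (nrow(det$annotations))
      ann[[length(ann) + 1L]] <- cbind(patient_id = pid, det$annotations)
    for (code in det$injuries) {
      if (!in_injury_chapter(code$category)) {
        warning(sprintf("convert_cohort(): '%s' (patient %s) is outside S00-T88; passed through unmapped",
                        format(code), pid), call. = FALSE)
        padded <- normalize_cm(structure(
          list(category = code$category,
               subclass = substr(code$subclass, 1L, 2L),
               seventh = if (nchar(code$subclass) >= 3L) substr(code$subclass, 3L, 3L) else NA_character_,
               encounter = NA_character_, raw = code$raw),
          class = "cm_code"), encounter_default = encounter_default)
        conv[[length(conv) + 1L]] <- data.frame(
          patient_id = pid, gm_code = format(code), cm_code = format(padded),
          rules_fired = "unmapped_chapter", stringsAsFactors = FALSE)
        next
      }
      cm <- tryCatch(
        to_cm(code, det$annotations, rules, policies, encounter_default),
        error = function(e) e)
      if (inherits(cm, "error")) {
        pid_err[[length(pid_err) + 1L]] <-
          data.frame(patient_id = pid, icd_code = format(code),
                     error = conditionMessage(cm), stringsAsFactors = FALSE)
      } else {
        conv[[length(conv) + 1L]] <- data.frame(
          patient_id = pid, gm_code = format(code), cm_code = format(cm),
          rules_fired = attr(cm, "rules_fired"), stringsAsFactors = FALSE)
      }
    }
    if (length(pid_err)) err <- c(err, pid_err)
  }
  empty_conv <- data.frame(patient_id = character(), gm_code = character(),
                           cm_code = character(), rules_fired = character(),
                           stringsAsFactors = FALSE)
  empty_err <- data.frame(patient_id = character(), icd_code = character(),
                          error = character(), stringsAsFactors = FALSE)
  structure(
    list(conversions = if (length(conv)) do.call(rbind, conv) else empty_conv,
         annotations = if (length(ann)) do.call(rbind, ann) else
           data.frame(patient_id = character(), detail_code = character(),
                      interpretation = character(), stringsAsFactors = FALSE),
         errors = if (length(err)) do.call(rbind, err) else empty_err),
    class = "cm_conversion")
}

#' @export
print.cm_conversion <- function(x, ...) {
  cat(sprintf("<cm_conversion> %d code(s), %d patient(s), %d annotation(s), %d error(s)\n",
              nrow(x$conversions), length(unique(x$conversions$patient_id)),
              nrow(x$annotations), nrow(x$errors)))
  invisible(x)
}

#' Path to a shipped fixture table
#'
#' @param name File name under the package's `extdata` directory; with no
#'   argument, lists the available fixtures.
#' @return A file path (or vector of available names).
#' @export
#' @examples
#' icd2iss_fixture()
icd2iss_fixture <- function(name = NULL) {
  dir <- system.file("extdata", package = "icd2iss")
  if (is.null(name)) return(list.files(dir))
  path <- file.path(dir, name)
  if (!file.exists(path))
    stop(sprintf("no fixture named '%s'; see icd2iss_fixture()", name))
  path
}
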