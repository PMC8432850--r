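#' @keywords internal
"_PACKAGE"

# ISS body-region taxonomy used throughout: 1 head/neck, 2 face, 3 thorax,
# 4 abdomen (incl. pelvic contents), 5 extremities (incl. pelvic girdle),
# 6 external.
REGION_NAMES <- c("head_neck", "face", "thorax", "abdomen",
                  "extremities", "external")

#' ISS body-region labels
#'
#' The six Injury Severity Score body regions in their conventional order:
#' head/neck, face, thorax, abdomen (including pelvic contents), extremities
#' (including the pelvic girdle), and external (skin, burns).
#'
#' @return Character vector of length 6.
#' @export
#' @examples
#' iss_regions()
iss_regions <- function() REGION_NAMES

#' Parse an ICD-10-GM diagnosis code
#'
#' ICD-10-GM billing codes carry at most six significant characters: a
#' three-character category (letter + two digits) and up to three further
#' digits after the dot. Optional secondary "detail" codes (e.g. the
#' `S06.7-!` unconsciousness family) are marked with a trailing `"!"` and add
#' clinical information to a primary diagnosis rather than coding an injury
#' of their own. A trailing `"-"` marks an incompletely specified code in
#' some exports; it is stripped and recorded, not treated as an error.
#'
#' @param raw A single code string, e.g. `"S22.03"` or `"S06.7-!"`.
#'   Case-insensitive; stored upper-case.
#' @return An object of class `gm_code` with fields `category`, `subclass`,
#'   `is_detail`, `incomplete` and `raw`.
#' @export
#' @examples
#' parse_gm("S22.03")
#' parse_gm("S06.7-!")
parse_gm <- function(raw) {
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(trimws(raw)))
    stop("parse_gm(): input must be a single non-empty code string")
  orig <- raw
  s <- toupper(trimws(raw))
  is_detail <- grepl("!$", s)
  s <- sub("!$", "", s)
  incomplete <- grepl("-$", s)
  s <- sub("-+$", "", s)
  sig <- gsub(".", "", s, fixed = TRUE)
  if (!grepl("^[A-Z][0-9]{2}[0-9]{0,3}$", sig))
    stop(sprintf("parse_gm(): malformed ICD-10-GM code '%s'", orig))
  # dot, if present, must sit after the category
  if (grepl("\\.", s) && !grepl("^[A-Z][0-9]{2}\\.[0-9]*$", s))
    stop(sprintf("parse_gm(): misplaced dot in '%s'", orig))
  structure(
    list(category = substr(sig, 1L, 3L),
         subclass = substring(sig, 4L),
         is_detail = is_detail,
         incomplete = incomplete,
         raw = orig),
    class = "gm_code")
}

#' @export
format.gm_code <- function(x, ...) {
  out <- x$category
  if (nzchar(x$subclass)) out <- paste0(out, ".", x$subclass)
  if (x$is_detail) out <- paste0(out, "!")
  out
}

#' @export
print.gm_code <- function(x, ...) {
  cat("<ICD-10-GM> ", format(x),
      if (x$incomplete) " (incomplete)", "\n", sep = "")
  invisible(x)
}

# dotless significant characters (category + subclass); the unit of all
# prefix matching
gm_sig <- function(code) paste0(code$category, code$subclass)

is_gm_code <- function(x) inherits(x, "gm_code")

# S00-T88 is the ICD-10 injury/poisoning chapter accepted by the default
# converter profile
in_injury_chapter <- function(category) {
  first <- substr(category, 1L, 1L)
  num <- suppressWarnings(as.integer(substr(category, 2L, 3L)))
  !is.na(num) && (first == "S" || (first == "T" && num <= 88L))
}

#' Parse an ICD-10-CM diagnosis code
#'
#' ICD-10-CM injury codes extend the three-character category with up to
#' three more characters, an information character whose meaning depends on
#' the subcategory (laterality, duration of unconsciousness, ...; `'X'` is
#' the placeholder) and a final encounter character (`'A'` initial, `'D'`
#' subsequent, `'S'` sequela). Rendered with the dot this yields the
#' eight-character form, e.g. `"S06.5X5A"`. Shorter inputs are accepted and
#' the absent positions left unset; [normalize_cm()] completes them.
#'
#' @param raw A single code string, 3-7 significant characters.
#' @param profile `"injury"` (default) accepts only categories S00-T88 and
#'   rejects other chapters; `"any"` accepts every syntactically valid code.
#' @return An object of class `cm_code` with fields `category`, `subclass`,
#'   `seventh` (the information character, `NA` when unset), `encounter`
#'   (`NA` when unset) and `raw`.
#' @export
#' @examples
#' parse_cm("S06.5X5A")
#' parse_cm("S22.05")
parse_cm <- function(raw, profile = c("injury", "any")) {
  profile <- match.arg(profile)
  if (!is.character(raw) || length(raw) != 1L || is.na(raw) || !nzchar(trimws(raw)))
    stop("parse_cm(): input must be a single non-empty code string")
  orig <- raw
  s <- toupper(trimws(raw))
  sig <- gsub(".", "", s, fixed = TRUE)
  if (!grepl("^[A-Z][0-9]{2}[0-9A-Z]{0,4}$", sig))
    stop(sprintf("parse_cm(): malformed ICD-10-CM code '%s'", orig))
  category <- substr(sig, 1L, 3L)
  if (profile == "injury" && !in_injury_chapter(category))
    stop(sprintf(
      "parse_cm(): '%s' is outside the S00-T88 injury chapter accepted by the 'injury' profile",
      orig))
  rest <- substring(sig, 4L)
  seventh <- NA_character_
  encounter <- NA_character_
  if (nchar(rest) == 4L) {
    encounter <- substr(rest, 4L, 4L)
    if (!encounter %in% c("A", "D", "S"))
      stop(sprintf("parse_cm(): encounter character '%s' in '%s' not one of A/D/S",
                   encounter, orig))
    rest <- substr(rest, 1L, 3L)
  }
  if (nchar(rest) == 3L) {
    seventh <- substr(rest, 3L, 3L)
    rest <- substr(rest, 1L, 2L)
  }
  subclass <- sub("X+$", "", rest)  # strip placeholder padding
  structure(
    list(category = category, subclass = subclass,
         seventh = seventh, encounter = encounter, raw = orig),
    class = "cm_code")
}

is_cm_code <- function(x) inherits(x, "cm_code")

# pad the subclass with the placeholder so the information character always
# lands in the sixth significant position
pad_subclass <- function(subclass) {
  formatC(subclass, width = 2L, flag = "-", format = "s") |>
    gsub(pattern = " ", replacement = "X")
}

#' @export
format.cm_code <- function(x, ...) {
  if (is.na(x$seventh) && is.na(x$encounter)) {
    out <- x$category
    if (nzchar(x$subclass)) out <- paste0(out, ".", x$subclass)
    return(out)
  }
  paste0(x$category, ".", pad_subclass(x$subclass),
         if (!is.na(x$seventh)) x$seventh else "X",
         if (!is.na(x$encounter)) x$encounter else "")
}

#' @export
print.cm_code <- function(x, ...) {
  cat("<ICD-10-CM> ", format(x), "\n", sep = "")
  invisible(x)
}

# dotless significant characters of the rendered code
cm_sig <- function(code) gsub(".", "", format(code), fixed = TRUE)

#' Normalise an ICD-10-CM code to its canonical eight-character form
#'
#' Pads the subclassification with the placeholder `'X'`, fills the
#' information character (position seven counting the dot) from
#' `seventh_default` when it is unset, and fills the encounter character
#' from `encounter_default`. The result always renders to the full
#' eight-character form (e.g. `"S22.05XA"`). Idempotent: normalising an
#' already-canonical code changes nothing.
#'
#' @param code A `cm_code` from [parse_cm()].
#' @param seventh_default Information character used when the code carries
#'   none; default the placeholder `"X"`. Policy-driven values are chosen
#'   upstream by [to_cm()].
#' @param encounter_default Encounter character used when unset; one of
#'   `"A"`, `"D"`, `"S"`. Trauma admissions are initial encounters, hence
#'   the default `"A"`.
#' @return A canonical `cm_code`.
#' @export
#' @examples
#' format(normalize_cm(parse_cm("S22.05")))       # "S22.05XA"
#' format(normalize_cm(parse_cm("S06.5"), "0"))   # "S06.5X0A"
normalize_cm <- function(code, seventh_default = "X", encounter_default = "A") {
  stopifnot(is_cm_code(code))
  if (!encounter_default %in% c("A", "D", "S"))
    stop("normalize_cm(): encounter_default must be one of 'A', 'D', 'S'")
  if (!grepl("^[0-9A-Z]$", seventh_default))
    stop("normalize_cm(): seventh_default must be a single alphanumeric character")
  if (is.na(code$seventh)) code$seventh <- toupper(seventh_default)
  if (is.na(code$encounter)) code$encounter <- encounter_default
  code
}

is_canonical_cm <- function(code) {
  is_cm_code(code) && !is.na(code$seventh) && !is.na(code$encounter)
}
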