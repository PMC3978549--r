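#' @keywords internal
"_PACKAGE"

# Closed 13-key symptom taxonomy. Hemiparesis/hemiplegia is carried as two
# flags (body, face); the "both body and face" presentation sets both.
.traditional_keys <- c(
  "hemiparesis_body", "hemiparesis_face",
  "impaired_speech_or_comprehension", "visual_disturbance",
  "ataxia_discoordination", "vertigo", "balance_difficulty"
)
.nontraditional_keys <- c(
  "pain_excl_headache", "mental_status_change", "headache",
  "lightheadedness", "other_neurologic", "nonneurologic"
)

.age_bands <- c("0-17", "18-29", "30-44", "45-64", "65-75", "76-84", "85+")
.age_band_breaks <- c(0, 18, 30, 45, 65, 76, 85, Inf)
.relations <- c("adult_child", "spouse", "other_relative", "friend", "stranger")
.stroke_types <- c("ischemic", "hemorrhagic", "unknown")

#' The stroke symptom taxonomy
#'
#' The closed set of 13 dichotomous stroke symptoms used throughout the
#' package, partitioned into traditional (focal neurological) and
#' nontraditional (non-focal) symptoms. Hemiparesis/hemiplegia contributes
#' two keys, one for the body and one for the face; a presentation
#' affecting both sets both flags.
#'
#' Traditional symptoms are hemiparesis/hemiplegia (body, face), impaired
#' speech or comprehension, visual disturbance, ataxia/discoordination,
#' vertigo, and difficulty with balance. Nontraditional symptoms are pain
#' (excluding headache), mental status change (disorientation, confusion,
#' loss of consciousness), headache, lightheadedness, other neurologic
#' symptoms (nausea, hiccups, nonfocal weakness), and nonneurologic
#' symptoms (chest pain, palpitations, shortness of breath). Headache is
#' classed nontraditional because it is not a focal neurological sign.
#'
#' @return Named character vector mapping each symptom key to
#'   `"traditional"` or `"nontraditional"`.
#' @examples
#' symptom_taxonomy()
#' classify_symptom("headache")
#' @export
symptom_taxonomy <- function() {
  c(
    stats::setNames(rep("traditional", length(.traditional_keys)), .traditional_keys),
    stats::setNames(rep("nontraditional", length(.nontraditional_keys)), .nontraditional_keys)
  )
}

#' @rdname symptom_taxonomy
#' @param key A symptom key; must belong to the closed taxonomy.
#' @export
classify_symptom <- function(key) {
  tax <- symptom_taxonomy()
  if (length(key) != 1L || !key %in% names(tax)) {
    stop("unknown symptom key: ", paste(key, collapse = ", "),
         " (taxonomy is closed; see symptom_taxonomy())", call. = FALSE)
  }
  unname(tax[[key]])
}

#' Coded-story schema
#'
#' Field names, types and controlled vocabularies for one coded stroke
#' narrative: narrator voice, witness/relation (third person only),
#' patient sex and age, the 13 symptom flags, stroke type, and the
#' assistance/delay/treatment fields.
#'
#' @return A list with `fields` (character), `levels` (named list of
#'   controlled vocabularies) and `symptoms` (the 13 symptom keys).
#' @export
coded_schema <- function() {
  list(
    fields = c(
      "story_id", "narrator", "witness", "relation", "patient_sex",
      "age_years", "age_band", names(symptom_taxonomy()), "stroke_type",
      "sought_assistance", "delayed_assistance", "immediate_treatment"
    ),
    levels = list(
      narrator = c("first", "third"),
      relation = .relations,
      patient_sex = c("female", "male"),
      age_band = .age_bands,
      stroke_type = .stroke_types
    ),
    symptoms = names(symptom_taxonomy())
  )
}

#' Age band for an age in years
#'
#' @param age_years Numeric vector of ages.
#' @return Character vector of age-band labels
#'   (`"0-17"`, `"18-29"`, `"30-44"`, `"45-64"`, `"65-75"`, `"76-84"`, `"85+"`).
#' @export
age_band_of <- function(age_years) {
  as.character(cut(age_years, breaks = .age_band_breaks, labels = .age_bands,
                   right = FALSE))
}

# One empty coded record with the full schema; used by generators and readers.
empty_coded_record <- function() {
  sch <- coded_schema()
  rec <- list(
    story_id = NA_character_, narrator = NA_character_, witness = NA,
    relation = NA_character_, patient_sex = NA_character_,
    age_years = NA_integer_, age_band = NA_character_
  )
  for (s in sch$symptoms) rec[[s]] <- NA
  rec$stroke_type <- NA_character_
  rec$sought_assistance <- NA
  rec$delayed_assistance <- NA
  rec$immediate_treatment <- NA
  rec
}

as_coded_df <- function(records) {
  if (is.data.frame(records)) return(records)
  if (length(records) == 0L) {
    return(as.data.frame(empty_coded_record(), stringsAsFactors = FALSE)[0L, ])
  }
  do.call(rbind, lapply(records, function(r) {
    as.data.frame(r[lengths(r) > 0], stringsAsFactors = FALSE)
  }))
}

#' Derived symptom-group flags
#'
#' Collapses the 13 symptom flags of each record into the three group
#' indicators used in the narrator analyses: any traditional symptom, any
#' nontraditional symptom, and any nontraditional symptom excluding mental
#' status change.
#'
#' @param records Data frame of coded records (see [coded_schema()]).
#' @return Data frame with logical columns `any_traditional`,
#'   `any_nontraditional`, `any_nontraditional_excl_msc`.
#' @examples
#' rec <- data.frame(mental_status_change = TRUE, headache = FALSE)
#' # a record with only mental status change is nontraditional, but not
#' # nontraditional-excluding-MSC
#' @export
derive_flags <- function(records) {
  records <- as_coded_df(records)
  pick <- function(keys) {
    keys <- intersect(keys, names(records))
    if (length(keys) == 0L) return(rep(FALSE, nrow(records)))
    m <- as.matrix(records[keys])
    m[is.na(m)] <- FALSE
    rowSums(m) > 0
  }
  data.frame(
    any_traditional = pick(.traditional_keys),
    any_nontraditional = pick(.nontraditional_keys),
    any_nontraditional_excl_msc = pick(setdiff(.nontraditional_keys, "mental_status_change"))
  )
}

#' Validate a coded record
#'
#' Checks the schema invariants: witness and relation are present iff the
#' narrator is third person; the age band is consistent with the age in
#' years when both are coded; controlled vocabularies are respected; and
#' patient sex is present (stories without it were excluded from
#' analysis and are flagged here rather than dropped).
#'
#' @param record A single coded record (one-row data frame or named list).
#' @return Character vector of violations, empty when the record is valid.
#'   Each violation names the offending field and rule.
#' @export
validate_story <- function(record) {
  r <- as.list(as_coded_df(record)[1L, ])
  sch <- coded_schema()
  v <- character()
  bad_level <- function(field) {
    !is.na(r[[field]]) && !r[[field]] %in% sch$levels[[field]]
  }
  for (f in names(sch$levels)) {
    if (!is.null(r[[f]]) && bad_level(f)) {
      v <- c(v, sprintf("%s: value '%s' not in controlled vocabulary", f, r[[f]]))
    }
  }
  if (is.null(r$patient_sex) || is.na(r$patient_sex)) {
    v <- c(v, "patient_sex: missing (record excluded from analysis)")
  }
  if (identical(r$narrator, "first")) {
    if (!is.null(r$relation) && !is.na(r$relation)) {
      v <- c(v, "relation: only allowed for third-person narrators")
    }
    if (!is.null(r$witness) && !is.na(r$witness)) {
      v <- c(v, "witness: only allowed for third-person narrators")
    }
  }
  if (!is.na(r$age_years %||% NA) && !is.na(r$age_band %||% NA)) {
    if (!identical(age_band_of(r$age_years), r$age_band)) {
      v <- c(v, sprintf("age_band: '%s' inconsistent with age_years=%s",
                        r$age_band, r$age_years))
    }
  }
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Percent agreement between two coders
#'
#' Raw percent agreement over all (story, field) cells of the coding
#' schema: the fraction of cells on which the two coders agree, with
#' missing-equals-missing counted as agreement. This is the metric the
#' coding workflow reports; Cohen's kappa per field is available as a
#' clearly separate extra via `kappa = TRUE`.
#'
#' @param coder_a,coder_b Data frames of coded records covering the same
#'   story ids.
#' @param kappa If `TRUE`, also return per-field Cohen's kappa.
#' @return The agreement proportion, or (with `kappa = TRUE`) a list with
#'   `percent_agreement` and `kappa` (named numeric, `NA` where undefined).
#' @export
percent_agreement <- function(coder_a, coder_b, kappa = FALSE) {
  a <- as_coded_df(coder_a); b <- as_coded_df(coder_b)
  if (!setequal(a$story_id, b$story_id) || anyDuplicated(a$story_id) ||
      anyDuplicated(b$story_id)) {
    stop("coder_a and coder_b must cover the same story ids exactly once each",
         call. = FALSE)
  }
  a <- a[order(a$story_id), , drop = FALSE]
  b <- b[order(b$story_id), , drop = FALSE]
  fields <- setdiff(intersect(names(a), names(b)), "story_id")
  cell_eq <- function(x, y) (is.na(x) & is.na(y)) | (!is.na(x) & !is.na(y) & x == y)
  eq <- vapply(fields, function(f) cell_eq(a[[f]], b[[f]]),
               logical(nrow(a)))
  eq <- matrix(eq, nrow = nrow(a))
  agreement <- mean(eq)
  if (!kappa) return(agreement)
  kap <- vapply(fields, function(f) {
    x <- as.character(a[[f]]); y <- as.character(b[[f]])
    keep <- !is.na(x) & !is.na(y)
    if (sum(keep) < 2L) return(NA_real_)
    lev <- union(x[keep], y[keep])
    if (length(lev) < 2L) return(NA_real_)
    tab <- table(factor(x[keep], lev), factor(y[keep], lev))
    po <- sum(diag(tab)) / sum(tab)
    pe <- sum(rowSums(tab) * colSums(tab)) / sum(tab)^2
    if (pe >= 1) return(NA_real_)
    (po - pe) / (1 - pe)
  }, numeric(1))
  list(percent_agreement = agreement, kappa = kap)
}

#' Lexicon-based auto-coder
#'
#' Inverts the corpus generator's phrase lexicons: a symptom flag is set
#' iff any phrase from that symptom's lexicon occurs in the text
#' (case-insensitive, exact phrase). Narrator, patient sex and stroke
#' type are recovered from surface markers (relation phrases, pronouns,
#' diagnosis phrases). This is a testing device that closes the loop with
#' [render_story()], not a clinical NLP system.
#'
#' @param text A single post text.
#' @param lexicons Phrase lexicons, defaulting to [story_lexicons()].
#' @return A one-row data frame: a partial coded record with the 13
#'   symptom flags, `narrator`, `patient_sex` and `stroke_type` filled
#'   where detectable (`NA` otherwise).
#' @export
auto_code <- function(text, lexicons = story_lexicons()) {
  missing_keys <- setdiff(names(symptom_taxonomy()), names(lexicons$symptoms))
  if (length(missing_keys) > 0L) {
    stop("lexicons do not cover the taxonomy; missing: ",
         paste(missing_keys, collapse = ", "), call. = FALSE)
  }
  low <- tolower(text)
  has_any <- function(phrases) any(vapply(tolower(phrases),
                                          function(p) grepl(p, low, fixed = TRUE),
                                          logical(1)))
  rec <- empty_coded_record()
  for (s in names(symptom_taxonomy())) rec[[s]] <- has_any(lexicons$symptoms[[s]])
  rec$narrator <- if (has_any(lexicons$narrator_third_markers)) "third" else "first"
  female <- has_any(lexicons$sex_markers$female)
  male <- has_any(lexicons$sex_markers$male)
  rec$patient_sex <- if (female && !male) "female" else if (male && !female) "male" else NA_character_
  rec$stroke_type <- if (has_any(lexicons$stroke_type_markers$ischemic)) {
    "ischemic"
  } else if (has_any(lexicons$stroke_type_markers$hemorrhagic)) {
    "hemorrhagic"
  } else if (has_any(lexicons$stroke_type_markers$unknown)) {
    "unknown"
  } else {
    NA_character_
  }
  as.data.frame(rec, stringsAsFactors = FALSE)
}

#' Read and write coded records as CSV
#'
#' One column per schema field, controlled vocabularies spelled as in
#' [coded_schema()], empty cell = missing.
#'
#' @param records Data frame of coded records.
#' @param path File path.
#' @return `read_coded_csv()` returns a data frame of coded records;
#'   `write_coded_csv()` invisibly returns `path`.
#' @export
write_coded_csv <- function(records, path) {
  utils::write.csv(as_coded_df(records), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_coded_csv
#' @export
read_coded_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = "")
  for (s in names(symptom_taxonomy())) {
    if (s %in% names(df)) df[[s]] <- as.logical(df[[s]])
  }
  for (f in c("witness", "sought_assistance", "delayed_assistance",
              "immediate_treatment")) {
    if (f %in% names(df)) df[[f]] <- as.logical(df[[f]])
  }
  if ("age_years" %in% names(df)) df$age_years <- as.integer(df$age_years)
  df
}
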