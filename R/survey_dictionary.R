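#' Survey data dictionary
#'
#' Machine-readable description of every column of an item-level survey
#' table: its section, storage type, and (for categorical items) the
#' declared level set. The dictionary defines the six survey sections —
#' demographics, medical history, military duty, sleep (PSQI, Berlin,
#' sleeping environment), diet/nutrition (dietary-habit items, Nutrition
#' Quotient), and gastrointestinal (GSRS, Bristol stool scale) — and is
#' the single source of truth for column order, completeness checks and
#' feature encoding.
#'
#' Types are one of `"id"`, `"logical"`, `"numeric"`, `"ordinal"` (integer
#' codes with an ordered level set), or `"nominal"` (unordered labels).
#'
#' @return A tibble with columns `column`, `section`, `type`, `levels`
#'   (list-column; `NULL` for numeric/id columns).
#' @export
#' @examples
#' dict <- survey_dictionary()
#' dplyr::count(dict, section)
survey_dictionary <- function() {
  row <- function(column, section, type, levels = NULL) {
    tibble::tibble(column = column, section = section, type = type,
                   levels = list(levels))
  }
  dplyr::bind_rows(
    row("respondent_id", "meta", "id"),
    row("consent", "meta", "logical"),

    row("age", "demographics", "numeric"),
    row("height_cm", "demographics", "numeric"),
    row("weight_kg", "demographics", "numeric"),
    row("rank", "demographics", "nominal",
        c("private", "private_first_class", "corporal", "sergeant")),
    row("education", "demographics", "ordinal", 1:4),
    row("smoking_status", "demographics", "nominal",
        c("never", "past", "active")),
    row("smoking_packs_per_day", "demographics", "numeric"),
    row("smoking_years", "demographics", "numeric"),
    row("alcohol_freq", "demographics", "ordinal", 1:4),
    row("coffee_freq", "demographics", "ordinal", 1:6),
    row("energy_drink_freq", "demographics", "ordinal", 1:6),
    row("exercise_freq", "demographics", "ordinal", 1:4),
    row("physical_grade", "demographics", "ordinal", 1:5),

    row("sleep_disorder_present", "medical", "nominal",
        c("none", "insomnia", "narcolepsy", "other")),
    row("sleep_disorder_past", "medical", "nominal",
        c("none", "insomnia", "narcolepsy", "other")),
    row("gi_disorder_present", "medical", "nominal",
        c("none", "reflux", "ibs")),
    row("gi_disorder_past", "medical", "nominal",
        c("none", "reflux", "ibs")),
    row("general_disease", "medical", "nominal",
        c("none", "hypertension", "other")),
    row("bp_history", "medical", "logical"),
    row("med_sleep", "medical", "logical"),
    row("med_digestive", "medical", "logical"),

    row("night_shift_dutyoff_freq", "military", "ordinal", 0:5),
    row("night_shift_dutyoff_fatigue", "military", "ordinal", 1:5),
    row("night_shift_no_dutyoff_freq", "military", "ordinal", 0:5),
    row("night_shift_no_dutyoff_fatigue", "military", "ordinal", 1:5),
    row("stress", "military", "ordinal", 1:5),

    purrr::map_dfr(
      c("noise", "light", "temperature", "bed", "roommates"),
      function(nm) row(paste0("sleep_env_", nm), "sleep_env", "ordinal", 1:5)),

    # PSQI: 4 open items + latency frequency + 9 disturbance ratings +
    # the "other disturbance" description + quality, medication,
    # sleepiness, enthusiasm = 19 items
    row("psqi_bedtime", "psqi", "numeric"),
    row("psqi_latency_min", "psqi", "numeric"),
    row("psqi_waketime", "psqi", "numeric"),
    row("psqi_sleep_hours", "psqi", "numeric"),
    row("psqi_cant_sleep_30min", "psqi", "ordinal", 0:3),
    purrr::map_dfr(
      c("wake_night", "bathroom", "breathe", "snore", "cold", "hot",
        "bad_dreams", "pain", "other_disturb"),
      function(nm) row(paste0("psqi_", nm), "psqi", "ordinal", 0:3)),
    row("psqi_other_desc", "psqi", "nominal",
        c("none", "noise", "stress", "pain", "other")),
    row("psqi_quality", "psqi", "ordinal", 0:3),
    row("psqi_medication", "psqi", "ordinal", 0:3),
    row("psqi_sleepy", "psqi", "ordinal", 0:3),
    row("psqi_enthusiasm", "psqi", "ordinal", 0:3),

    purrr::map_dfr(paste0("berlin_c1_", 1:5),
                   function(nm) row(nm, "berlin", "ordinal", 0:1)),
    purrr::map_dfr(paste0("berlin_c2_", 1:4),
                   function(nm) row(nm, "berlin", "ordinal", 0:1)),
    row("berlin_drive_freq", "berlin", "ordinal", 0:3),

    purrr::map_dfr(sprintf("diet_%02d", 1:25),
                   function(nm) row(nm, "diet", "ordinal", 1:7)),
    purrr::map_dfr(sprintf("nq_%02d", 1:21),
                   function(nm) row(nm, "nq", "ordinal", 1:5)),
    purrr::map_dfr(sprintf("gsrs_%02d", 1:15),
                   function(nm) row(nm, "gsrs", "ordinal", 1:7)),
    row("bss", "bss", "ordinal", 1:7)
  )
}

#' Column names of one or more survey sections
#'
#' @param sections Character vector of section names as used by
#'   [survey_dictionary()].
#' @return Character vector of column names, in dictionary order.
#' @export
survey_columns <- function(sections) {
  dict <- survey_dictionary()
  dict$column[dict$section %in% sections]
}

# internal: required (non-meta) item columns for completeness checks
required_item_columns <- function() {
  dict <- survey_dictionary()
  dict$column[!dict$section %in% "meta"]
}
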