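# The 132-feature schema and the descriptor vocabularies behind it.
#
# Record-level descriptor fields (multi-select in the diary) and
# profile-level token fields each contribute one binary presence feature per
# vocabulary token. Vocabulary sizes are fixed so that the schema always
# totals 132 features across 8 categories.

pv_vocab <- list(
  locations = c(
    "head", "neck", "jaw", "shoulder_left", "shoulder_right", "upper_back",
    "lower_back", "chest", "abdomen", "hip_left", "hip_right", "elbow_left",
    "elbow_right", "wrist_left", "wrist_right", "hand_left", "hand_right",
    "knee_left", "knee_right", "ankle_left", "ankle_right", "foot_left",
    "foot_right", "pelvis"
  ),
  symptoms = c(
    "fatigue", "nausea", "dizziness", "numbness", "tingling", "stiffness",
    "swelling", "weakness", "insomnia", "headache", "fever", "sweating",
    "cramping", "spasm", "burning_sensation", "light_sensitivity",
    "sound_sensitivity", "appetite_loss", "irritability", "brain_fog"
  ),
  characteristics = c(
    "aching", "burning", "sharp", "dull", "throbbing", "stabbing",
    "shooting", "tender", "radiating", "squeezing", "gnawing", "pressure",
    "electric"
  ),
  environments = c(
    "home", "work", "outdoors", "vehicle", "school", "gym", "public_place"
  ),
  aggravating = c(
    "sitting", "standing", "walking", "lifting", "bending", "stress",
    "cold_weather", "humidity", "exercise", "driving", "poor_sleep",
    "screen_time", "noise", "menstruation", "alcohol"
  ),
  alleviating = c(
    "rest", "heat", "ice", "stretching", "massage", "meditation",
    "medication_use", "sleep", "distraction", "gentle_exercise", "bath",
    "physiotherapy", "breathing_exercises", "music"
  ),
  ineffective = c(
    "rest", "heat", "ice", "stretching", "massage", "otc_analgesics",
    "topical_cream", "acupuncture", "chiropractic", "cannabis",
    "positioning", "compression", "elevation", "caffeine"
  ),
  conditions = c(
    "arthritis", "fibromyalgia", "migraine", "neuropathy", "sciatica",
    "endometriosis"
  ),
  medications = c(
    "nsaid", "opioid", "anticonvulsant", "antidepressant", "muscle_relaxant"
  ),
  mental_health = c("depression", "anxiety")
)

# Which record-level descriptor field feeds which schema subcategory.
pv_record_fields <- c("locations", "symptoms", "characteristics",
                      "environments", "aggravating", "alleviating",
                      "ineffective")
pv_profile_fields <- c("conditions", "medications", "mental_health")

#' The 132-feature schema
#'
#' Returns the ordered feature schema used by [extract_features()]: one row
#' per feature with its category (8 categories), subcategory for descriptor
#' blocks, and value kind. The layout is fixed: demographic (2), app usage
#' (2), pain statistics (8), pain descriptors (64: 24 body locations, 20
#' associated symptoms, 13 characteristics, 7 environments), factors
#' impacting pain (43: 15 aggravating, 14 alleviating, 14 ineffective), pain
#' conditions (6), medications (5) and mental-health conditions (2) — 132
#' features in total.
#'
#' @return A tibble with columns `feature`, `category`, `subcategory`,
#'   `kind` (one of `"numeric"`, `"binary"`, `"categorical"`), 132 rows.
#' @examples
#' feature_schema()
#' dplyr::count(feature_schema(), category)
#' @export
feature_schema <- function() {
  stats <- tibble(
    feature = c("severity_mean", "severity_sd", "abs_change_mean",
                "abs_change_sd", "trend_delta", "trend_abs_delta",
                "severity_level", "volatility_level"),
    category = "pain_statistics",
    subcategory = "pain_statistics",
    kind = c(rep("numeric", 6L), "binary", "binary")
  )
  desc_block <- function(field, category) {
    tibble(
      feature = paste(sub("s$", "", field), pv_vocab[[field]], sep = "_"),
      category = category,
      subcategory = field,
      kind = "binary"
    )
  }
  dplyr::bind_rows(
    tibble(feature = c("gender", "age"), category = "demographic",
           subcategory = "demographic",
           kind = c("categorical", "numeric")),
    tibble(feature = c("n_records", "n_days"), category = "app_usage",
           subcategory = "app_usage", kind = "numeric"),
    stats,
    desc_block("locations", "pain_descriptors"),
    desc_block("symptoms", "pain_descriptors"),
    desc_block("characteristics", "pain_descriptors"),
    desc_block("environments", "pain_descriptors"),
    desc_block("aggravating", "factors"),
    desc_block("alleviating", "factors"),
    desc_block("ineffective", "factors"),
    desc_block("conditions", "conditions"),
    desc_block("medications", "medications"),
    desc_block("mental_health", "mental_health")
  )
}

# Map a descriptor field name to its feature-name prefix ("locations" ->
# "location_head", ...). Kept in one place so generator and extractor agree.
pv_feature_name <- function(field, token) {
  paste(sub("s$", "", field), token, sep = "_")
}
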