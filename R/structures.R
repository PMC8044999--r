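#' Label vocabulary of the stylized mouse atlas
#'
#' The atlas distinguishes the 13 anatomical structures in which tracer
#' presence is scored (brain regions, CSF compartments, and the spinal
#' outflow), plus auxiliary labels needed by the pipeline: remaining brain
#' parenchyma, skull/bone and muscle (the tracer-free regions used for
#' threshold calibration), blood vessels and nasal turbinates (elevated
#' short-wavelength autofluorescence), a spinal subarachnoid sleeve that
#' completes the CSF outflow path, and the embedding background.
#'
#' @return A tibble with columns `label` (integer code used in the label
#'   volume), `structure` (snake_case id), `display` (human-readable name),
#'   `scored` (is it one of the 13 scored structures), and `compartment`
#'   (`"parenchyma"`, `"csf"`, `"tissue"`, or `"background"`).
#' @export
atlas_labels <- function() {
  tibble::tribble(
    ~label, ~structure,                ~display,                        ~scored, ~compartment,
    0L,  "background",                "Embedding background",           FALSE, "background",
    1L,  "nasal_turbinates",          "Nasal turbinates",               TRUE,  "tissue",
    2L,  "olfactory_bulb",            "Olfactory bulb",                 TRUE,  "parenchyma",
    3L,  "cortex",                    "Cortex",                         TRUE,  "parenchyma",
    4L,  "hippocampus",               "Hippocampus",                    TRUE,  "parenchyma",
    5L,  "striatum",                  "Striatum",                       TRUE,  "parenchyma",
    6L,  "sas_cerebrum",              "Subarachnoid space (cerebrum)",  TRUE,  "csf",
    7L,  "lateral_ventricle",         "Lateral ventricle",              TRUE,  "csf",
    8L,  "third_ventricle",           "Third ventricle",                TRUE,  "csf",
    9L,  "fourth_ventricle",          "Fourth ventricle",               TRUE,  "csf",
    10L, "interpeduncular_cistern",   "Interpeduncular cistern",        TRUE,  "csf",
    11L, "sas_cerebellum",            "Subarachnoid space (cerebellum)",TRUE,  "csf",
    12L, "spinal_cord",               "Spinal cord",                    TRUE,  "tissue",
    13L, "spinal_nerves",             "Spinal nerves",                  TRUE,  "tissue",
    14L, "rest_of_brain",             "Brain (other)",                  FALSE, "parenchyma",
    15L, "sas_spinal",                "Subarachnoid space (spinal)",    FALSE, "csf",
    16L, "bone",                      "Skull / bone",                   FALSE, "tissue",
    17L, "muscle",                    "Muscle / soft tissue",           FALSE, "tissue",
    18L, "blood_vessel",              "Blood vessel",                   FALSE, "tissue"
  )
}

#' The 13 scored anatomical structures
#'
#' @return Character vector of structure ids, in the conventional
#'   rostral-to-caudal reporting order.
#' @export
scored_structures <- function() {
  lab <- atlas_labels()
  lab$structure[lab$scored]
}

#' Integer label code for a structure id
#' @param structure Character vector of structure ids.
#' @return Integer label codes.
#' @keywords internal
structure_code <- function(structure) {
  lab <- atlas_labels()
  i <- match(structure, lab$structure)
  if (anyNA(i)) stop("unknown structure label: ",
                     paste(structure[is.na(i)], collapse = ", "))
  lab$label[i]
}

#' Labels of brain parenchyma (the "brain label" for volumetry)
#' @keywords internal
brain_structures <- function() {
  c("olfactory_bulb", "cortex", "hippocampus", "striatum", "rest_of_brain")
}

#' CSF compartment labels (connectivity contract + fast transport)
#' @keywords internal
csf_structures <- function() {
  c("sas_cerebrum", "lateral_ventricle", "third_ventricle",
    "fourth_ventricle", "interpeduncular_cistern", "sas_cerebellum",
    "sas_spinal")
}
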