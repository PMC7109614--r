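#' Load the differential-diagnosis knowledge base
#'
#' The knowledge base encodes, per diagnosis, the suggestive clinical features
#' that help distinguish respiratory diseases with a clinical picture similar
#' to COPD: asthma, congestive heart failure, bronchiectasis, tuberculosis,
#' obliterative bronchiolitis and diffuse panbronchiolitis, plus COPD itself.
#' Free-text features are decomposed into atomic canonical keys; the verbatim
#' source text of each feature is kept alongside its key for auditability.
#'
#' @param path CSV with columns `diagnosis`, `feature_key`, `source_text`.
#' @param vocabulary_path Optional CSV (`feature_key`, `display`) restricting
#'   the allowed keys; defaults to the bundled vocabulary.
#' @return A `copd_kb` list: `profiles` (named list of feature-key vectors in
#'   fixed diagnosis order), `table` (the tibble), `vocabulary` (tibble).
#' @examples
#' kb <- load_knowledge_base()
#' names(kb$profiles)
#' @export
load_knowledge_base <- function(path = copd_sys_file("differential_kb.csv"),
                                vocabulary_path = NULL) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tbl) == 0L) {
    copd_abort("knowledge base file is empty", "copd_kb_error")
  }
  needed <- c("diagnosis", "feature_key")
  if (!all(needed %in% names(tbl))) {
    copd_abort("knowledge base needs columns diagnosis, feature_key", "copd_kb_error")
  }
  vocab <- readr::read_csv(vocabulary_path %||% copd_sys_file("feature_vocabulary.csv"),
                           show_col_types = FALSE, progress = FALSE)
  unknown <- setdiff(unique(tbl$feature_key), vocab$feature_key)
  if (length(unknown) > 0L) {
    copd_abort(paste0("unknown feature key in knowledge base: ", unknown[1]),
               "copd_kb_error")
  }

  diagnoses <- unique(tbl$diagnosis)
  expected <- c("COPD", "asthma", "congestive_heart_failure", "bronchiectasis",
                "tuberculosis", "obliterative_bronchiolitis",
                "diffuse_panbronchiolitis")
  missing <- setdiff(expected, diagnoses)
  if (length(missing) > 0L) {
    copd_abort(paste0("knowledge base missing diagnosis: ",
                      paste(missing, collapse = ", ")), "copd_kb_error")
  }
  profiles <- lapply(diagnoses, function(d) {
    keys <- tbl$feature_key[tbl$diagnosis == d]
    if (anyDuplicated(keys)) {
      copd_abort(paste0("duplicate feature key within diagnosis ", d), "copd_kb_error")
    }
    keys
  })
  names(profiles) <- diagnoses
  structure(list(profiles = profiles, table = as_tibble(tbl),
                 vocabulary = as_tibble(vocab)),
            class = "copd_kb")
}

#' Parse presentation features
#'
#' Validates a set of observed canonical feature keys against the vocabulary;
#' unknown keys are rejected.
#'
#' @param features Character vector of feature keys.
#' @param kb Knowledge base (for its vocabulary).
#' @return The validated (deduplicated) character vector.
#' @export
presentation_features <- function(features, kb = load_knowledge_base()) {
  features <- unique(as.character(features))
  unknown <- setdiff(features, kb$vocabulary$feature_key)
  if (length(unknown) > 0L) {
    copd_abort(paste0("unknown presentation feature key: ", unknown[1]),
               "copd_feature_error")
  }
  features
}

#' Rank differential diagnoses for a presentation
#'
#' Scores every diagnosis profile against the observed feature set with the
#' Jaccard coefficient |F ∩ P| / |F ∪ P| and returns the ranking with the
#' matched features for explainability. Ties are broken by the fixed diagnosis
#' order of the knowledge base; an empty feature set scores everything 0.
#' This is decision support — key information on similar clinical pictures —
#' not an automated diagnosis.
#'
#' @param features Character vector of canonical feature keys (validated
#'   against the vocabulary).
#' @param kb Knowledge base.
#' @return A tibble ordered by descending score: `rank`, `diagnosis`, `score`,
#'   `n_matched`, `matched_features` (list column).
#' @examples
#' suggest_differentials(c("onset_early_life", "symptoms_vary_day_to_day",
#'                         "allergy_rhinitis_eczema"))
#' @export
suggest_differentials <- function(features, kb = load_knowledge_base()) {
  features <- presentation_features(features, kb)
  out <- tibble(
    diagnosis = names(kb$profiles),
    kb_order = seq_along(kb$profiles),
    score = unname(map_dbl(kb$profiles, function(p) {
      u <- length(union(features, p))
      if (u == 0L) 0 else length(intersect(features, p)) / u
    })),
    matched_features = unname(map(kb$profiles, function(p)
      intersect(features, p)))
  )
  out |>
    mutate(n_matched = lengths(.data$matched_features)) |>
    arrange(desc(.data$score), .data$kb_order) |>
    mutate(rank = row_number()) |>
    select("rank", "diagnosis", "score", "n_matched", "matched_features")
}

#' @export
print.copd_kb <- function(x, ...) {
  cat("<copd_kb>", length(x$profiles), "diagnosis profiles,",
      nrow(x$table), "features\n")
  invisible(x)
}
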