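# Patient-level aggregation: ICD-10 diagnosis grouping, per-patient symptom
# profiles, diagnosis-by-domain crosstabs and coverage statistics.
#
# SMI code families are F20x (schizophrenia), F25x (schizoaffective
# disorder) and F31x (bipolar disorder); more than one distinct family makes
# the "Multiple" group. The non-SMI (negative control) group is any of F32
# (excluding F32.3), F33 (excluding F33.3), F40-F48 or F60 with no SMI code;
# F32.3/F33.3 (depression with psychotic symptoms) are excluded outright so
# the cohorts cannot overlap. Everything else is Unclassified.

DIAGNOSIS_GROUPS <- c("F20", "F25", "F31", "Multiple", "NonSMI", "Unclassified")
SMI_FAMILIES <- c("F20", "F25", "F31")

#' Assign a diagnosis group from ICD-10 codes
#'
#' SMI codes take precedence over non-SMI codes; family matching is on the
#' leading characters of the code.
#'
#' @param icd10_codes character vector of ICD-10 codes (e.g. `"F20.0"`).
#' @return one of `"F20"`, `"F25"`, `"F31"`, `"Multiple"`, `"NonSMI"`,
#'   `"Unclassified"`.
#' @export
assign_diagnosis_group <- function(icd10_codes) {
  codes <- toupper(trimws(as.character(icd10_codes)))
  codes <- codes[nzchar(codes)]
  if (length(codes) == 0L) return("Unclassified")
  fam <- SMI_FAMILIES[vapply(SMI_FAMILIES, function(f) any(startsWith(codes, f)),
                             TRUE)]
  if (length(fam) > 1L) return("Multiple")
  if (length(fam) == 1L) return(fam)
  is_nonsmi <- function(code) {
    if (startsWith(code, "F32")) return(!startsWith(code, "F32.3"))
    if (startsWith(code, "F33")) return(!startsWith(code, "F33.3"))
    if (startsWith(code, "F4")) {
      return(substr(code, 1, 3) %in% paste0("F4", 0:8))
    }
    startsWith(code, "F60")
  }
  if (any(vapply(codes, is_nonsmi, TRUE))) return("NonSMI")
  "Unclassified"
}

#' Build per-patient symptom profiles
#'
#' A patient has a symptom iff at least one instance of that concept is
#' labelled positive in any of their documents (unique-patient semantics).
#' Every patient with at least one document gets a profile, symptomatic or
#' not.
#'
#' @param predictions data.frame with columns `doc_id`, `concept`, `label`
#'   (e.g. from [instances_to_df] plus a label column).
#' @param metadata corpus data.frame (see [read_corpus]) with `doc_id`,
#'   `patient_id` and `icd10_codes`.
#' @param lexicon an [smi_lexicon], used to induce domain sets from symptom
#'   sets.
#' @return data.frame of class `patient_profiles`: `patient_id`,
#'   `diagnosis_group`, `n_documents`, list columns `symptoms` and `domains`.
#' @export
build_profiles <- function(predictions, metadata, lexicon) {
  stopifnot(is.data.frame(predictions), is.data.frame(metadata),
            inherits(lexicon, "smi_lexicon"))
  missing_docs <- setdiff(predictions$doc_id, metadata$doc_id)
  if (length(missing_docs)) {
    stop("predictions reference document(s) without patient metadata: ",
         paste(utils::head(missing_docs, 5), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(metadata$patient_id) | !nzchar(metadata$patient_id))) {
    stop("document without patient_id in metadata", call. = FALSE)
  }
  pos <- predictions[predictions$label == "positive", , drop = FALSE]
  pos$patient_id <- metadata$patient_id[match(pos$doc_id, metadata$doc_id)]
  patients <- sort(unique(metadata$patient_id))
  profiles <- do.call(rbind, lapply(patients, function(pid) {
    docs <- metadata[metadata$patient_id == pid, , drop = FALSE]
    codes <- unique(unlist(docs$icd10_codes))
    syms <- sort(unique(pos$concept[pos$patient_id == pid]))
    doms <- sort(unique(vapply(syms, function(s) domain_of(lexicon, s), "")))
    data.frame(patient_id = pid,
               diagnosis_group = assign_diagnosis_group(codes),
               n_documents = nrow(docs),
               symptoms = I(list(syms)),
               domains = I(list(doms)),
               stringsAsFactors = FALSE)
  }))
  class(profiles) <- c("patient_profiles", "data.frame")
  profiles
}

#' Total row for a diagnosis-by-domain crosstab
#'
#' @param cells numeric matrix of per-diagnosis-group counts (one row per
#'   group, one column per domain).
#' @return named numeric vector of column sums.
#' @export
crosstab_total_row <- function(cells) {
  stopifnot(is.matrix(cells) || is.data.frame(cells))
  colSums(as.matrix(cells))
}

#' Cross-tabulate patients by diagnosis group and symptom domain
#'
#' Each cell is the number of unique patients in the diagnosis group with at
#' least one symptom in the domain; a patient with symptoms in two domains
#' increments both columns once each. The Total row is the column sum over
#' the five diagnosis groups. Unclassified patients are dropped from the
#' table; their count is attached as the `n_unclassified` attribute.
#'
#' @param profiles a `patient_profiles` data.frame from [build_profiles].
#' @return integer matrix with rows F20, F25, F31, Multiple, NonSMI, Total
#'   and one column per symptom domain.
#' @export
crosstab_domains <- function(profiles) {
  stopifnot(is.data.frame(profiles), nrow(profiles) > 0L)
  groups <- setdiff(DIAGNOSIS_GROUPS, "Unclassified")
  tab <- matrix(0L, nrow = length(groups) + 1L, ncol = length(SYMPTOM_DOMAINS),
                dimnames = list(c(groups, "Total"), SYMPTOM_DOMAINS))
  for (g in groups) {
    sub <- profiles[profiles$diagnosis_group == g, , drop = FALSE]
    for (d in SYMPTOM_DOMAINS) {
      tab[g, d] <- sum(vapply(sub$domains, function(ds) d %in% ds, TRUE))
    }
  }
  tab["Total", ] <- as.integer(crosstab_total_row(tab[groups, , drop = FALSE]))
  attr(tab, "n_unclassified") <- sum(profiles$diagnosis_group == "Unclassified")
  tab
}

#' Integer percentage, rounded half away from zero
#'
#' The rounding rule used for all printed coverage percentages (e.g.
#' 6920 covered of 7962 patients is 86.91...%, printed as 87).
#'
#' @param covered,total non-negative counts; `total` > 0.
#' @return integer percentage.
#' @export
coverage_percentage <- function(covered, total) {
  stopifnot(total > 0)
  x <- 100 * covered / total
  as.integer(trunc(x + 0.5 * sign(x)))
}

#' Coverage statistics per cohort
#'
#' For each cohort (SMI = diagnosis groups F20/F25/F31/Multiple; NonSMI):
#' total positive instances; documents with at least one positive instance
#' (count and integer percentage of the cohort's documents); patients with at
#' least one symptom (count and integer percentage of the cohort's patients
#' with at least one document).
#'
#' @param predictions data.frame with `doc_id`, `concept`, `label`.
#' @param metadata corpus data.frame with `doc_id`, `patient_id`,
#'   `icd10_codes`.
#' @param profiles optional pre-computed `patient_profiles`; built from the
#'   arguments when omitted (needs `lexicon`).
#' @param lexicon an [smi_lexicon] (only needed when `profiles` is missing).
#' @return data.frame, one row per cohort: `cohort`, `n_symptoms`,
#'   `n_documents`, `documents_covered`, `documents_pct`, `n_patients`,
#'   `patients_covered`, `patients_pct`.
#' @export
coverage_stats <- function(predictions, metadata, profiles = NULL,
                           lexicon = NULL) {
  if (is.null(profiles)) {
    if (is.null(lexicon)) stop("supply either profiles or a lexicon",
                               call. = FALSE)
    profiles <- build_profiles(predictions, metadata, lexicon)
  }
  metadata$group <- profiles$diagnosis_group[match(metadata$patient_id,
                                                   profiles$patient_id)]
  cohort_of <- function(group) {
    ifelse(group %in% c("F20", "F25", "F31", "Multiple"), "SMI",
           ifelse(group == "NonSMI", "NonSMI", "Unclassified"))
  }
  metadata$cohort <- cohort_of(metadata$group)
  profiles$cohort <- cohort_of(profiles$diagnosis_group)
  pos <- predictions[predictions$label == "positive", , drop = FALSE]
  pos$cohort <- metadata$cohort[match(pos$doc_id, metadata$doc_id)]
  out <- do.call(rbind, lapply(c("SMI", "NonSMI"), function(ch) {
    docs <- metadata[metadata$cohort == ch, , drop = FALSE]
    if (nrow(docs) == 0L) {
      stop("cohort '", ch, "' contains no documents", call. = FALSE)
    }
    pats <- profiles[profiles$cohort == ch, , drop = FALSE]
    n_sym <- sum(pos$cohort == ch)
    docs_cov <- length(unique(pos$doc_id[pos$cohort == ch]))
    pats_cov <- sum(vapply(pats$symptoms, length, 0L) > 0)
    data.frame(cohort = ch,
               n_symptoms = n_sym,
               n_documents = nrow(docs),
               documents_covered = docs_cov,
               documents_pct = coverage_percentage(docs_cov, nrow(docs)),
               n_patients = nrow(pats),
               patients_covered = pats_cov,
               patients_pct = coverage_percentage(pats_cov, nrow(pats)),
               stringsAsFactors = FALSE)
  }))
  out
}
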