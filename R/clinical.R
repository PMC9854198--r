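# Clinical covariate simulation for the synthetic cohort.

#' Default clinical marginal frequencies
#'
#' Marginal category frequencies of the clinical covariates used by
#' [generate_clinical()], matching the distribution reported for a 270-patient
#' EGFR-mutant NSCLC cohort treated with first-line TKIs (nodal stage, distant
#' metastasis stage, histology, laboratory categories, smoking status).
#' Patients with unknown nodal stage are folded into the observed categories.
#'
#' @return named list of probability vectors.
#' @export
clinical_marginals <- function() {
  list(
    n_stage       = c(`0` = 69, `1` = 20, `2` = 75, `3` = 104) / 268,
    m_stage       = c(`0` = 10, `1a` = 82, `1b` = 41, `1c` = 137) / 270,
    histology     = c(adeno = 263, `non-adeno` = 7) / 270,
    total_protein = c(high = 87, low = 6, missing = 177) / 270,
    mcv           = c(high = 85, normal = 81, low = 5, missing = 99) / 270,
    smoking       = c(yes = 69, no = 201) / 270
  )
}

#' Simulate clinical covariates
#'
#' Draws independent categorical clinical covariates for `n` patients:
#' clinical N stage (0-3), M stage (0/1a/1b/1c), histology
#' (adenocarcinoma vs other NSCLC), total serum protein and mean corpuscular
#' volume categories (with an explicit "missing" level), and smoking status.
#'
#' @param n number of patients (>= 1).
#' @param marginals named list of category probabilities, see
#'   [clinical_marginals()].
#' @param seed optional RNG seed.
#' @return tibble with `patient_id` and one factor column per covariate.
#' @examples
#' generate_clinical(5, seed = 1)
#' @export
generate_clinical <- function(n, marginals = clinical_marginals(), seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a single count >= 1", call. = FALSE)
  }
  n <- as.integer(n)
  draw <- function(p) {
    factor(sample(names(p), n, replace = TRUE, prob = p), levels = names(p))
  }
  gen <- function() {
    tibble::tibble(
      patient_id    = sprintf("P%04d", seq_len(n)),
      n_stage       = draw(marginals$n_stage),
      m_stage       = draw(marginals$m_stage),
      histology     = draw(marginals$histology),
      total_protein = draw(marginals$total_protein),
      mcv           = draw(marginals$mcv),
      smoking       = draw(marginals$smoking)
    )
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Numeric encoding of clinical covariates
#'
#' Encodes the simulated clinical table for modelling: ordinal N stage (0-3),
#' ordinal M stage (0-3 for 0/1a/1b/1c), binary histology (1 = adenocarcinoma),
#' and indicator columns for the laboratory categories with their explicit
#' "missing" level; smoking as binary (1 = smoker).
#'
#' @param clinical tibble from [generate_clinical()].
#' @return tibble of numeric columns plus `patient_id`.
#' @export
encode_clinical <- function(clinical) {
  tibble::tibble(
    patient_id = clinical$patient_id,
    n_stage    = as.numeric(as.character(clinical$n_stage)),
    m_stage    = match(as.character(clinical$m_stage),
                       c("0", "1a", "1b", "1c")) - 1,
    histology  = as.numeric(clinical$histology == "adeno"),
    tp_high    = as.numeric(clinical$total_protein == "high"),
    tp_low     = as.numeric(clinical$total_protein == "low"),
    tp_missing = as.numeric(clinical$total_protein == "missing"),
    mcv_high   = as.numeric(clinical$mcv == "high"),
    mcv_low    = as.numeric(clinical$mcv == "low"),
    mcv_missing = as.numeric(clinical$mcv == "missing"),
    smoking    = as.numeric(clinical$smoking == "yes")
  )
}
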