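## Deterministic phenotype computations. Units are the conventional HOMA-IR
## pairing (insulin in mU/L, glucose in mmol/L, divisor 22.5) and are
## mandatory in input headers so mismatches fail loudly.

#' HOMA-IR insulin-resistance index
#'
#' `(fasting insulin [mU/L] x fasting glucose [mmol/L]) / 22.5`. The divisor
#' normalises a healthy reference (insulin 1 mU/L at glucose 22.5 mmol/L
#' gives exactly 1). Vectorised.
#'
#' @param insulin fasting insulin, mU/L (> 0).
#' @param glucose fasting glucose, mmol/L (> 0).
#' @return dimensionless HOMA-IR.
#' @examples
#' homaIr(1, 22.5)   # 1
#' homaIr(10, 9)     # 4
#' @export
homaIr <- function(insulin, glucose) {
  if (any(!is.finite(insulin)) || any(!is.finite(glucose)) ||
      any(insulin <= 0) || any(glucose <= 0))
    stop("insulin and glucose must be positive and finite")
  insulin * glucose / 22.5
}

#' NAFLD activity score (NAS)
#'
#' Sum of steatosis (0-3), lobular inflammation (0-3) and hepatocyte
#' ballooning (0-2); range 0-8. Fibrosis is staged separately and never
#' summed. When inflammation and ballooning are both 0 (no steatohepatitis
#' features), the total equals the steatosis score.
#'
#' @param steatosis integer 0-3.
#' @param inflammation lobular inflammation, integer 0-3.
#' @param ballooning hepatocyte ballooning, integer 0-2.
#' @return integer total, 0-8. Vectorised.
#' @examples
#' nasTotal(3, 0, 0)  # 3 == steatosis
#' nasTotal(3, 3, 2)  # 8, the maximum
#' @export
nasTotal <- function(steatosis, inflammation, ballooning) {
  chk <- function(x, lo, hi, nm) {
    if (any(is.na(x)) || any(x != as.integer(x)) || any(x < lo | x > hi))
      stop(nm, " must be an integer in [", lo, ", ", hi, "]")
  }
  chk(steatosis, 0, 3, "steatosis")
  chk(inflammation, 0, 3, "inflammation")
  chk(ballooning, 0, 2, "ballooning")
  as.integer(steatosis + inflammation + ballooning)
}

#' Read a phenotype table with mandatory unit-labelled headers
#'
#' Requires columns `animal_id`, `glucose_mmol_l`, `insulin_mu_l` (unit
#' suffixes enforced) and the NAS components `steatosis`,
#' `lobular_inflammation`, `ballooning`.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readPhenotypes <- function(path) {
  df <- readTsv(path)
  need <- c("animal_id", "glucose_mmol_l", "insulin_mu_l", "steatosis",
            "lobular_inflammation", "ballooning")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype table missing column(s): ", paste(miss, collapse = ", "),
         " (glucose/insulin headers must carry units: _mmol_l, _mu_l)")
  df
}

#' Augment a phenotype table with HOMA-IR and total NAS
#'
#' @param pheno data.frame as from [readPhenotypes()].
#' @return the table with `homa_ir` and `nas_total` columns (re)computed.
#' @export
phenotypeSummary <- function(pheno) {
  pheno$homa_ir <- homaIr(pheno$insulin_mu_l, pheno$glucose_mmol_l)
  pheno$nas_total <- nasTotal(pheno$steatosis, pheno$lobular_inflammation,
                              pheno$ballooning)
  pheno
}
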