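#' MDRD estimated glomerular filtration rate
#'
#' Four-variable IDMS-traceable MDRD equation:
#' \deqn{eGFR = 175 \cdot Scr^{-1.154} \cdot age^{-0.203}
#'   \cdot 0.742^{[female]} \cdot 1.212^{[black]}}
#' in mL/min/1.73 m^2, with serum creatinine in mg/dL and age in years.
#'
#' @param scr_mg_dl Serum creatinine (mg/dL), > 0.  Vectorised.
#' @param age_y Age in years, > 0.
#' @param female,black Logical indicators.
#' @return eGFR in mL/min/1.73 m^2.
#' @examples
#' egfr_mdrd(1.0, 50, female = FALSE)
#' @export
egfr_mdrd <- function(scr_mg_dl, age_y, female = FALSE, black = FALSE) {
  if (any(scr_mg_dl <= 0) || any(age_y <= 0))
    stop("creatinine and age must be positive", call. = FALSE)
  175 * scr_mg_dl^(-1.154) * age_y^(-0.203) *
    ifelse(female, 0.742, 1) * ifelse(black, 1.212, 1)
}

#' Hepatic function flag
#'
#' Classifies hepatic function as abnormal when any serum marker strictly
#' exceeds its threshold: AST > 40 IU/L, ALT > 40 IU/L, GGT > 63 IU/L, or
#' total bilirubin > 1.2 mg/dL.  Values exactly at a threshold are normal.
#'
#' @param ast,alt,ggt,tbil Serum values (vectorised), all >= 0.
#' @return Character vector, `"normal"` or `"abnormal"`.
#' @examples
#' hepatic_flag(40, 40, 63, 1.2)  # "normal" (thresholds are strict)
#' hepatic_flag(41, 0, 0, 0)      # "abnormal"
#' @export
hepatic_flag <- function(ast, alt, ggt, tbil) {
  if (any(c(ast, alt, ggt, tbil) < 0))
    stop("serum values must be >= 0", call. = FALSE)
  ifelse(ast > 40 | alt > 40 | ggt > 63 | tbil > 1.2,
         "abnormal", "normal")
}
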