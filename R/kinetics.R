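## Steady-state enzyme kinetics: specificity constants and relative
## cleavage efficiencies for lesion-containing restriction-site substrates.
## Measured K_M / V_max values are inputs (taken as printed); only the
## ratios are computed here. The Michaelis-Menten refit exists to validate
## synthetic fixtures, not to re-derive measured constants.

#' Specificity constant V_max / K_M
#'
#' @param v_max maximal velocity (nM min^-1).
#' @param k_m Michaelis constant (nM, > 0).
#' @return Specificity constant in min^-1.
#' @export
specificity <- function(v_max, k_m) {
  if (any(!is.finite(k_m)) || any(k_m <= 0))
    stop("input error: K_M must be positive", call. = FALSE)
  v_max / k_m
}

#' Cleavage efficiency relative to a reference substrate
#'
#' @param spec specificity constant(s) of the site(s) of interest (min^-1).
#' @param reference specificity constant of the reference (undamaged)
#'   substrate.
#' @return Dimensionless ratio; 1 for the reference against itself.
#' @export
relative_efficiency <- function(spec, reference) {
  if (!is.finite(reference) || reference <= 0)
    stop("input error: undefined reference specificity", call. = FALSE)
  spec / reference
}

#' Michaelis-Menten initial rate
#'
#' `v0 = V_max * S / (K_M + S)`; in the low-substrate limit the slope of v0
#' versus S approaches V_max / K_M, the regime in which a specificity
#' constant can be read from a linear fit even when saturation is
#' unreachable.
#'
#' @param v_max,k_m kinetic constants (nM min^-1, nM).
#' @param s substrate concentration(s), nM (>= 0).
#' @return Initial rate(s), nM min^-1.
#' @export
mm_rate <- function(v_max, k_m, s) {
  stopifnot(all(s >= 0))
  v_max * s / (k_m + s)
}

#' Refit Michaelis-Menten constants from rate data
#'
#' Nonlinear least squares via the self-starting `SSmicmen` model.
#'
#' @param s substrate concentrations, nM.
#' @param v0 initial rates, nM min^-1.
#' @return List with `v_max`, `k_m` and the `nls` fit.
#' @export
fit_mm <- function(s, v0) {
  df <- data.frame(s = s, v0 = v0)
  fit <- stats::nls(v0 ~ SSmicmen(s, Vm, K), data = df)
  co <- stats::coef(fit)
  list(v_max = unname(co["Vm"]), k_m = unname(co["K"]), fit = fit)
}

#' Measured EcoRI kinetics on oxoG-containing substrates
#'
#' Loads the packaged table of steady-state constants for cleavage of the
#' GAATTC site in its undamaged and 8-oxoguanine-modified contexts and
#' computes specificity constants and efficiencies relative to the
#' undamaged substrate. Substrates for which saturation was unreachable
#' carry a directly measured specificity (from the linear v0-versus-S
#' slope) instead of individual K_M / V_max values.
#'
#' @param path TSV path; defaults to the packaged table.
#' @return Data frame with `site`, `k_m_nM`, `v_max_nM_min`,
#'   `specificity_min`, `relative`.
#' @export
kinetics_table <- function(path = system.file("extdata",
                                              "ecori_kinetics.tsv",
                                              package = "oxoduplex")) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  spec <- vapply(seq_len(nrow(d)), function(i) {
    if (is.finite(d$k_m_nM[i]) && is.finite(d$v_max_nM_min[i]))
      specificity(d$v_max_nM_min[i], d$k_m_nM[i])
    else d$specificity_direct_min[i]
  }, numeric(1))
  ref <- spec[which(d$reference)[1]]
  data.frame(site = d$site, k_m_nM = d$k_m_nM, v_max_nM_min = d$v_max_nM_min,
             specificity_min = spec,
             relative = ifelse(is.finite(spec),
                               relative_efficiency(spec, ref), NA_real_),
             stringsAsFactors = FALSE)
}
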