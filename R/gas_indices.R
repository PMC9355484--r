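# Derived stomatal indices and fluorescence-based Rubisco velocity
# partitioning from paired gas-exchange / fluorescence observations.

#' Stomatal indices from a steady-state gas-exchange record
#'
#' Intrinsic water-use efficiency WUE = A/gs, internal-to-external CO2 ratio
#' Ci/Ca, and the stomatal limitation index Ls = 1 − Ci/Ca.
#'
#' @param record list or one-row data.frame with `a`, `gs`, `ci`, `ca`
#'   (case-insensitive names); or supply the fields directly.
#' @param a,gs,ci,ca alternative direct inputs (vectorised).
#' @return data.frame with columns `wue` (µmol CO2 mol⁻¹ H2O), `ci_ca`
#'   (dimensionless) and `ls` (dimensionless; `ls + ci_ca == 1` exactly).
#' @export
#' @examples
#' stomatal_indices(a = 12, gs = 0.3, ci = 249, ca = 415)
stomatal_indices <- function(record = NULL, a = NULL, gs = NULL,
                             ci = NULL, ca = NULL) {
  if (!is.null(record)) {
    r <- if (is.data.frame(record)) record else as.data.frame(record)
    names(r) <- tolower(names(r))
    a <- r$a; gs <- r$gs; ci <- r$ci; ca <- r$ca
  }
  if (any(gs <= 0)) stop("gs must be positive")
  if (any(ca <= 0)) stop("ca must be positive")
  ci_ca <- ci / ca
  data.frame(wue = a / gs, ci_ca = ci_ca, ls = 1 - ci_ca)
}

#' Rubisco carboxylation and oxygenation velocities
#'
#' Fluorescence-based partitioning of net assimilation into carboxylation
#' (Vc) and oxygenation (Vo) velocities, assuming 4 electrons per
#' carboxylation and 4 per oxygenation:
#' \deqn{Vc = (ETR + 8(A + Rd))/12, \quad Vo = 2(ETR - 4(A + Rd))/12.}
#' Both stoichiometric identities hold algebraically:
#' A = Vc − 0.5·Vo − Rd and ETR = 4(Vc + Vo). When the measured ETR is
#' insufficient to support the stated A (implying Vo < 0), the pair is
#' returned with `valid = FALSE` rather than raising.
#'
#' @param a net CO2 assimilation, µmol m⁻² s⁻¹.
#' @param etr linear electron transport rate, µmol e⁻ m⁻² s⁻¹ (≥ 0).
#' @param rd day respiration, µmol m⁻² s⁻¹ (≥ 0); default 1.
#' @param e_c,e_o electron costs per carboxylation / oxygenation (default 4
#'   and 4, giving the 8/4/12 coefficients above); exposed for sensitivity
#'   analyses.
#' @return data.frame with columns `vc`, `vo`, `valid`.
#' @export
#' @examples
#' rubisco_velocities(a = 10, etr = 100, rd = 1)
rubisco_velocities <- function(a, etr, rd = 1, e_c = 4, e_o = 4) {
  if (any(etr < 0)) stop("etr must be non-negative")
  if (any(rd < 0)) stop("rd must be non-negative")
  # Solve  a = vc - 0.5 vo - rd ;  etr = e_c vc + e_o vo  for (vc, vo)
  g <- a + rd
  det <- e_o + 0.5 * e_c
  vc <- (e_o * g + 0.5 * etr) / det
  vo <- (etr - e_c * g) / det
  data.frame(vc = vc, vo = vo, valid = vo >= 0)
}

#' Percent change between a control and a treated mean
#'
#' 100·(control − treated)/control: a decline is positive, an increase
#' negative, matching the convention of reporting treatment effects as
#' percent reductions relative to control.
#'
#' @param control_mean control-group mean (non-zero).
#' @param treated_mean treated-group mean.
#' @return percent change (decline-positive).
#' @export
#' @examples
#' percent_change(100, 86)   # 14
#' percent_change(100, 106)  # -6
percent_change <- function(control_mean, treated_mean) {
  if (any(control_mean == 0)) stop("control_mean must be non-zero")
  100 * (control_mean - treated_mean) / control_mean
}
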