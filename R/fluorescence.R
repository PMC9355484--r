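# PAM chlorophyll-fluorescence calculus.
#
# Quenching analysis of one saturating-pulse measurement: dark-adapted
# maximal PSII efficiency, light-adapted quenching coefficients under the
# puddle (qP) and lake (qL) antenna models, the three-way partition of
# absorbed excitation energy (PhiPSII + PhiNPQ + PhiNO = 1), Stern-Volmer
# NPQ, and the linear electron transport rate.

#' Maximal PSII photochemical efficiency (dark-adapted)
#'
#' Fv/Fm = (Fm − Fo)/Fm from a dark-adapted saturating-pulse measurement.
#' Healthy unstressed C3 leaves typically fall in 0.75–0.83.
#'
#' @param fo minimal dark-adapted fluorescence, arbitrary units.
#' @param fm maximal dark-adapted fluorescence, same units.
#' @return Fv/Fm, dimensionless in (0, 1).
#' @export
#' @examples
#' dark_adapted_indices(500, 2000)  # 0.75
dark_adapted_indices <- function(fo, fm) {
  if (any(fo <= 0) || any(fm <= 0)) stop("fo and fm must be positive")
  if (any(fo >= fm)) stop("fo must be smaller than fm")
  1 - fo / fm
}

#' Estimate Fo' when the far-red measurement is missing
#'
#' Oxborough–Baker relation Fo′ = Fo / (Fv/Fm + Fo/Fm′). Exact fallback for
#' datasets lacking the far-red minimal-fluorescence step; at Fm′ = Fm it
#' reduces to Fo′ = Fo.
#'
#' @param fo,fm dark-adapted minimal and maximal fluorescence (0 < fo < fm).
#' @param fm_prime light-adapted maximal fluorescence, 0 < fm_prime ≤ fm.
#' @return estimated Fo′, in (0, fo].
#' @export
estimate_fo_prime <- function(fo, fm, fm_prime) {
  if (any(fo <= 0) || any(fo >= fm)) stop("need 0 < fo < fm")
  if (any(fm_prime <= 0)) stop("fm_prime must be positive")
  if (any(fm_prime > fm)) stop("fm_prime must not exceed fm")
  fo / ((1 - fo / fm) + fo / fm_prime)
}

#' Light-adapted fluorescence indices and PSII energy partitioning
#'
#' Computes the standard quenching-analysis parameter set from the raw
#' F-levels of one light-adapted saturating-pulse measurement:
#' \itemize{
#'   \item ΦPSII = (Fm′ − Fs)/Fm′ — effective PSII quantum yield
#'   \item ΦNPQ = Fs/Fm′ − Fs/Fm — yield of regulated thermal dissipation
#'   \item ΦNO = Fs/Fm — yield of non-regulated dissipation
#'   \item qP = (Fm′ − Fs)/(Fm′ − Fo′) — photochemical quenching, puddle model
#'   \item qL = qP · Fo′/Fs — photochemical quenching, lake model
#'   \item NPQ = (Fm − Fm′)/Fm′ — Stern–Volmer non-photochemical quenching
#'   \item Fv′/Fm′ = (Fm′ − Fo′)/Fm′
#' }
#' The three yields partition absorbed excitation energy and sum to one by
#' construction. 1 − qL (the fraction of closed PSII centres, i.e. reduced
#' primary quinone acceptor QA, under the lake model) is returned as its own
#' field because it is commonly plotted directly.
#'
#' @param record list or one-row data.frame with `fo`, `fm`, `fs`,
#'   `fm_prime` (alias `fmp`), optional `fo_prime` (alias `fop`), and
#'   optionally `q` (actinic PPFD), `alpha`, `f_psii` for ETR.
#' @param q,alpha,f_psii actinic PPFD, leaf absorptance and PSII fraction
#'   used for ETR when not present in the record (defaults 0.84 and 0.5 are
#'   the conventional broad-leaf values).
#' @return list of class `fluor_indices` with fields `fv_fm`, `fvp_fmp`,
#'   `phi_psii`, `phi_npq`, `phi_no`, `qp`, `ql`, `one_minus_ql`, `npq`,
#'   `etr` (NA when no PPFD is available).
#' @export
#' @examples
#' light_adapted_indices(list(fo = 500, fm = 2000, fs = 750,
#'                            fm_prime = 1250, fo_prime = 450))
light_adapted_indices <- function(record, q = NULL, alpha = 0.84,
                                  f_psii = 0.5) {
  r <- .lower_fields(record)
  fo <- r$fo; fm <- r$fm; fs <- r$fs
  fmp <- r$fm_prime %||% r$fmp
  fop <- r$fo_prime %||% r$fop
  if (is.null(fo) || is.null(fm) || is.null(fs) || is.null(fmp))
    stop("record must provide fo, fm, fs and fm_prime")
  if (is.null(fop) || is.na(fop)) fop <- estimate_fo_prime(fo, fm, fmp)
  viol <- validate_fluor_record(list(fo = fo, fm = fm, fs = fs,
                                     fm_prime = fmp, fo_prime = fop))
  if (length(viol))
    stop("inadmissible fluorescence record: ", paste(viol, collapse = "; "))
  if (fmp == fop)
    stop("degenerate denominator for qP: fm_prime equals fo_prime")

  phi_psii <- (fmp - fs) / fmp
  phi_no <- fs / fm
  phi_npq <- fs / fmp - fs / fm
  qp <- (fmp - fs) / (fmp - fop)
  ql <- qp * fop / fs
  npq <- (fm - fmp) / fmp
  fvp_fmp <- (fmp - fop) / fmp

  q_use <- r$q %||% q
  etr <- if (is.null(q_use) || is.na(q_use)) NA_real_ else
    electron_transport_rate(phi_psii, q_use,
                            r$alpha %||% alpha, r$f_psii %||% f_psii)
  structure(list(fv_fm = 1 - fo / fm, fvp_fmp = fvp_fmp,
                 phi_psii = phi_psii, phi_npq = phi_npq, phi_no = phi_no,
                 qp = qp, ql = ql, one_minus_ql = 1 - ql,
                 npq = npq, etr = etr),
            class = "fluor_indices")
}

#' Linear electron transport rate
#'
#' ETR = ΦPSII · Q · α · f, the Genty-type linear electron flux through
#' PSII, where Q is incident PPFD, α the leaf absorptance and f the fraction
#' of absorbed quanta reaching PSII.
#'
#' @param phi_psii effective PSII quantum yield in [0, 1].
#' @param q incident PPFD, µmol photons m⁻² s⁻¹ (≥ 0).
#' @param alpha leaf absorptance in (0, 1]; default 0.84.
#' @param f_psii PSII fraction in (0, 1]; default 0.5.
#' @return ETR, µmol electrons m⁻² s⁻¹.
#' @export
#' @examples
#' electron_transport_rate(0.4, 500)  # 84
electron_transport_rate <- function(phi_psii, q, alpha = 0.84, f_psii = 0.5) {
  if (any(phi_psii < 0 | phi_psii > 1)) stop("phi_psii must lie in [0,1]")
  if (any(q < 0)) stop("q must be non-negative")
  if (any(alpha <= 0 | alpha > 1)) stop("alpha must lie in (0,1]")
  if (any(f_psii <= 0 | f_psii > 1)) stop("f_psii must lie in (0,1]")
  phi_psii * q * alpha * f_psii
}
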