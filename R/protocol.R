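#' Default measurement protocol
#'
#' Instrument protocol used throughout the package: the CO2 setpoint path of
#' an A/Ci auto-program (a decreasing-then-ascending bitonic sequence starting
#' from ambient), the PPFD levels of a light-response auto-program, the
#' saturating-pulse and actinic intensities of the PAM fluorometry routine,
#' and the steady-state chamber environment.
#'
#' @param co2_setpoints CO2 setpoints of the A/Ci program, µmol mol⁻¹.
#' @param include_ambient logical; record the starting ambient concentration
#'   as an additional (first) observation of the A/Ci curve.
#' @param ppfd_levels PPFD levels of the light-response program,
#'   µmol photons m⁻² s⁻¹.
#' @param saturating_pulse saturating flash intensity, µmol m⁻² s⁻¹.
#' @param actinic actinic illumination during light-adapted fluorescence,
#'   µmol m⁻² s⁻¹.
#' @param chamber_co2,chamber_ppfd,chamber_rh,chamber_t steady-state chamber
#'   environment: CO2 (µmol mol⁻¹), PPFD (µmol m⁻² s⁻¹), relative humidity
#'   (fraction) and temperature (°C).
#' @return A list of class `protocol_config`.
#' @export
#' @examples
#' p <- default_protocol()
#' p$co2_setpoints
default_protocol <- function(co2_setpoints = c(300, 200, 100, 50, 200, 400,
                                               600, 800, 1000, 1200, 1500),
                             include_ambient = FALSE,
                             ppfd_levels = c(0, 10, 50, 75, 100, 200, 400,
                                             600, 800, 1000, 1200, 1500),
                             saturating_pulse = 8000,
                             actinic = 1400,
                             chamber_co2 = 415,
                             chamber_ppfd = 500,
                             chamber_rh = 0.5,
                             chamber_t = 24) {
  stopifnot(length(co2_setpoints) > 0, length(ppfd_levels) > 0,
            all(co2_setpoints >= 0), all(ppfd_levels >= 0),
            saturating_pulse >= 0, actinic >= 0)
  structure(list(co2_setpoints = co2_setpoints,
                 include_ambient = isTRUE(include_ambient),
                 ppfd_levels = ppfd_levels,
                 saturating_pulse = saturating_pulse,
                 actinic = actinic,
                 chamber_co2 = chamber_co2,
                 chamber_ppfd = chamber_ppfd,
                 chamber_rh = chamber_rh,
                 chamber_t = chamber_t),
            class = "protocol_config")
}

#' A/Ci observation grid implied by a protocol
#'
#' The CO2 setpoints actually recorded, including the ambient starting point
#' when the protocol flags it.
#'
#' @param protocol a `protocol_config`.
#' @return numeric vector of CO2 setpoints, µmol mol⁻¹.
#' @export
aci_grid <- function(protocol = default_protocol()) {
  if (protocol$include_ambient)
    c(protocol$chamber_co2, protocol$co2_setpoints)
  else protocol$co2_setpoints
}

#' Read a protocol / dialect configuration from YAML
#'
#' Loads a YAML file holding any of: `protocol` (fields of
#' [default_protocol()]), `column_map` (named mapping from canonical column
#' names to file column names), and `unit_scales` (named numeric multipliers
#' applied per canonical column at read time).
#'
#' @param path YAML file path.
#' @return list with elements `protocol`, `column_map`, `unit_scales`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  protocol <- do.call(default_protocol, as.list(raw$protocol %||% list()))
  column_map <- raw$column_map %||% list()
  unit_scales <- raw$unit_scales %||% list()
  if (length(unit_scales))
    unit_scales <- stats::setNames(as.numeric(unlist(unit_scales)),
                                   names(unit_scales))
  list(protocol = protocol,
       column_map = unlist(column_map),
       unit_scales = unit_scales)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
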