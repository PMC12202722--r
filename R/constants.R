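#' Gyromagnetic ratio of a nucleus
#'
#' Returns the gyromagnetic ratio in MHz/T for the nuclei used throughout the
#' package. Values: 1H 42.577 MHz/T, 13C 10.708 MHz/T. Any other numeric value
#' can be passed straight through where a `gamma` argument is accepted.
#'
#' @param nucleus `"13C"` (default) or `"1H"`.
#' @return Gyromagnetic ratio in MHz/T.
#' @export
#' @examples
#' gyromagnetic_ratio("13C")
gyromagnetic_ratio <- function(nucleus = c("13C", "1H")) {
  nucleus <- match.arg(nucleus)
  c(`13C` = 10.708, `1H` = 42.577)[[nucleus]]
}

#' Default 13C resonance frequency at 7 T
#'
#' 10.708 MHz/T x 7 T, conventionally quoted as 74.96 MHz.
#' @return Frequency in MHz.
#' @export
carbon_frequency_7t <- function() 74.96

stop_invalid <- function(...) {
  stop(structure(class = c("hpmrsim_invalid_parameter", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
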