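# Canonical internal units: mass mg, volume L, time h; systemic
# concentrations mg/L; enzyme-site concentrations umol/L.  Conversion between
# the two concentration scales goes through the molecular weight.

#' Convert mg/L to umol/L
#' @param x concentration in mg/L.
#' @param mw molecular weight in g/mol.
#' @return concentration in umol/L.
#' @export
mgL_to_uM <- function(x, mw) x * 1000 / mw

#' Convert umol/L to mg/L
#' @param x concentration in umol/L.
#' @param mw molecular weight in g/mol.
#' @return concentration in mg/L.
#' @export
uM_to_mgL <- function(x, mw) x * mw / 1000

# ul/min scaled by mg of microsomal protein (or million cells) -> L/h
.ulmin_to_Lh <- function(ul_min, scale) ul_min * scale * 60 / 1e6
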