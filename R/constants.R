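# Physical constants and unit factors shared across the pipeline.

.R_GAS <- 8.314          # J mol-1 K-1
.KELVIN0 <- 273.15
.T_REF <- 298.15         # K, van 't Hoff reference temperature
.MOLAR_MASS <- c(CH4 = 16.04, CO2 = 44.01)  # g mol-1
.MOLAR_MASS_C <- 12.01
.GWP100_CH4 <- 28        # mass-basis 100-yr global warming potential of CH4
.SEC_PER_DAY <- 86400

#' @keywords internal
match_gas <- function(gas) {
  gas <- toupper(as.character(gas))
  bad <- !gas %in% c("CH4", "CO2")
  if (any(bad))
    stop("unknown gas: ", paste(unique(gas[bad]), collapse = ", "),
         " (supported: CH4, CO2)", call. = FALSE)
  gas
}

stopifnot_finite <- function(x, name) {
  if (!all(is.finite(x))) stop("'", name, "' must be finite", call. = FALSE)
  invisible(x)
}
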