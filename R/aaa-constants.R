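# Package-wide constants (loaded before all other sources).

#' The five columnar input classes of a T4 neuron, in canonical order
#' @export
T4_INPUT_CLASSES <- c("Mi9", "Tm3", "Mi1", "Mi4", "C3")

# free-parameter naming used by the fitting and posterior routines
PARAM_NAMES <- c(paste0("gain_", T4_INPUT_CLASSES),
                 paste0("thr_", T4_INPUT_CLASSES), "E_leak", "g_leak")
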