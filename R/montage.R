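#' Standard electrode montages
#'
#' `montage_60()` returns the 60 most central positions of the extended
#' 10-20 layout, the montage assumed by the cohort generator defaults.
#' `montage_16()` is a reduced central subset used for fast simulations;
#' both contain the channels the analysis depends on (FCz, Cz, C5, C6).
#'
#' @return Character vector of unique channel labels.
#' @export
#' @examples
#' length(montage_60())
#' all(c("FCz", "C5", "C6", "Cz") %in% montage_16())
montage_60 <- function() {
  c("Fp1", "Fp2",
    "AF7", "AF3", "AFz", "AF4", "AF8",
    "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO7", "PO3", "POz", "PO4", "PO8",
    "O1", "Oz", "O2")
}

#' @rdname montage_60
#' @export
montage_16 <- function() {
  c("Fz", "F3", "F4", "FC1", "FC2", "FCz", "C3", "C4", "Cz",
    "C5", "C6", "CP1", "CP2", "Pz", "O1", "O2")
}

# channels that must be present for the pipeline's statistics
required_channels <- function() c("FCz", "Cz", "C5", "C6")

# fronto-central channels that carry the planted class effect (those present
# in the montage are used)
focus_channels <- function() c("Fz", "FCz", "FC1", "FC2", "Cz")
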