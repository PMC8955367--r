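# Electrode montages ---------------------------------------------------------

# 64-channel extended 10-20 Quick-Cap layout, front to back, left to right.
# M1/M2 are the mastoid references and are dropped from analysis montages.
.montage64 <- c(
  "FP1", "FPZ", "FP2",
  "AF3", "AF4",
  "F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8",
  "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8",
  "T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8",
  "M1", "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8", "M2",
  "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8",
  "PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8",
  "CB1", "O1", "OZ", "O2", "CB2"
)

.reference_channels <- c("M1", "M2")

#' Standard 10-20 analysis montage
#'
#' Channel labels of the extended 10-20 system as recorded by a 64-electrode
#' cap, with the mastoid reference electrodes (M1, M2) removed, leaving the
#' 62 scalp channels used as network nodes.
#'
#' @param include_reference if `TRUE`, return all 64 labels including M1/M2.
#' @return character vector of channel labels in canonical (cap) order.
#' @export
#' @examples
#' length(montage_1020())  # 62
montage_1020 <- function(include_reference = FALSE) {
  if (include_reference) .montage64 else setdiff(.montage64, .reference_channels)
}
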