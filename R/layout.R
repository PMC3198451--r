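#' Electrode layout: an 80-channel extended 10-20 montage
#'
#' Deterministic unit-disc (top view) projection of an 80-electrode
#' extended 10-20 arrangement. Rows run anterior (+y, nose) to posterior;
#' odd-numbered labels sit on the left (-x), even-numbered on the right,
#' `z`-labelled electrodes on the midline. The montage is exactly
#' mirror-symmetric: for every electrode at (x, y) there is a partner at
#' (-x, y), which downstream code relies on when checking left/right
#' topography mirroring. It contains the midline electrodes Fz, FCz, Cz,
#' CPz, Pz plus two flanking electrode columns per side for each of those
#' rows (the fronto-central analysis set).
#'
#' @return data.frame with columns `label`, `x`, `y` (80 rows).
#' @examples
#' lay <- makeLayout()
#' nrow(lay)                      # 80
#' lay[lay$label == "FCz", ]
#' @export
makeLayout <- function() {
  row <- function(y, labels, cols) {
    data.frame(label = labels, x = 0.95 * (cols / 5) * sqrt(1 - y^2),
               y = y, stringsAsFactors = FALSE)
  }
  lay <- rbind(
    row(0.80, c("Fp1", "Fpz", "Fp2"), c(-1, 0, 1)),
    row(0.60, c("AF7", "AF3", "AF1", "AFz", "AF2", "AF4", "AF8"),
        c(-4, -2, -1, 0, 1, 2, 4)),
    row(0.40, c("F9", "F7", "F5", "F3", "F1", "Fz",
                "F2", "F4", "F6", "F8", "F10"), -5:5),
    row(0.20, c("FT9", "FT7", "FC5", "FC3", "FC1", "FCz",
                "FC2", "FC4", "FC6", "FT8", "FT10"), -5:5),
    row(0.00, c("T9", "T7", "C5", "C3", "C1", "Cz",
                "C2", "C4", "C6", "T8", "T10"), -5:5),
    row(-0.20, c("TP9", "TP7", "CP5", "CP3", "CP1", "CPz",
                 "CP2", "CP4", "CP6", "TP8", "TP10"), -5:5),
    row(-0.40, c("P9", "P7", "P5", "P3", "P1", "Pz",
                 "P2", "P4", "P6", "P8", "P10"), -5:5),
    row(-0.60, c("PO9", "PO7", "PO3", "POz", "PO4", "PO8", "PO10"),
        c(-5, -4, -2, 0, 2, 4, 5)),
    row(-0.80, c("O9", "O1", "Oz", "O2", "O10"), c(-5, -1, 0, 1, 5)),
    row(-0.95, c("I1", "Iz", "I2"), c(-1, 0, 1))
  )
  rownames(lay) <- NULL
  lay
}

#' Write an electrode layout as TSV (label, x, y)
#'
#' @param layout data.frame from [makeLayout()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeLayout <- function(layout, path) {
  utils::write.table(layout, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Left<->right mirror partner indices of a layout (used by tests and the
# topography generator's symmetry guarantees).
mirrorIndex <- function(layout) {
  key <- paste(round(-layout$x, 9), round(layout$y, 9))
  match(key, paste(round(layout$x, 9), round(layout$y, 9)))
}
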