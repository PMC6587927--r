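#' Standard 64-channel montage
#'
#' Builds the 64-channel extended 10-20 montage used throughout the package,
#' with schematic 2-D positions on a unit head disk. Positions are a planar
#' projection generated from the row (anterior-posterior) and index
#' (lateral) structure of the channel labels; they are intended for synthetic
#' topographies and spatial weighting, not for source analysis.
#'
#' @return An object of class `montage_spec`: a data.frame with columns
#'   `channel`, `x`, `y` (64 rows, positions unique, all parietal ROI
#'   channels present).
#' @export
standard_montage_64 <- function() {
  channels <- c(
    "Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3", "FC1",
    "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1", "P3", "P5",
    "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz", "Pz", "CPz",
    "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4", "F6", "F8", "FT8",
    "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4", "C6", "T8", "TP8", "CP6",
    "CP4", "CP2", "P2", "P4", "P6", "P8", "P10", "PO8", "PO4", "O2")
  row_y <- c(Fp = 0.88, AF = 0.70, F = 0.52, FT = 0.30, FC = 0.30,
             T = 0.0, C = 0.0, TP = -0.30, CP = -0.30, P = -0.52,
             PO = -0.70, O = -0.88, I = -0.98)
  pos <- t(vapply(channels, function(ch) {
    m <- regmatches(ch, regexec("^([A-Za-z]+?)(z|[0-9]+)$", ch))[[1]]
    prefix <- m[2]; suffix <- m[3]
    y <- row_y[[prefix]]
    halfw <- sqrt(max(1.0 - y^2, 0.04))
    if (suffix == "z") {
      x <- 0
    } else {
      n <- as.integer(suffix)
      side <- if (n %% 2 == 1) -1 else 1
      x <- side * (ceiling(n / 2) / 5) * halfw
    }
    c(x = x, y = y)
  }, numeric(2)))
  out <- data.frame(channel = channels, x = pos[, "x"], y = pos[, "y"],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("montage_spec", "data.frame")
  validate_montage(out)
  out
}

validate_montage <- function(montage) {
  stopifnot(is.data.frame(montage),
            all(c("channel", "x", "y") %in% names(montage)))
  if (nrow(montage) != 64L)
    stop("montage must have exactly 64 channels, got ", nrow(montage))
  missing_roi <- setdiff(roi_channels(), montage$channel)
  if (length(missing_roi))
    stop("montage lacks ROI channel(s): ", paste(missing_roi, collapse = ", "))
  if (anyDuplicated(paste(montage$x, montage$y)))
    stop("montage positions must be unique")
  invisible(montage)
}

#' @export
print.montage_spec <- function(x, ...) {
  cat("<montage_spec> ", nrow(x), " channels; ROI present: ",
      paste(roi_channels(), collapse = ", "), "\n", sep = "")
  invisible(x)
}
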