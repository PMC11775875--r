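#' Standard 10-10 montage with idealized spherical positions
#'
#' Positions are computed on a unit sphere from the electrode label's
#' sagittal row (Fp, AF, F, FC, C, CP, P, PO, O) and lateral column
#' (z, 1/2, ..., 9/10): the row sets an anterior-posterior rotation in
#' 18 degree steps from the vertex and the column a lateral rotation in
#' 18 degree steps (odd = left, even = right). This idealized geometry is
#' sufficient for distance-weighted channel interpolation and topography
#' simulation; it is not a digitized cap.
#'
#' @param labels channel labels to include; default is a 45-channel EEG
#'   set plus three ocular channels (`VEOG`, `HEOGL`, `HEOGR`).
#' @return data.frame with columns `label`, `kind` (`"eeg"`/`"eog"`),
#'   `x`, `y`, `z` (unit sphere; EOG rows are placed on the lower front
#'   of the sphere). `x` points right, `y` anterior, `z` up.
#' @export
standard_montage <- function(labels = NULL) {
  default_eeg <- c(
    "Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6",
    "T7", "C3", "Cz", "C4", "T8",
    "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
    "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
    "PO9", "PO7", "PO3", "POz", "PO4", "PO8", "PO10",
    "O1", "Oz", "O2")
  eog <- c("VEOG", "HEOGL", "HEOGR")
  if (is.null(labels)) labels <- c(default_eeg, eog)
  labels <- normalize_channel_labels(labels)
  kind <- ifelse(grepl("EOG", labels, ignore.case = TRUE), "eog", "eeg")
  pos <- t(vapply(labels, electrode_position, numeric(3)))
  data.frame(label = labels, kind = kind,
             x = pos[, 1], y = pos[, 2], z = pos[, 3],
             stringsAsFactors = FALSE)
}

# map a 10-10 label to xyz on the unit sphere (see standard_montage)
electrode_position <- function(label) {
  if (grepl("EOG", label, ignore.case = TRUE)) {
    # below-equator frontal placements, used only for plotting/QC
    return(switch(toupper(label),
                  VEOG = c(0.35, 0.9, -0.26),
                  HEOGL = c(-0.75, 0.62, -0.22),
                  HEOGR = c(0.75, 0.62, -0.22),
                  c(0, 1, -0.3)))
  }
  m <- regmatches(label, regexec("^([A-Za-z]+)(z|[0-9]+)$", label))[[1]]
  if (length(m) != 3L) stop("unrecognized electrode label: ", label)
  row <- toupper(m[2]); col <- m[3]
  ap <- c(FP = 72, AF = 54, F = 36, FC = 18, C = 0,
          CP = -18, P = -36, PO = -54, O = -72, I = -90)
  # T7/T8 are the temporal continuation of the C row
  if (row == "T") { row <- "C"; col <- if (col %in% c("7", "3")) "7" else "8" }
  if (!row %in% names(ap)) stop("unrecognized electrode row in: ", label)
  u <- ap[[row]] * pi / 180
  if (col == "z" || col == "Z") {
    k <- 0
  } else {
    n <- as.integer(col)
    k <- ceiling(n / 2) * ifelse(n %% 2 == 1L, -1, 1)  # odd left, even right
  }
  w <- k * 18 * pi / 180
  # rotate vertex (0,0,1) by u about the left-right axis, then by w laterally
  c(cos(u) * sin(w), sin(u), cos(u) * cos(w))
}

#' Normalize channel-name dialects to standard 10-10 form
#'
#' Upper-cases the row letters and lower-cases the terminal `z`
#' (`OZ` -> `Oz`, `po9` -> `PO9`, `fp1` -> `Fp1`), leaving EOG labels
#' upper-case.
#'
#' @param labels character vector.
#' @return normalized character vector.
#' @export
normalize_channel_labels <- function(labels) {
  out <- vapply(labels, function(l) {
    if (grepl("EOG", l, ignore.case = TRUE)) return(toupper(l))
    l <- toupper(l)
    l <- sub("Z$", "z", l)
    if (grepl("^FP", l)) l <- sub("^FP", "Fp", l)
    l
  }, character(1))
  unname(out)
}

#' Occipito-temporal region-of-interest clusters
#'
#' The three electrode clusters used for response quantification:
#' left occipito-temporal (PO3, PO7, P7, PO9), right occipito-temporal
#' (PO4, PO8, P8, PO10) and medial occipital (O1, O2, Oz).
#'
#' @return named list of character vectors with class `roi_set`.
#' @export
roi_set <- function() {
  structure(list(
    left = c("PO3", "PO7", "P7", "PO9"),
    right = c("PO4", "PO8", "P8", "PO10"),
    medial = c("O1", "O2", "Oz")
  ), class = "roi_set")
}
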