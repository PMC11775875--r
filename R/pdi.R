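#' Physical dissimilarity index between two stimulus images
#'
#' Quantifies the low-level pixel difference between a neutral face and a
#' morph so that neural responses can be normalized for physical stimulus
#' change. The operative definition is the root-mean-square pixel
#' difference inside the face mask, divided by 255, giving a unitless
#' value in `[0, 1]` (identical images give 0, images differing by the
#' full 8-bit range everywhere in the mask give 1).
#' `method = "mad"` uses the mean absolute difference instead.
#'
#' @param neutral_img,morph_img integer matrices (0-255), same size.
#' @param mask logical matrix (TRUE = inside the face oval); NULL uses
#'   the full frame.
#' @param method `"rms"` (default) or `"mad"`.
#' @return scalar PDI in `[0, 1]`.
#' @export
compute_pdi <- function(neutral_img, morph_img, mask = NULL,
                        method = c("rms", "mad")) {
  method <- match.arg(method)
  if (!identical(dim(neutral_img), dim(morph_img)))
    stop("image dimensions differ")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(neutral_img), ncol(neutral_img))
  if (!identical(dim(mask), dim(neutral_img)))
    stop("mask dimensions differ from images")
  d <- (as.numeric(neutral_img) - as.numeric(morph_img))[as.logical(mask)]
  if (method == "rms") sqrt(mean(d^2)) / 255 else mean(abs(d)) / 255
}

#' PDI table for a morph image set
#'
#' @param images output of [generate_morph_images()], or a list with
#'   `neutral`, `morphs`, `mask`.
#' @param emotion label attached to the rows.
#' @param method passed to [compute_pdi()].
#' @return data.frame `emotion`, `intensity`, `pdi`.
#' @export
pdi_table <- function(images, emotion = "happy", method = "rms") {
  data.frame(
    emotion = emotion,
    intensity = as.numeric(names(images$morphs)),
    pdi = vapply(images$morphs, function(m)
      compute_pdi(images$neutral, m, images$mask, method), numeric(1)),
    row.names = NULL)
}

#' Normalize baseline-corrected amplitudes by physical dissimilarity
#'
#' Divides each BCA value by the PDI of the (emotion, intensity) cell it
#' came from, removing the physical stimulus-change gradient from the
#' neural intensity profile.
#'
#' @param bca_table data.frame with columns `emotion`, `intensity`,
#'   `value` (and any others, carried through).
#' @param pdi_tab data.frame with `emotion`, `intensity`, `pdi` (> 0).
#' @return `bca_table` with `value` replaced by `value / pdi` and a
#'   `pdi` column appended.
#' @export
pdi_normalize <- function(bca_table, pdi_tab) {
  key <- paste(bca_table$emotion, bca_table$intensity)
  pkey <- paste(pdi_tab$emotion, pdi_tab$intensity)
  idx <- match(key, pkey)
  if (anyNA(idx))
    stop("missing PDI for cells: ",
         paste(unique(key[is.na(idx)]), collapse = ", "))
  p <- pdi_tab$pdi[idx]
  if (any(p <= 0)) stop("PDI must be > 0 for normalization")
  out <- bca_table
  out$value <- bca_table$value / p
  out$pdi <- p
  out
}
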