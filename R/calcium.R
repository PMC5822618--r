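#' Non-contrast CT volume
#'
#' @param voxels_hu 3D array of Hounsfield units (x, y, slice); a matrix is
#'   treated as a single slice.
#' @param pixel_spacing_mm Length-2 in-plane spacing, mm.
#' @param slice_thickness_mm Reconstructed slice thickness, mm (the classic
#'   scoring protocol uses 3 mm).
#' @return An object of class `ct_volume`.
#' @export
ct_volume <- function(voxels_hu, pixel_spacing_mm, slice_thickness_mm = 3) {
  if (is.matrix(voxels_hu)) dim(voxels_hu) <- c(dim(voxels_hu), 1L)
  if (length(dim(voxels_hu)) != 3) stop("voxels_hu must be a 3D array")
  if (length(pixel_spacing_mm) == 1) {
    pixel_spacing_mm <- rep(pixel_spacing_mm, 2)
  }
  if (any(pixel_spacing_mm <= 0) || slice_thickness_mm <= 0) {
    stop("pixel spacing and slice thickness must be > 0")
  }
  structure(list(voxels_hu = voxels_hu,
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 slice_thickness_mm = slice_thickness_mm),
            class = "ct_volume")
}

#' Agatston coronary calcium score
#'
#' Classic per-slice scoring: voxels >= 130 HU are grouped into 4-connected
#' in-plane components (no 3D merging); components smaller than
#' `min_area_mm2` are dropped; each remaining lesion scores
#' area (mm^2) x weight, with the weight set by the lesion's peak HU
#' (130-199: 1, 200-299: 2, 300-399: 3, >= 400: 4). The total is the sum
#' over all slices. Deterministic.
#'
#' @param vol A `ct_volume`.
#' @param min_area_mm2 Minimum lesion area retained, mm^2.
#' @param hu_threshold Attenuation threshold, HU.
#' @return A list: `total` (Agatston units) and `lesions` (data.frame:
#'   `slice`, `area_mm2`, `peak_hu`, `weight`, `score`).
#' @export
agatston_score <- function(vol, min_area_mm2 = 1.0, hu_threshold = 130) {
  stopifnot(inherits(vol, "ct_volume"))
  px_area <- prod(vol$pixel_spacing_mm)
  lesions <- list()
  for (s in seq_len(dim(vol$voxels_hu)[3])) {
    sl <- vol$voxels_hu[, , s]
    bin <- sl >= hu_threshold
    if (!any(bin)) next
    lab <- label_components4(bin)
    for (comp in seq_len(max(lab))) {
      in_comp <- lab == comp
      area <- sum(in_comp) * px_area
      if (area < min_area_mm2) next
      peak <- max(sl[in_comp])
      weight <- agatston_weight(peak)
      lesions[[length(lesions) + 1L]] <-
        data.frame(slice = s, area_mm2 = area, peak_hu = peak,
                   weight = weight, score = area * weight)
    }
  }
  if (!length(lesions)) {
    return(list(total = 0,
                lesions = data.frame(slice = integer(), area_mm2 = numeric(),
                                     peak_hu = numeric(), weight = integer(),
                                     score = numeric())))
  }
  df <- do.call(rbind, lesions)
  list(total = sum(df$score), lesions = df)
}

agatston_weight <- function(peak_hu) {
  if (peak_hu >= 400) 4L
  else if (peak_hu >= 300) 3L
  else if (peak_hu >= 200) 2L
  else 1L
}

# 4-connected component labeling of a logical matrix (iterative flood fill)
label_components4 <- function(bin) {
  nr <- nrow(bin); nc <- ncol(bin)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(bin)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      idx <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- ((idx - 1L) %% nr) + 1L
      j <- ((idx - 1L) %/% nr) + 1L
      for (nb in c(if (i > 1L) idx - 1L, if (i < nr) idx + 1L,
                   if (j > 1L) idx - nr, if (j < nc) idx + nr)) {
        if (bin[nb] && lab[nb] == 0L) {
          lab[nb] <- cur
          stack <- c(stack, nb)
        }
      }
    }
  }
  lab
}

#' Stratify a cohort by coronary calcium score
#'
#' Labels subjects at or below the threshold `"low"` and above it `"high"`.
#' With no threshold given, the median of the non-missing scores is used
#' (the study design splits at the cohort median).
#'
#' @param table Data frame with a `cac` column; rows with missing `cac`
#'   get `NA` labels.
#' @param threshold Agatston threshold; `NULL` for the median split.
#' @return Factor of labels `c("low", "high")`, one per row.
#' @export
cac_stratify <- function(table, threshold = NULL) {
  if (!"cac" %in% names(table)) stop("table has no 'cac' column")
  cac <- table$cac
  if (all(is.na(cac))) stop("all CAC scores are missing")
  if (is.null(threshold)) threshold <- stats::median(cac, na.rm = TRUE)
  factor(ifelse(is.na(cac), NA, ifelse(cac <= threshold, "low", "high")),
         levels = c("low", "high"))
}
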