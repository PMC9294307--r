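#' Idealized 62-channel 10-10 electrode montage on a sphere
#'
#' Builds scalp electrode positions for the 62 cephalic channels used by the
#' recording protocol (extended 10-20 labels) plus a right-earlobe reference
#' site. Positions are constructed geometrically on the scalp sphere: the
#' outer circumferential ring sits 18 degrees above the ear plane, midline
#' electrodes step in 18-degree increments from the vertex, and intermediate
#' electrodes are placed by spherical interpolation along the arc joining the
#' midline anchor of their row to its temporal end point.
#'
#' @param scalp_radius Scalp sphere radius in mm (default 92, matching
#'   [build_head_model()]).
#' @param center Sphere center in MNI mm coordinates (RAS axis order).
#' @return A `data.frame` with columns `label`, `x`, `y`, `z` (MNI mm) and 62
#'   rows, with the reference electrode position attached as attribute
#'   `"reference"` (named vector) and `"reference_label"` (`"A2"`).
#' @export
ten_ten_montage <- function(scalp_radius = 92, center = c(0, -15, 5)) {
  deg <- pi / 180
  # unit vector from inclination theta (from vertex) and azimuth phi
  # (from anterior midline, positive toward the right ear); RAS axes
  unit_vec <- function(theta, phi) {
    c(sin(theta * deg) * sin(phi * deg),
      sin(theta * deg) * cos(phi * deg),
      cos(theta * deg))
  }
  slerp <- function(a, b, t) {
    om <- acos(max(-1, min(1, sum(a * b))))
    if (om < 1e-9) return(a)
    (sin((1 - t) * om) * a + sin(t * om) * b) / sin(om)
  }

  pos <- list()
  # perimeter ring (theta = 72), 18-degree azimuth steps
  perim <- list(
    Fpz = 0, Fp2 = 18, AF8 = 36, F8 = 54, FT8 = 72, T8 = 90,
    TP8 = 108, P8 = 126, PO8 = 144, O2 = 162, Oz = 180,
    O1 = -162, PO7 = -144, P7 = -126, TP7 = -108, T7 = -90,
    FT7 = -72, F7 = -54, AF7 = -36, Fp1 = -18
  )
  for (lab in names(perim)) pos[[lab]] <- unit_vec(72, perim[[lab]])

  # midline (anterior azimuth 0, posterior 180)
  midline <- list(Fz = c(36, 0), FCz = c(18, 0), Cz = c(0, 0),
                  CPz = c(18, 180), Pz = c(36, 180), POz = c(54, 180))
  for (lab in names(midline))
    pos[[lab]] <- unit_vec(midline[[lab]][1], midline[[lab]][2])

  # interior rows: slerp from midline anchor toward the temporal end point
  rows <- list(
    list(anchor = unit_vec(54, 0), ends = c("AF7", "AF8"),
         names = list(c("AF3"), c("AF4")), fracs = 0.5),
    list(anchor = pos$Fz, ends = c("F7", "F8"),
         names = list(c("F1", "F3", "F5"), c("F2", "F4", "F6")),
         fracs = c(0.25, 0.5, 0.75)),
    list(anchor = pos$FCz, ends = c("FT7", "FT8"),
         names = list(c("FC1", "FC3", "FC5"), c("FC2", "FC4", "FC6")),
         fracs = c(0.25, 0.5, 0.75)),
    list(anchor = pos$Cz, ends = c("T7", "T8"),
         names = list(c("C1", "C3", "C5"), c("C2", "C4", "C6")),
         fracs = c(0.25, 0.5, 0.75)),
    list(anchor = pos$CPz, ends = c("TP7", "TP8"),
         names = list(c("CP1", "CP3", "CP5"), c("CP2", "CP4", "CP6")),
         fracs = c(0.25, 0.5, 0.75)),
    list(anchor = pos$Pz, ends = c("P7", "P8"),
         names = list(c("P1", "P3", "P5"), c("P2", "P4", "P6")),
         fracs = c(0.25, 0.5, 0.75)),
    list(anchor = pos$POz, ends = c("PO7", "PO8"),
         names = list(c("PO3", "PO5"), c("PO4", "PO6")),
         fracs = c(1 / 3, 2 / 3))
  )
  for (row in rows) {
    for (side in 1:2) {
      endv <- pos[[row$ends[side]]]
      for (j in seq_along(row$fracs)) {
        pos[[row$names[[side]][j]]] <- slerp(row$anchor, endv, row$fracs[j])
      }
    }
  }

  labels <- names(pos)
  stopifnot(length(labels) == 62L)
  mat <- do.call(rbind, pos)
  mat <- mat / sqrt(rowSums(mat^2))
  xyz <- sweep(mat * scalp_radius, 2, center, "+")
  out <- data.frame(label = labels, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  ref_unit <- unit_vec(105, 95)
  ref <- ref_unit / sqrt(sum(ref_unit^2)) * scalp_radius + center
  names(ref) <- c("x", "y", "z")
  attr(out, "reference") <- ref
  attr(out, "reference_label") <- "A2"
  attr(out, "center") <- center
  attr(out, "scalp_radius") <- scalp_radius
  out
}

#' Extract the channel position matrix from a montage
#' @param montage A montage from [ten_ten_montage()].
#' @return Numeric matrix (channels x 3) with channel labels as row names.
#' @export
montage_positions <- function(montage) {
  m <- as.matrix(montage[, c("x", "y", "z")])
  rownames(m) <- montage$label
  m
}
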