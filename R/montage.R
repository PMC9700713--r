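#' Standard 32-channel modified 10-20 montage
#'
#' Returns the channel layout of a 32-electrode cap positioned according to a
#' modified International 10-20 system (Fp1 ... PO10), plus a vertical EOG
#' channel used for blink detection. Two-dimensional positions (mm) are an
#' azimuthal-equidistant projection of the standard 10-20 spherical angles
#' onto the plane, with the equatorial ring (Fp1/2, F7/8, T7/8, P7/8, O1/2)
#' at a 90 mm radius; the exact cap geometry of any particular system is not
#' claimed, only a standard projection suitable for scalp-map interpolation.
#'
#' @param head_radius radius (mm) assigned to the 90-degree inclination ring.
#' @return A data.frame with columns `name`, `x` (mm, left negative),
#'   `y` (mm, anterior positive), and `role` (`"scalp"` or `"eog"`).
#' @examples
#' m <- montage_1020()
#' sum(m$role == "scalp")  # 32
#' @export
montage_1020 <- function(head_radius = 90) {
  # (name, inclination degrees from vertex, azimuth degrees clockwise from
  # anterior midline; negative = left hemisphere)
  tab <- rbind(
    c("Fp1", 72, -18), c("Fp2", 72, 18),
    c("F7", 72, -54), c("F3", 44, -29), c("Fz", 36, 0),
    c("F4", 44, 29), c("F8", 72, 54),
    c("FC5", 58, -63), c("FC1", 22, -34), c("FC2", 22, 34), c("FC6", 58, 63),
    c("T7", 72, -90), c("C3", 36, -90), c("Cz", 0, 0), c("C4", 36, 90),
    c("T8", 72, 90),
    c("TP9", 90, -108), c("CP5", 58, -117), c("CP1", 22, -146),
    c("CP2", 22, 146), c("CP6", 58, 117), c("TP10", 90, 108),
    c("P7", 72, -126), c("P3", 44, -151), c("Pz", 36, 180),
    c("P4", 44, 151), c("P8", 72, 126),
    c("PO9", 90, -144), c("O1", 72, -162), c("Oz", 72, 180),
    c("O2", 72, 162), c("PO10", 90, 144)
  )
  incl <- as.numeric(tab[, 2])
  az <- as.numeric(tab[, 3]) * pi / 180
  r <- head_radius * incl / 90
  out <- data.frame(
    name = tab[, 1],
    x = r * sin(az),
    y = r * cos(az),
    role = "scalp",
    stringsAsFactors = FALSE
  )
  # vertical EOG below the right supraorbital ridge; excluded from scalp maps
  out <- rbind(out, data.frame(name = "vEOG", x = 25, y = 105, role = "eog"))
  stopifnot(!anyDuplicated(out$name))
  out
}

#' Names of the scalp channels in a montage
#' @param montage a montage data.frame as returned by [montage_1020()].
#' @return character vector of scalp channel names.
#' @export
scalp_channels <- function(montage) montage$name[montage$role == "scalp"]
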