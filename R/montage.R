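#' Electrode montages for motor-hotspot localization
#'
#' Builds the two montages used by the package: `"healthy63"`, a 63-channel
#' 10-10 layout (Fpz and FCz are the ground and reference electrodes and are
#' therefore not data channels), and `"stroke29"`, a 29-channel 10-20 layout.
#' Electrode positions are computed on a spherical head model of radius
#' `head_radius` mm whose coordinate frame has its origin at the vertex
#' electrode Cz, +x toward the right preauricular point, +y toward the
#' nasion, and +z up. Electrodes lie on the sphere (centered `head_radius`
#' below Cz), so distances from Cz reach `sqrt(2) * head_radius` at ear
#' level.
#'
#' Positions follow the classical arc construction of the 10-20 system:
#' midline electrodes sit at 18 degree steps along the nasion-inion arc, the
#' outer ring (Fp1/2, F7/8, T7/8, P7/8, O1/2, ...) at 72 degrees inclination
#' in 18 degree azimuthal steps, and intermediate electrodes subdivide the
#' great-circle arc from the midline electrode of their row to the ring
#' electrode of that row into quarters.
#'
#' @param name `"healthy63"` or `"stroke29"`.
#' @param head_radius Scalp sphere radius in mm.
#' @return An object of class `electrode_montage`: a list with `name`,
#'   `labels`, `positions` (labels x 3 matrix, mm, Cz origin) and
#'   `head_radius`.
#' @examples
#' m <- load_montage("healthy63")
#' m$positions["C3", ]
#' @export
load_montage <- function(name = c("healthy63", "stroke29"), head_radius = 90) {
  name <- match.arg(name)
  labels <- montage_labels(name)
  pos <- t(vapply(labels, electrode_position, numeric(3)))
  pos <- pos * head_radius
  # shift so Cz (sphere top) is the origin
  pos[, 3] <- pos[, 3] - head_radius
  dimnames(pos) <- list(labels, c("x", "y", "z"))
  m <- structure(
    list(name = name, labels = labels, positions = pos,
         head_radius = head_radius),
    class = "electrode_montage"
  )
  validate_montage(m)
  m
}

montage_labels <- function(name) {
  if (name == "healthy63") {
    c(
      "Fp1", "Fp2",
      "AF7", "AF3", "AFz", "AF4", "AF8",
      "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
      "FT9", "FT7", "FC5", "FC3", "FC1", "FC2", "FC4", "FC6", "FT8", "FT10",
      "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
      "TP9", "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8", "TP10",
      "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
      "PO7", "PO3", "POz", "PO4", "PO8",
      "O1", "Oz", "O2"
    )
  } else {
    c(
      "Fp1", "Fp2",
      "F7", "F3", "Fz", "F4", "F8",
      "FC5", "FC1", "FC2", "FC6",
      "T7", "C3", "Cz", "C4", "T8",
      "CP5", "CP1", "CP2", "CP6",
      "P7", "P3", "Pz", "P4", "P8",
      "POz",
      "O1", "Oz", "O2"
    )
  }
}

# Unit-sphere direction of a 10-10 label. x right, y nasion, z up.
electrode_position <- function(label) {
  u <- function(incl, azim) {
    # incl: degrees from vertex; azim: degrees from +y (nasion), positive
    # toward the right ear
    ti <- incl * pi / 180
    ta <- azim * pi / 180
    c(sin(ti) * sin(ta), sin(ti) * cos(ta), cos(ti))
  }
  slerp <- function(a, b, f) {
    w <- acos(max(-1, min(1, sum(a * b))))
    if (w < 1e-12) return(a)
    (sin((1 - f) * w) * a + sin(f * w) * b) / sin(w)
  }
  midline <- c(Fpz = 72, AFz = 54, Fz = 36, FCz = 18, Cz = 0,
               CPz = -18, Pz = -36, POz = -54, Oz = -72)
  # outer ring, inclination 72, azimuth from front in 18 degree steps
  ring <- c(Fpz = 0, Fp2 = 18, AF8 = 36, F8 = 54, FT8 = 72, T8 = 90,
            TP8 = 108, P8 = 126, PO8 = 144, O2 = 162, Oz = 180)
  below <- c(FT10 = 72, TP10 = 108, PO10 = 144)  # inclination 90

  mirror <- function(v) c(-v[1], v[2], v[3])
  lab <- label
  # left-hemisphere labels (odd index or 7/9 endings) = mirror of right
  row_num <- regmatches(lab, regexpr("[0-9]+$", lab))
  if (length(row_num) == 1 && nchar(row_num)) {
    n <- as.integer(row_num)
    if (n %% 2 == 1) {
      right <- paste0(sub("[0-9]+$", "", lab), n + 1)
      return(mirror(electrode_position(right)))
    }
  }
  if (lab %in% names(midline)) {
    a <- midline[[lab]]
    return(u(abs(a), if (a >= 0) 0 else 180))
  }
  if (lab %in% names(ring)) return(u(72, ring[[lab]]))
  if (lab %in% names(below)) return(u(90, below[[lab]]))
  # intermediate right-hemisphere electrode: quarter-arc subdivision from the
  # midline electrode of the row to its ring electrode
  row <- sub("[0-9]+$", "", lab)
  idx <- as.integer(regmatches(lab, regexpr("[0-9]+$", lab)))
  ring_of_row <- c(AF = "AF8", F = "F8", FC = "FT8", C = "T8",
                   CP = "TP8", P = "P8", PO = "PO8")
  mid_of_row <- c(AF = "AFz", F = "Fz", FC = "FCz", C = "Cz",
                  CP = "CPz", P = "Pz", PO = "POz")
  if (!row %in% names(ring_of_row))
    stop("unknown electrode label: ", lab)
  frac <- switch(as.character(idx),
                 "2" = 1 / 4, "4" = 2 / 4, "6" = 3 / 4,
                 stop("unknown electrode label: ", lab))
  # AF4 / PO4 are the only intermediate electrodes of their rows; they sit at
  # the half-arc position like F4/P4
  if (row %in% c("AF", "PO") && idx == 4) frac <- 2 / 4
  slerp(electrode_position(mid_of_row[[row]]),
        electrode_position(ring_of_row[[row]]), frac)
}

validate_montage <- function(m) {
  stopifnot(!anyDuplicated(m$labels), nrow(m$positions) == length(m$labels))
  if ("Cz" %in% m$labels)
    stopifnot(max(abs(m$positions["Cz", ])) < 1e-9)
  # electrodes lie on the scalp sphere; the farthest (ear-level) are
  # sqrt(2) * R from the Cz origin
  r <- sqrt(rowSums(m$positions^2))
  if (any(r > 1.05 * sqrt(2) * m$head_radius))
    stop("electrode positions outside the head model")
  if (any(c("Fpz", "FCz") %in% m$labels))
    stop("Fpz and FCz are ground/reference electrodes, not data channels")
  invisible(m)
}

#' @export
print.electrode_montage <- function(x, ...) {
  cat("<electrode_montage> ", x$name, ": ", length(x$labels),
      " channels, head radius ", x$head_radius, " mm (Cz origin)\n", sep = "")
  invisible(x)
}

# ---- channel sets -----------------------------------------------------------

# Default channel-set memberships. The full sets (Set1) are the montages; the
# reduced sets shrink toward the hand motor area (C3 for the right hand, C4
# for the left hand). Lateralized sets are given for the right hand and
# mirrored for the left.
channel_set_table <- function(montage_name) {
  if (montage_name == "healthy63") {
    list(
      Set1 = list(hand_specific = FALSE, labels = NULL),  # full montage
      Set2 = list(hand_specific = FALSE, labels = c(
        "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
        "FT7", "FC5", "FC3", "FC1", "FC2", "FC4", "FC6", "FT8",
        "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
        "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
        "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8")),
      Set3 = list(hand_specific = FALSE, labels = c(
        "FT7", "FC5", "FC3", "FC1", "FC2", "FC4", "FC6", "FT8",
        "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
        "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8")),
      Set4 = list(hand_specific = TRUE, labels = c(
        "FT7", "FC5", "FC3", "FC1",
        "T7", "C5", "C3", "C1", "Cz",
        "TP7", "CP5", "CP3", "CP1", "CPz")),
      Set5 = list(hand_specific = TRUE, labels = c(
        "FC5", "FC3", "FC1", "C5", "C3", "C1", "CP5", "CP3", "CP1"))
    )
  } else {
    list(
      Set1 = list(hand_specific = FALSE, labels = NULL),
      Set2 = list(hand_specific = TRUE, labels = c(
        "F3", "FC5", "FC1", "T7", "C3", "Cz", "CP5", "CP1", "P3")),
      Set3 = list(hand_specific = TRUE, labels = c(
        "FC5", "FC1", "C3", "CP5", "CP1"))
    )
  }
}

mirror_label <- function(label) {
  n <- suppressWarnings(as.integer(regmatches(label, regexpr("[0-9]+$", label))))
  if (length(n) == 0 || is.na(n)) return(label)  # midline
  base <- sub("[0-9]+$", "", label)
  paste0(base, if (n %% 2 == 1) n + 1 else n - 1)
}

#' Select one of the configured channel sets
#'
#' Channel sets nest from the full montage (`Set1`) down to a compact set
#' over the hand motor area (9 channels for the healthy montage, 5 for the
#' stroke montage). The smallest sets are centered on C3 for right-hand data
#' and on C4 (mirrored membership) for left-hand data. Memberships can be
#' overridden with `override`.
#'
#' @param montage An `electrode_montage`.
#' @param set_id `"Set1"` .. `"Set5"` (healthy) or `"Set1"` .. `"Set3"`
#'   (stroke).
#' @param hand `"left"`, `"right"`, or `"both"`. Hand-specific sets require
#'   a definite hand.
#' @param override Optional named list mapping set ids to character vectors
#'   of labels (right-hand convention; mirrored automatically for the left
#'   hand).
#' @return An object of class `channel_set` with `set_id`, `labels` (in
#'   montage order) and `hand`.
#' @examples
#' m <- load_montage("healthy63")
#' select_channel_set(m, "Set5", "right")$labels
#' @export
select_channel_set <- function(montage, set_id, hand = c("both", "left", "right"),
                               override = NULL) {
  stopifnot(inherits(montage, "electrode_montage"))
  hand <- match.arg(hand)
  tab <- channel_set_table(montage$name)
  if (!is.null(override)) tab[names(override)] <-
      lapply(override, function(l) list(hand_specific = TRUE, labels = l))
  if (!set_id %in% names(tab))
    stop("unknown channel set '", set_id, "' for montage '", montage$name,
         "'; valid sets: ", paste(names(tab), collapse = ", "))
  entry <- tab[[set_id]]
  labels <- if (is.null(entry$labels)) montage$labels else entry$labels
  if (entry$hand_specific) {
    if (hand == "both")
      stop("channel set ", set_id, " is hand-specific; choose hand 'left' or 'right'")
    if (hand == "left") labels <- vapply(labels, mirror_label, character(1))
  }
  missing <- setdiff(labels, montage$labels)
  if (length(missing))
    stop("channel set labels not in montage: ", paste(missing, collapse = ", "))
  labels <- montage$labels[montage$labels %in% labels]  # montage order
  structure(list(set_id = set_id, labels = labels, hand = hand),
            class = "channel_set")
}

#' @export
print.channel_set <- function(x, ...) {
  cat("<channel_set> ", x$set_id, " (", x$hand, "): ",
      paste(x$labels, collapse = " "), "\n", sep = "")
  invisible(x)
}
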