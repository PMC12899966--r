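#' The 52 ARKit blend shape names
#'
#' Canonical, ordered registry of the 52 blend shape coefficients streamed by
#' ARKit's face tracking (`ARFaceAnchor.blendShapes`). The order follows the
#' ARKit documentation grouping: left eye, right eye, mouth and jaw, brows /
#' cheeks / nose, tongue. All package data structures (frame matrices,
#' prototype vectors, CSV columns) use this order.
#'
#' @return Character vector of length 52.
#' @export
#' @examples
#' length(arkit_blendshapes())
#' head(arkit_blendshapes())
arkit_blendshapes <- function() {
  c(
    # left eye
    "eyeBlinkLeft", "eyeLookDownLeft", "eyeLookInLeft", "eyeLookOutLeft",
    "eyeLookUpLeft", "eyeSquintLeft", "eyeWideLeft",
    # right eye
    "eyeBlinkRight", "eyeLookDownRight", "eyeLookInRight", "eyeLookOutRight",
    "eyeLookUpRight", "eyeSquintRight", "eyeWideRight",
    # mouth and jaw
    "jawForward", "jawLeft", "jawRight", "jawOpen",
    "mouthClose", "mouthFunnel", "mouthPucker", "mouthLeft", "mouthRight",
    "mouthSmileLeft", "mouthSmileRight", "mouthFrownLeft", "mouthFrownRight",
    "mouthDimpleLeft", "mouthDimpleRight", "mouthStretchLeft",
    "mouthStretchRight", "mouthRollLower", "mouthRollUpper",
    "mouthShrugLower", "mouthShrugUpper", "mouthPressLeft", "mouthPressRight",
    "mouthLowerDownLeft", "mouthLowerDownRight", "mouthUpperUpLeft",
    "mouthUpperUpRight",
    # brows, cheeks, nose
    "browDownLeft", "browDownRight", "browInnerUp",
    "browOuterUpLeft", "browOuterUpRight",
    "cheekPuff", "cheekSquintLeft", "cheekSquintRight",
    "noseSneerLeft", "noseSneerRight",
    # tongue
    "tongueOut"
  )
}

#' Facial region of each blend shape
#'
#' Assigns each blend shape to one of seven facial regions (jaw, eye, mouth,
#' cheek, brow, nose, tongue) by its name prefix, e.g. `jawOpen` -> `jaw`,
#' `browInnerUp` -> `brow`. The seven regions partition the 52 names.
#'
#' @param names Blend shape names; defaults to the full registry.
#' @return Named character vector mapping each blend shape to its region.
#' @export
#' @examples
#' table(blendshape_regions())
blendshape_regions <- function(names = arkit_blendshapes()) {
  stopifnot(all(names %in% arkit_blendshapes()))
  prefixes <- c(
    jaw = "^jaw", eye = "^eye", mouth = "^mouth", cheek = "^cheek",
    brow = "^brow", nose = "^nose", tongue = "^tongue"
  )
  region <- rep(NA_character_, length(names))
  for (r in names(prefixes)) {
    region[grepl(prefixes[[r]], names)] <- r
  }
  stats::setNames(region, names)
}

#' The seven emotion labels in canonical order
#'
#' Canonical alphabetical order of the seven basic emotions used throughout
#' the package, including as the deterministic tie-break order in
#' classification.
#'
#' @return Character vector of length 7.
#' @export
emotions <- function() {
  c("anger", "contempt", "disgust", "fear", "joy", "sadness", "surprise")
}


# Mirror pairs a participant can perform on both sides at once. Inward/outward
# gaze (eyeLookIn*/eyeLookOut*) cannot be produced symmetrically and the
# remaining Left/Right names (jawLeft, mouthRight, ...) are directional
# movements, not mirror pairs, so all of those stay single movements:
# 16 collapsed pairs + 20 singles = 36 movements covering all 52 shapes.
.symmetric_movement_bases <- c(
  "eyeBlink", "eyeLookDown", "eyeLookUp", "eyeSquint", "eyeWide",
  "mouthSmile", "mouthFrown", "mouthDimple", "mouthStretch", "mouthPress",
  "mouthLowerDown", "mouthUpperUp", "browDown", "browOuterUp",
  "cheekSquint", "noseSneer"
)

#' The 36 blend-shape-targeting movement labels
#'
#' Symmetric left/right blend shapes are elicited together as a single
#' movement (e.g. `browDown` covers `browDownLeft` and `browDownRight`);
#' shapes without a performable mirror twin (directional jaw/mouth/gaze
#' shapes, midline shapes) are one movement each. The 52 coefficients thus
#' collapse to 36 movement recordings per subject.
#'
#' @return Character vector of 36 movement names, in registry order.
#' @export
movement_labels <- function() {
  nm <- arkit_blendshapes()
  base <- sub("(Left|Right)$", "", nm)
  lab <- ifelse(base %in% .symmetric_movement_bases, base, nm)
  unique(lab)
}

#' Blend shapes driven by a movement label
#'
#' @param movement One movement label from [movement_labels()].
#' @return Character vector of one or two registry names (the symmetric pair).
#' @export
movement_blendshapes <- function(movement) {
  if (!movement %in% movement_labels()) {
    stop("unknown movement label: ", movement, call. = FALSE)
  }
  if (movement %in% .symmetric_movement_bases) {
    return(paste0(movement, c("Left", "Right")))
  }
  movement
}
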