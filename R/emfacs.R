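# Default EMFACS-guided emotion -> blend shape mapping. Each entry pairs a
# blend shape with the FACS action unit (AU) it approximates; AU codes are
# metadata only (classification uses set membership). Contempt is unilateral:
# only one side of the face is active, encoded as two disjoint variants.
.default_emfacs <- function() {
  m <- list(
    anger = c(
      browDownLeft = 4, browDownRight = 4,
      eyeSquintLeft = 7, eyeSquintRight = 7,
      eyeWideLeft = 5, eyeWideRight = 5,
      mouthPucker = 23
    ),
    contempt = c(
      mouthDimpleLeft = 14, mouthDimpleRight = 14,
      mouthSmileLeft = 12, mouthSmileRight = 12
    ),
    disgust = c(
      browDownLeft = 4, browDownRight = 4,
      mouthFrownLeft = 15, mouthFrownRight = 15,
      mouthLowerDownLeft = 16, mouthLowerDownRight = 16,
      noseSneerLeft = 9, noseSneerRight = 9
    ),
    fear = c(
      browDownLeft = 4, browDownRight = 4, browInnerUp = 1,
      browOuterUpLeft = 2, browOuterUpRight = 2,
      eyeSquintLeft = 7, eyeSquintRight = 7,
      eyeWideLeft = 5, eyeWideRight = 5,
      jawOpen = 26,
      mouthStretchLeft = 20, mouthStretchRight = 20
    ),
    joy = c(
      cheekSquintLeft = 6, cheekSquintRight = 6,
      mouthSmileLeft = 12, mouthSmileRight = 12
    ),
    sadness = c(
      browDownLeft = 4, browDownRight = 4, browInnerUp = 1,
      mouthFrownLeft = 15, mouthFrownRight = 15
    ),
    surprise = c(
      browInnerUp = 1, browOuterUpLeft = 2, browOuterUpRight = 2,
      eyeWideLeft = 5, eyeWideRight = 5, jawOpen = 26
    )
  )
  m
}

#' The EMFACS emotion-to-blend-shape table
#'
#' Returns the mapping from each of the seven basic emotions to the blend
#' shapes whose underlying FACS action units define that emotion under
#' EMFACS, together with contempt's two unilateral variants (left:
#' mouthDimpleLeft + mouthSmileLeft; right: the mirror pair). The default
#' table can be replaced by a user mapping via [load_mapping()].
#'
#' @param mapping Optional named list `emotion -> character vector of blend
#'   shape names` overriding the default sets (AU codes are dropped for
#'   overridden emotions).
#' @return An object of class `emfacs_table`: a list with elements `mapping`
#'   (emotion -> named numeric vector, names = blend shapes, values = AU
#'   codes, `NA` where unknown) and `contempt_variants` (list `left`/`right`).
#' @export
#' @examples
#' tab <- emfacs_table()
#' names(tab$mapping)
#' relevant_blendshapes("joy", table = tab)
emfacs_table <- function(mapping = NULL) {
  tab <- .default_emfacs()
  if (!is.null(mapping)) {
    reg <- arkit_blendshapes()
    for (emo in names(mapping)) {
      if (!emo %in% emotions()) {
        stop("unknown emotion in mapping: ", emo, call. = FALSE)
      }
      nm <- mapping[[emo]]
      if (length(nm) == 0) {
        stop("empty blend shape set for emotion: ", emo, call. = FALSE)
      }
      bad <- setdiff(nm, reg)
      if (length(bad)) {
        stop("unknown blend shape in mapping: ", bad[1], call. = FALSE)
      }
      au <- .default_emfacs()[[emo]]
      tab[[emo]] <- stats::setNames(
        ifelse(nm %in% names(au), au[nm], NA_real_), nm)
    }
  }
  structure(
    list(
      mapping = tab,
      contempt_variants = list(
        left = c("mouthDimpleLeft", "mouthSmileLeft"),
        right = c("mouthDimpleRight", "mouthSmileRight")
      )
    ),
    class = "emfacs_table"
  )
}

#' Blend shapes relevant to an emotion
#'
#' @param emotion One of the seven emotions.
#' @param contempt_variant For contempt only: `"left"` or `"right"`, selecting
#'   the active side of the unilateral expression.
#' @param table An [emfacs_table()].
#' @return Character vector of blend shape names (sorted).
#' @export
#' @examples
#' relevant_blendshapes("fear")
#' relevant_blendshapes("contempt", "left")
relevant_blendshapes <- function(emotion, contempt_variant = NULL,
                                 table = emfacs_table()) {
  if (!emotion %in% names(table$mapping)) {
    stop("unknown emotion: ", emotion, call. = FALSE)
  }
  if (identical(emotion, "contempt")) {
    if (is.null(contempt_variant)) {
      stop("contempt requires contempt_variant = 'left' or 'right'",
           call. = FALSE)
    }
    if (!contempt_variant %in% c("left", "right")) {
      stop("contempt_variant must be 'left' or 'right'", call. = FALSE)
    }
    return(sort(table$contempt_variants[[contempt_variant]]))
  }
  if (!is.null(contempt_variant)) {
    stop("contempt_variant only applies to contempt", call. = FALSE)
  }
  sort(names(table$mapping[[emotion]]))
}

#' Blend shapes not used by any emotion
#'
#' @param table An [emfacs_table()].
#' @return Character vector of registry names absent from every emotion set.
#' @export
unused_blendshapes <- function(table = emfacs_table()) {
  used <- unique(unlist(lapply(table$mapping, names), use.names = FALSE))
  setdiff(arkit_blendshapes(), used)
}

#' The 12 opposite blend shape pairs
#'
#' Pairs of blend shapes that encode mutually exclusive actions (e.g.
#' `browDownLeft` vs `browOuterUpLeft`); when one activates, its opposite is
#' expected at 0. `eyeWide`/`eyeSquint` are near- rather than strictly
#' opposite and may co-activate in practice.
#'
#' @return Data frame with columns `blendshape_1`, `blendshape_2` (12 rows).
#' @export
opposite_pairs <- function() {
  data.frame(
    blendshape_1 = c(
      "browDownLeft", "browDownRight",
      "eyeLookDownLeft", "eyeLookDownRight",
      "eyeLookInLeft", "eyeLookInRight",
      "eyeWideLeft", "eyeWideRight",
      "mouthFrownLeft", "mouthFrownRight",
      "mouthLeft", "jawLeft"
    ),
    blendshape_2 = c(
      "browOuterUpLeft", "browOuterUpRight",
      "eyeLookUpLeft", "eyeLookUpRight",
      "eyeLookOutLeft", "eyeLookOutRight",
      "eyeSquintLeft", "eyeSquintRight",
      "mouthSmileLeft", "mouthSmileRight",
      "mouthRight", "jawRight"
    )
  )
}

#' Load an emotion mapping from a config file
#'
#' Reads a YAML (or JSON) file of the form `emotion: [blendshape, ...]` and
#' returns the corresponding validated [emfacs_table()]; with no path the
#' default EMFACS table is returned. Emotions absent from the file keep their
#' default sets.
#'
#' @param path Optional path to a YAML/JSON mapping file.
#' @return An [emfacs_table()].
#' @export
load_mapping <- function(path = NULL) {
  if (is.null(path)) return(emfacs_table())
  if (!file.exists(path)) stop("mapping file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- lapply(cfg, unlist)
  emfacs_table(mapping = cfg)
}
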