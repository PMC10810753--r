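#' Five-object pop-out scene
#'
#' A scene describes the stimulus display for one trial of the face pop-out
#' task: a screen, five rectangular areas of interest (AOIs) — one face and
#' four non-face objects (noise, phone, bird, car) — and the position index at
#' which the face appears (counterbalanced across the six stimuli).
#'
#' AOI containment is half-open, `[x0, x1) x [y0, y1)`, so AOIs that share an
#' edge do not double-assign samples. AOIs must be pairwise non-overlapping
#' and lie within the screen.
#'
#' @param stimulus_id Integer stimulus identifier (1-6 in the standard task).
#' @param face_position Which of the five layout slots holds the face.
#' @param screen Screen size in pixels, `c(width, height)`.
#' @param aois Optional data frame with columns `label, x0, y0, x1, y1`
#'   overriding the default ring layout.
#' @return An object of class `gaze_scene`.
#' @examples
#' sc <- gaze_scene(1)
#' assign_aoi(mean(sc$aois$x0[1] + sc$aois$x1[1]) / 2,
#'            (sc$aois$y0[1] + sc$aois$y1[1]) / 2, sc)
#' @export
gaze_scene <- function(stimulus_id = 1L, face_position = ((stimulus_id - 1L) %% 5L) + 1L,
                       screen = c(1920L, 1080L), aois = NULL) {
  labels <- c("face", "noise", "phone", "bird", "car")
  if (is.null(aois)) {
    # five boxes on a ring around screen centre; centre itself is AOI-free so
    # the gaze-contingent trial start is outside every AOI
    ang <- (c(90, 162, 234, 306, 18)) * pi / 180
    cx <- screen[1] / 2 + 380 * cos(ang)
    cy <- screen[2] / 2 + 380 * sin(ang)
    half <- 160
    aois <- data.frame(
      label = "",
      x0 = round(cx - half), y0 = round(cy - half),
      x1 = round(cx + half), y1 = round(cy + half),
      stringsAsFactors = FALSE
    )
  }
  ord <- seq_len(nrow(aois))
  lab <- rep(NA_character_, nrow(aois))
  lab[face_position] <- "face"
  lab[setdiff(ord, face_position)] <- setdiff(labels, "face")[seq_len(nrow(aois) - 1L)]
  aois$label <- lab
  scene <- structure(
    list(stimulus_id = as.integer(stimulus_id),
         face_position = as.integer(face_position),
         screen = as.integer(screen), aois = aois),
    class = "gaze_scene"
  )
  validate_scene(scene)
  scene
}

#' @rdname gaze_scene
#' @param scene A `gaze_scene`.
#' @export
validate_scene <- function(scene) {
  a <- scene$aois
  if (any(a$x1 <= a$x0) || any(a$y1 <= a$y0))
    stop("degenerate AOI rectangle(s)")
  if (any(a$x0 < 0) || any(a$y0 < 0) ||
      any(a$x1 > scene$screen[1]) || any(a$y1 > scene$screen[2]))
    stop("AOI(s) outside the screen")
  n <- nrow(a)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    overlap_x <- a$x0[i] < a$x1[j] && a$x0[j] < a$x1[i]
    overlap_y <- a$y0[i] < a$y1[j] && a$y0[j] < a$y1[i]
    if (overlap_x && overlap_y)
      stop(sprintf("AOIs '%s' and '%s' overlap", a$label[i], a$label[j]))
  }
  invisible(scene)
}

#' Default scene set for the six-trial task
#'
#' One scene per stimulus, face position counterbalanced across slots.
#'
#' @param n_stimuli Number of distinct displays (default 6).
#' @return A list of `gaze_scene` objects indexed by stimulus id.
#' @export
default_scenes <- function(n_stimuli = 6L) {
  lapply(seq_len(n_stimuli), gaze_scene)
}

#' Map gaze coordinates to an AOI label
#'
#' Vectorised point-in-rectangle lookup with half-open containment;
#' coordinates outside every AOI (including off-screen) map to `NA`.
#'
#' @param x,y Gaze coordinates in pixels (vectors of equal length).
#' @param scene A `gaze_scene`.
#' @return Character vector of AOI labels, `NA` where no AOI contains the point.
#' @export
assign_aoi <- function(x, y, scene) {
  a <- scene$aois
  out <- rep(NA_character_, length(x))
  for (i in seq_len(nrow(a))) {
    hit <- !is.na(x) & !is.na(y) &
      x >= a$x0[i] & x < a$x1[i] & y >= a$y0[i] & y < a$y1[i]
    out[hit] <- a$label[i]
  }
  out
}

#' Chance level of first-looking at any one object
#'
#' With `m` equally available objects the chance probability that a given AOI
#' receives the first look is `1/m`; for the five-object pop-out display this
#' is 0.20.
#'
#' @param scene A `gaze_scene`.
#' @return A single probability.
#' @export
chance_level <- function(scene) 1 / nrow(scene$aois)

#' Read/write scene layouts as YAML
#'
#' The YAML layout lists screen size, stimulus id, face position and one
#' `label/x0/y0/x1/y1` block per AOI.
#'
#' @param scene A `gaze_scene`.
#' @param path File path.
#' @return `read_scene_yaml` returns a `gaze_scene`; `write_scene_yaml`
#'   returns `path` invisibly.
#' @export
write_scene_yaml <- function(scene, path) {
  obj <- list(
    stimulus_id = scene$stimulus_id,
    face_position = scene$face_position,
    screen = as.list(setNames(scene$screen, c("width", "height"))),
    aois = lapply(seq_len(nrow(scene$aois)), function(i) as.list(scene$aois[i, ]))
  )
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_scene_yaml
#' @export
read_scene_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  aois <- do.call(rbind, lapply(obj$aois, function(a)
    data.frame(label = a$label, x0 = a$x0, y0 = a$y0, x1 = a$x1, y1 = a$y1,
               stringsAsFactors = FALSE)))
  sc <- structure(
    list(stimulus_id = as.integer(obj$stimulus_id),
         face_position = as.integer(obj$face_position),
         screen = c(obj$screen$width, obj$screen$height),
         aois = aois),
    class = "gaze_scene"
  )
  validate_scene(sc)
  sc
}
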