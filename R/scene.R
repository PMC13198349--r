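# Labeled scenes and time sequences.

LANDMARK_NAMES <- c("apex", "tv_centre", "attach_anterior", "attach_posterior")

#' Construct a labeled scene
#'
#' A scene is a named list of structure meshes (categories from
#' [STRUCTURE_CATEGORIES]) plus anatomical landmarks: the apex, the tricuspid
#' annulus centre, and the anterior and posterior RV attachment points.
#'
#' @param structures named list of `triangle_mesh`, names in
#'   [STRUCTURE_CATEGORIES]; `SEPTUM` and `RV_WALL` are mandatory
#' @param landmarks named list of length-3 points (at least `apex`,
#'   `tv_centre`, `attach_anterior`, `attach_posterior`)
#' @return object of class `labeled_scene`
#' @export
labeled_scene <- function(structures, landmarks) {
  nm <- names(structures)
  if (is.null(nm) || any(nm == "")) stop("structures must be a named list")
  if (anyDuplicated(nm)) stop("duplicate structure category keys")
  unknown <- setdiff(nm, STRUCTURE_CATEGORIES)
  if (length(unknown) > 0) {
    stop("unknown structure categories: ", paste(unknown, collapse = ", "),
         " (known: ", paste(STRUCTURE_CATEGORIES, collapse = ", "), ")")
  }
  for (req in c("SEPTUM", "RV_WALL")) {
    if (!req %in% nm) stop("scene is missing mandatory category ", req)
  }
  for (k in nm) {
    if (!inherits(structures[[k]], "triangle_mesh")) {
      stop("structure ", k, " is not a triangle_mesh")
    }
  }
  miss <- setdiff(LANDMARK_NAMES, names(landmarks))
  if (length(miss) > 0) stop("missing landmarks: ", paste(miss, collapse = ", "))
  structure(list(structures = structures, landmarks = landmarks),
            class = "labeled_scene")
}

#' @export
print.labeled_scene <- function(x, ...) {
  cat("<labeled_scene>\n")
  for (k in names(x$structures)) {
    m <- x$structures[[k]]
    cat(sprintf("  %-8s %6d vertices %6d faces  %s\n", k,
                nrow(m$vertices), nrow(m$faces),
                if (is_closed_mesh(m)) "closed" else "open"))
  }
  invisible(x)
}

#' Construct a cardiac-phase scene sequence
#'
#' Frames share identical per-category topology (vertex counts and face
#' connectivity), so that per-node quantities can be tracked across phases.
#'
#' @param frames list of `labeled_scene` (length >= 2)
#' @param phase phase fraction per frame in `[0, 1)`; defaults to
#'   `(0:(n-1))/n`
#' @return object of class `scene_sequence`
#' @export
scene_sequence <- function(frames, phase = NULL) {
  n <- length(frames)
  if (n < 2) stop("a scene sequence needs at least 2 frames")
  if (is.null(phase)) phase <- (seq_len(n) - 1) / n
  if (length(phase) != n) stop("phase length must match frame count")
  cats <- names(frames[[1]]$structures)
  for (i in seq_len(n)) {
    fi <- frames[[i]]
    if (!inherits(fi, "labeled_scene")) stop("frame ", i, " is not a labeled_scene")
    if (!identical(sort(names(fi$structures)), sort(cats))) {
      stop("frame ", i, " has different structure categories than frame 1")
    }
    for (k in cats) {
      m0 <- frames[[1]]$structures[[k]]
      mi <- fi$structures[[k]]
      if (nrow(mi$vertices) != nrow(m0$vertices)) {
        stop(sprintf("topology mismatch: category %s has %d vertices in frame %d but %d in frame 1",
                     k, nrow(mi$vertices), i, nrow(m0$vertices)))
      }
      if (!identical(mi$faces, m0$faces)) {
        stop(sprintf("topology mismatch: category %s face connectivity differs in frame %d",
                     k, i))
      }
    }
  }
  structure(list(frames = frames, phase = phase), class = "scene_sequence")
}

#' @export
print.scene_sequence <- function(x, ...) {
  cat(sprintf("<scene_sequence: %d frames, categories %s>\n", length(x$frames),
              paste(names(x$frames[[1]]$structures), collapse = ", ")))
  invisible(x)
}

n_frames <- function(sequence) length(sequence$frames)

#' Per-frame cavity volumes of a sequence (mL)
#' @param sequence a `scene_sequence` whose scenes carry a closed `CAVITY` mesh
#' @export
frame_volumes <- function(sequence) {
  vapply(sequence$frames, function(sc) {
    cav <- sc$structures$CAVITY
    if (is.null(cav)) stop("sequence has no CAVITY structure")
    closed_mesh_volume(cav)
  }, numeric(1))
}

#' Ejection fraction measured from a sequence (%)
#'
#' `100 * (maxV - minV) / maxV` over the per-frame cavity volumes.
#' @param sequence a `scene_sequence` with closed cavity meshes
#' @export
measured_ef <- function(sequence) {
  v <- frame_volumes(sequence)
  100 * (max(v) - min(v)) / max(v)
}

#' Print per-category mesh statistics and closure status
#' @param scene a `labeled_scene`
#' @return invisibly, a data.frame of category, vertex/face counts, closure
#' @export
validate_scene <- function(scene) {
  rows <- lapply(names(scene$structures), function(k) {
    m <- scene$structures[[k]]
    data.frame(category = k, vertices = nrow(m$vertices), faces = nrow(m$faces),
               closed = is_closed_mesh(m),
               boundary_edges = boundary_edge_count(m))
  })
  df <- do.call(rbind, rows)
  print(df, row.names = FALSE)
  invisible(df)
}
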