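#' The 33-point pose-landmark topology
#'
#' Names of the 33 body landmarks produced by common monocular pose engines,
#' in topology order (indices 0-32). All pose containers in this package carry
#' exactly this set, in this order.
#'
#' @return Character vector of length 33.
#' @export
#' @examples
#' length(landmark_names())
landmark_names <- function() {
  c(
    "nose",
    "left_eye_inner", "left_eye", "left_eye_outer",
    "right_eye_inner", "right_eye", "right_eye_outer",
    "left_ear", "right_ear",
    "mouth_left", "mouth_right",
    "left_shoulder", "right_shoulder",
    "left_elbow", "right_elbow",
    "left_wrist", "right_wrist",
    "left_pinky", "right_pinky",
    "left_index", "right_index",
    "left_thumb", "right_thumb",
    "left_hip", "right_hip",
    "left_knee", "right_knee",
    "left_ankle", "right_ankle",
    "left_heel", "right_heel",
    "left_foot_index", "right_foot_index"
  )
}

# axis order used everywhere: x lateral (+ to walker's left), y vertical (+up),
# z forward (+ walking direction); right-handed.
.axes <- c("x", "y", "z")
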