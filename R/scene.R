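#' Specify a synthetic vessel
#'
#' Describes one simulated microvessel: a centerline polyline, a true
#' diameter, and a true axial velocity for the advected red-blood-cell /
#' plasma-gap texture. The cross-section is an inverted super-Gaussian
#' ("flattened tube") profile whose full width at half maximum equals
#' \code{diameter_um} exactly, so FWHM diametry has an analytic ground truth.
#'
#' @param points n x 2 matrix (columns x, y; pixels, 1-based) of centerline
#'   control points, ordered along the flow direction.
#' @param diameter_um true diameter (micrometres). Must lie in the 6-75 um
#'   detectability range of the imaging method.
#' @param velocity_mm_s true axial velocity (mm/s), signed along the
#'   parametrization of \code{points}.
#' @param contrast fractional intensity depression at the tube axis relative
#'   to the local background (0-1).
#' @param texture_length_um correlation length of the frozen axial intensity
#'   texture (micrometres).
#' @param type ground-truth vessel label: "arteriole", "venule" or
#'   "unlabeled".
#' @return a \code{vessel_spec} object.
#' @export
vessel_spec <- function(points, diameter_um, velocity_mm_s = 0,
                        contrast = 0.5, texture_length_um = 8,
                        type = "unlabeled") {
  points <- as.matrix(points)
  if (ncol(points) != 2 || nrow(points) < 2) {
    stop("points must be an n x 2 matrix with n >= 2")
  }
  if (diameter_um < 6 || diameter_um > 75) {
    stop("diameter_um must lie within the 6-75 um detectability range")
  }
  if (contrast <= 0 || contrast >= 1) stop("contrast must be in (0, 1)")
  type <- match.arg(type, c("unlabeled", "arteriole", "venule"))
  structure(
    list(
      points = points, diameter_um = diameter_um,
      velocity_mm_s = velocity_mm_s, contrast = contrast,
      texture_length_um = texture_length_um, type = type
    ),
    class = "vessel_spec"
  )
}

#' Specify a synthetic imaging scene
#'
#' Collects the field geometry, acquisition constants, degradations
#' (sensor noise, illumination gradient, whole-frame jitter, blink frames)
#' and the vessel list for \code{\link{render_sequence}}. Defaults mirror
#' the acquisition used for conjunctival imaging: 50 frames/s over one
#' second at 1.25 um/pixel.
#'
#' @param width,height field size in pixels (>= 64).
#' @param pixel_size_um pixel size on the object plane (um/pixel).
#' @param n_frames number of frames.
#' @param frame_rate_hz frame rate (frames/s).
#' @param background background intensity on a [0, 1] scale.
#' @param noise_sd standard deviation of additive Gaussian sensor noise.
#' @param illumination_gradient peak-to-peak amplitude of a planar
#'   illumination ramp, as a fraction of \code{background}.
#' @param background_texture standard deviation of the static scleral
#'   mottle (frozen 2-d texture of the tissue under the vessels), as a
#'   fraction of \code{background}. Real conjunctival fields always carry
#'   such static structure; it is what intensity-based registration locks
#'   onto, so leaving it at zero makes registration degenerate for scenes
#'   whose only content is moving blood.
#' @param background_texture_scale_px correlation scale of the mottle (px).
#' @param jitter_amplitude_px standard deviation of random whole-frame
#'   translations (pixels); ignored when \code{jitter_path} is given.
#' @param jitter_path optional \code{n_frames} x 2 matrix of explicit frame
#'   translations (dx, dy) in pixels; row for the first frame is typically
#'   \code{c(0, 0)}.
#' @param blink_frames 1-based indices of frames rendered as blinks
#'   (near-uniform dark frames at 10\% of the background intensity).
#' @param vessels list of \code{\link{vessel_spec}} objects.
#' @return a \code{scene_spec} object.
#' @export
scene_spec <- function(width, height, pixel_size_um = 1.25, n_frames = 50,
                       frame_rate_hz = 50, background = 0.8,
                       noise_sd = 0.01, illumination_gradient = 0,
                       background_texture = 0.05,
                       background_texture_scale_px = 6,
                       jitter_amplitude_px = 0, jitter_path = NULL,
                       blink_frames = integer(0), vessels = list()) {
  if (width < 64 || height < 64) stop("field dimensions must be >= 64 px")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (frame_rate_hz <= 0) stop("frame_rate_hz must be positive")
  if (n_frames < 1) stop("n_frames must be >= 1")
  if (background <= 0 || background > 1) stop("background must be in (0, 1]")
  if (length(blink_frames) &&
      (any(blink_frames < 1) || any(blink_frames > n_frames))) {
    stop("blink_frames must be valid frame indices (1..n_frames)")
  }
  if (!is.null(jitter_path)) {
    jitter_path <- as.matrix(jitter_path)
    if (nrow(jitter_path) != n_frames || ncol(jitter_path) != 2) {
      stop("jitter_path must be an n_frames x 2 matrix")
    }
  }
  for (v in vessels) {
    if (!inherits(v, "vessel_spec")) stop("vessels must be vessel_spec objects")
  }
  structure(
    list(
      width = as.integer(width), height = as.integer(height),
      pixel_size_um = pixel_size_um, n_frames = as.integer(n_frames),
      frame_rate_hz = frame_rate_hz, background = background,
      noise_sd = noise_sd, illumination_gradient = illumination_gradient,
      background_texture = background_texture,
      background_texture_scale_px = background_texture_scale_px,
      jitter_amplitude_px = jitter_amplitude_px, jitter_path = jitter_path,
      blink_frames = as.integer(blink_frames), vessels = vessels
    ),
    class = "scene_spec"
  )
}

# Convert a true axial velocity to a texture displacement in px/frame.
velocity_to_px_per_frame <- function(v_mm_s, pixel_size_um, frame_rate_hz) {
  v_mm_s * 1000 / frame_rate_hz / pixel_size_um
}
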