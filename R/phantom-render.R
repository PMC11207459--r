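## Parametric rasterization of the phantom anatomy at one time point.
## Row index = superior -> inferior (SI) direction; positive respiratory
## displacement shifts the liver inferiorly (larger row coordinate).
## Rendering is supersampled and block-averaged (partial-volume effect),
## so organ boundaries move continuously between frames.

block_mean <- function(m, H, W) {
  ss <- nrow(m) / H
  R1 <- matrix(0, H, nrow(m))
  R1[cbind(rep(seq_len(H), each = ss), seq_len(nrow(m)))] <- 1 / ss
  R2 <- matrix(0, W, ncol(m))
  R2[cbind(rep(seq_len(W), each = ss), seq_len(ncol(m)))] <- 1 / ss
  R1 %*% m %*% t(R2)
}

render_phantom_frame <- function(phantom, t, supersample = 3L) {
  cfg <- phantom$config
  g <- phantom$organ_geometry
  H0 <- cfg$grid_shape[1]; W0 <- cfg$grid_shape[2]
  ss <- as.integer(supersample)
  H <- H0 * ss; W <- W0 * ss
  px <- cfg$pixel_size_mm / ss
  y <- (seq_len(H) - 0.5) * px          # mm, rows
  x <- (seq_len(W) - 0.5) * px          # mm, cols
  Y <- matrix(y, H, W)
  X <- matrix(x, H, W, byrow = TRUE)

  ## abdominal view: body bounded by air; pelvic mid-sagittal view:
  ## tissue fills the field of view and the bladder is the bright organ
  if (cfg$region == "abdomen") {
    body <- X >= g$body_cols_mm[1] & X <= g$body_cols_mm[2] &
      Y >= 0.04 * g$fov_mm[1] & Y <= 0.96 * g$fov_mm[1]
    img <- ifelse(body, 0.5, 0)
  } else {
    body <- matrix(TRUE, H, W)
    img <- matrix(0.2, H, W)
  }
  liver_mask <- matrix(FALSE, H, W)
  bladder_mask <- matrix(FALSE, H, W)

  if (cfg$region == "abdomen") {
    d <- traj_at(phantom, "resp_displacement", t)
    xc <- mean(g$liver_cols_mm)
    hw <- diff(g$liver_cols_mm) / 2
    u <- (X - xc) / hw
    inside_cols <- abs(u) <= 1
    lb <- g$liver_boundary_mm + d + g$liver_dome_mm * u^2
    bottom <- lb + g$liver_thickness_mm * sqrt(pmax(1 - u^2, 0))
    liver_mask <- body & inside_cols & Y >= lb & Y <= bottom
    lung <- body & inside_cols & Y < lb
    img[lung] <- 0.08
    img[liver_mask] <- 0.9
    for (v in seq_len(nrow(g$vessel_centers_mm))) {
      vc <- g$vessel_centers_mm[v, ]
      vessel <- (Y - (vc[1] + d))^2 + (X - vc[2])^2 <= g$vessel_radius_mm[v]^2
      img[vessel & liver_mask] <- 0.25
    }
  } else {
    d <- traj_at(phantom, "resp_displacement", t)
    a <- traj_at(phantom, "bladder_a", t)
    b <- traj_at(phantom, "bladder_b", t)
    cy <- g$bladder_center_mm[1] + 0.2 * d
    cx <- g$bladder_center_mm[2]
    bladder_mask <- ((Y - cy) / b)^2 + ((X - cx) / a)^2 <= 1
    ## dim bowel-like structure; the bladder stays the bright class
    bowel <- ((Y - 0.2 * g$fov_mm[1]) / 20)^2 + ((X - 0.3 * g$fov_mm[2]) / 26)^2 <= 1
    img[bowel] <- 0.35
    img[bladder_mask] <- 0.9
  }
  list(image = block_mean(img, H0, W0),
       liver_mask = block_mean(liver_mask, H0, W0) >= 0.5,
       bladder_mask = block_mean(bladder_mask, H0, W0) >= 0.5)
}

#' Noise-free phantom image at a given time
#'
#' @param phantom a [make_breathing_phantom()] object.
#' @param t time (s).
#' @return 2D matrix of the phantom intensity at time `t`.
#' @export
phantom_image <- function(phantom, t = 0)
  render_phantom_frame(phantom, t)$image

#' Render a fast calibration image time series
#'
#' Emulates the high-frame-rate 2D bSSFP-like calibration acquisition:
#' one magnitude frame per `1/frame_rate` interval with the liver (or
#' bladder) displaced according to the phantom trajectory, plus additive
#' complex Gaussian noise. Ground-truth organ masks are returned with
#' every frame.
#'
#' @param phantom a [make_breathing_phantom()] object.
#' @param seq a [seq_params()] object (frame rate, matrix).
#' @param duration_s length to render (s); defaults to the trajectory
#'   span. Must not exceed it.
#' @param noise_sd standard deviation of the complex noise per channel
#'   (image scale is ~[0, 1]).
#' @param seed seed for the noise stream.
#' @return an `image_series` list: `frames` (H x W x T array),
#'   `masks` (logical H x W x T; liver for the abdominal phantom,
#'   bladder for the pelvic one), `timestamps` (s), `pixel_size_mm`,
#'   `region`.
#' @export
render_image_series <- function(phantom, seq = seq_params(),
                                duration_s = NULL, noise_sd = 0.02,
                                seed = phantom$seed + 1L) {
  if (is.null(duration_s)) duration_s <- phantom$config$duration_s
  if (duration_s > phantom$config$duration_s + 1e-9)
    stop("requested duration exceeds the phantom trajectory", call. = FALSE)
  n_frames <- floor(duration_s * seq$frame_rate_hz)
  ts <- (seq_len(n_frames) - 1) / seq$frame_rate_hz
  H <- phantom$config$grid_shape[1]; W <- phantom$config$grid_shape[2]
  frames <- array(0, c(H, W, n_frames))
  masks <- array(FALSE, c(H, W, n_frames))
  mask_field <- if (phantom$config$region == "abdomen") "liver_mask"
                else "bladder_mask"
  with_seed(seed, {
    for (k in seq_len(n_frames)) {
      fr <- render_phantom_frame(phantom, ts[k])
      if (noise_sd > 0) {
        re <- fr$image + matrix(rnorm(H * W, sd = noise_sd), H, W)
        im <- matrix(rnorm(H * W, sd = noise_sd), H, W)
        frames[, , k] <- sqrt(re^2 + im^2)
      } else frames[, , k] <- fr$image
      masks[, , k] <- fr[[mask_field]]
    }
  })
  structure(list(frames = frames, masks = masks, timestamps = ts,
                 pixel_size_mm = phantom$config$pixel_size_mm,
                 region = phantom$config$region),
            class = "image_series")
}
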