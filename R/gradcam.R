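# Volumetric Grad-CAM: class-gradient-weighted activation maps at a named
# convolutional stage, trilinearly upsampled to the input grid.

#' 3D Grad-CAM saliency map
#'
#' Channel weights are the spatial means of the class-score gradient at the
#' tap stage; the heatmap is `relu(sum_c w_c A_c)`, trilinearly upsampled to
#' the input spatial shape and min-max normalized to `[0, 1]` (an all-zero map
#' stays zero).
#'
#' @param net a `resrepanet` (eval mode is used).
#' @param x input feature volume `(d1, d2, d3, 1, batch)`.
#' @param target_class 1 = NC unit, 2 = AD unit (default 2).
#' @param tap_stage name of a convolutional stage (default `"res4"`).
#' @return array `(d1, d2, d3, batch)` of heatmaps in `[0, 1]`.
#' @export
gradcam3d <- function(net, x, target_class = 2L, tap_stage = "res4") {
  st <- net$spec$stages
  ok <- st$name[st$kind %in% c("resrep", "resblock3d", "ncsa")]
  if (!tap_stage %in% ok)
    stop(sprintf("unknown or non-convolutional tap stage '%s'", tap_stage), call. = FALSE)
  if (isTRUE(net$deploy))
    stop("Grad-CAM requires the training-form network (gradients through BN)",
         call. = FALSE)
  fw <- network_forward(net, x, training = FALSE, want_cache = TRUE, want_taps = TRUE)
  B <- dim(x)[5]
  dlogits <- matrix(0, B, net$spec$num_classes)
  dlogits[, target_class] <- 1
  bw <- network_backward(net, fw$cache, dlogits, tap_grad_stage = tap_stage)
  A <- fw$taps[[tap_stage]]
  G <- bw$tap_grad
  d <- dim(A)
  S <- prod(d[1:3])
  out <- array(0, c(dim(x)[1:3], B))
  for (b in seq_len(B)) {
    Ab <- matrix(A[, , , , b], S, d[4])
    Gb <- matrix(G[, , , , b], S, d[4])
    w <- .colMeans(Gb, S, d[4])
    cam <- relu(array(Ab %*% w, d[1:3]))
    cam <- trilinear_upsample(cam, dim(x)[1:3])
    rng <- range(cam)
    if (rng[2] > rng[1]) cam <- (cam - rng[1]) / (rng[2] - rng[1])
    out[, , , b] <- cam
  }
  out
}

#' Trilinear upsampling of a 3D volume
#'
#' Interpolates voxel centers (half-pixel alignment) to a target grid.
#'
#' @param vol numeric 3D array.
#' @param out_shape target dimensions.
#' @return array of dimension `out_shape`.
#' @export
trilinear_upsample <- function(vol, out_shape) {
  d <- dim(vol)
  if (all(d == out_shape)) return(vol)
  axis_map <- function(n_in, n_out) {
    src <- (seq_len(n_out) - 0.5) * n_in / n_out + 0.5
    i0 <- pmin(pmax(floor(src), 1), n_in)
    i1 <- pmin(i0 + 1, n_in)
    f <- pmin(pmax(src - i0, 0), 1)
    list(i0 = i0, i1 = i1, f = f)
  }
  m1 <- axis_map(d[1], out_shape[1])
  m2 <- axis_map(d[2], out_shape[2])
  m3 <- axis_map(d[3], out_shape[3])
  out <- array(0, out_shape)
  for (a in 0:1) for (b in 0:1) for (c in 0:1) {
    ix <- if (a == 0) m1$i0 else m1$i1
    iy <- if (b == 0) m2$i0 else m2$i1
    iz <- if (c == 0) m3$i0 else m3$i1
    wx <- if (a == 0) 1 - m1$f else m1$f
    wy <- if (b == 0) 1 - m2$f else m2$f
    wz <- if (c == 0) 1 - m3$f else m3$f
    w <- outer(outer(wx, wy), wz)
    out <- out + w * vol[ix, iy, iz]
  }
  out
}

#' Write an axial/coronal/sagittal heatmap triptych as PNG
#'
#' Mid-volume slices of the underlay with the Grad-CAM heatmap alpha-blended
#' on top.
#'
#' @param cam heatmap array `(d1, d2, d3)` in `[0, 1]`.
#' @param underlay matching anatomical volume (or `NULL`).
#' @param path output PNG path.
#' @export
write_gradcam_png <- function(cam, underlay = NULL, path) {
  d <- dim(cam)
  grDevices::png(path, width = 900, height = 320)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(1, 3), mar = c(1, 1, 2, 1))
  slices <- list(sagittal = list(cam[d[1] %/% 2, , ], if (!is.null(underlay)) underlay[d[1] %/% 2, , ]),
                 coronal = list(cam[, d[2] %/% 2, ], if (!is.null(underlay)) underlay[, d[2] %/% 2, ]),
                 axial = list(cam[, , d[3] %/% 2], if (!is.null(underlay)) underlay[, , d[3] %/% 2]))
  for (nm in names(slices)) {
    s <- slices[[nm]]
    if (!is.null(s[[2]]))
      graphics::image(s[[2]], col = grDevices::gray.colors(64, 0, 1), axes = FALSE,
                      main = nm)
    else
      graphics::image(s[[1]] * 0, col = "black", axes = FALSE, main = nm)
    hot <- grDevices::hcl.colors(64, "Inferno", alpha = 0.5)
    graphics::image(s[[1]], col = hot, add = TRUE,
                    zlim = c(1e-6, 1))
  }
  invisible(path)
}
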