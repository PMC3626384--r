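#' Phantom specification
#'
#' Describes a synthetic coronal ventilation-MRI acquisition: a stack of
#' 256 x 256 slices (8-14 typical) holding two ellipsoidal lungs whose
#' cross-section waxes and wanes anterior to posterior, a bright tracheal
#' tube with bronchial stubs spanning the middle slices, four in-lung
#' intensity classes (negligible / low / intermediate / high ventilation)
#' arranged concentrically, optional zero-signal defect pockets, and
#' background noise drawn from the adjusted Rayleigh model via inverse
#' transform.
#'
#' @param n_slices number of coronal slices.
#' @param n_rows,n_cols slice dimensions in pixels.
#' @param class_levels four mean intensities, strictly increasing
#'   (negligible, low, intermediate, high).
#' @param class_fractions spatial area fractions of the four classes inside
#'   each lung (sum to 1); classes are arranged concentrically with high
#'   ventilation at the core and negligible ventilation at the rim.
#' @param jitter_sd SD of the additive Gaussian jitter on lung/airway signal.
#' @param noise_sigma,noise_alpha,noise_delta background-noise model
#'   parameters (see [adjusted_rayleigh()]).
#' @param blur_sigma optional Gaussian blur width in pixels (0 = none).
#' @param lung_scale multiplier on the lung semi-axes (default 1; values much
#'   above 1 push the ellipses out of the slice and are rejected).
#' @param trachea_width tube width in pixels; the tube sits at the horizontal
#'   centre of the image, separated from the lungs by at least 2 px.
#' @param trachea_slices integer vector of slice indices containing the
#'   airway (default: the middle third of the stack).
#' @param trachea_level airway intensity (default: the high-ventilation
#'   level, the airway holds the largest share of inhaled gas).
#' @param defect_n number of defect pockets per affected slice.
#' @param defect_radius length-2 integer range of defect radii (pixels).
#' @param in_plane_mm,slice_thickness_mm,slice_gap_mm voxel geometry.
#' @param seed integer seed; the phantom is bit-identical for equal seeds.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_slices = 10, n_rows = 256, n_cols = 256,
                         class_levels = c(0, 60, 120, 200),
                         class_fractions = c(0.05, 0.15, 0.30, 0.50),
                         jitter_sd = 5, lung_scale = 1,
                         noise_sigma = 10, noise_alpha = 1, noise_delta = 0,
                         blur_sigma = 0,
                         trachea_width = 12, trachea_slices = NULL,
                         trachea_level = NULL,
                         defect_n = 0, defect_radius = c(4, 6),
                         in_plane_mm = 1.8, slice_thickness_mm = 13,
                         slice_gap_mm = 0, seed = 42) {
  stopifnot(n_slices >= 1, n_rows >= 64, n_cols >= 64,
            length(class_levels) == 4L, all(diff(class_levels) > 0),
            length(class_fractions) == 4L, all(class_fractions >= 0),
            abs(sum(class_fractions) - 1) < 1e-9,
            noise_sigma > 0, noise_alpha > 0, trachea_width >= 4)
  if (is.null(trachea_slices)) {
    trachea_slices <- seq(max(1L, ceiling(n_slices / 3)),
                          min(n_slices, floor(2 * n_slices / 3)))
  }
  structure(
    list(n_slices = as.integer(n_slices), n_rows = as.integer(n_rows),
         n_cols = as.integer(n_cols),
         class_levels = class_levels, class_fractions = class_fractions,
         jitter_sd = jitter_sd, lung_scale = lung_scale,
         noise_sigma = noise_sigma,
         noise_alpha = noise_alpha, noise_delta = noise_delta,
         blur_sigma = blur_sigma,
         trachea_width = as.integer(trachea_width),
         trachea_slices = as.integer(trachea_slices),
         trachea_level = trachea_level %||% class_levels[4L],
         defect_n = as.integer(defect_n),
         defect_radius = as.integer(defect_radius),
         in_plane_mm = in_plane_mm, slice_thickness_mm = slice_thickness_mm,
         slice_gap_mm = slice_gap_mm, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# per-slice lung ellipse parameters; scale follows a spherical profile
phantom_lung_geometry <- function(spec) {
  n <- spec$n_slices
  mid <- (n + 1) / 2
  half <- max(mid - 0.5, 1)
  lapply(seq_len(n), function(k) {
    s <- sqrt(pmax(0.15, 1 - ((k - mid) / (half + 1))^2)) *
      (spec$lung_scale %||% 1)
    # lungs stay clear of the bottom-centre noise sampling box
    # (cr + a <= 0.78 * n_rows < n_rows - 25 for slices >= 114 rows)
    a <- 0.28 * spec$n_rows * s           # vertical semi-axis
    b <- 0.125 * spec$n_cols * s          # horizontal semi-axis
    cr <- 0.50 * spec$n_rows
    list(
      left = list(cr = cr, cc = 0.30 * spec$n_cols, a = a, b = b),
      right = list(cr = cr, cc = 0.70 * spec$n_cols, a = a, b = b)
    )
  })
}

# normalized elliptic radius (<= 1 inside the lung) for every pixel
elliptic_rho <- function(nr, nc, ell) {
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  sqrt(((r - ell$cr) / ell$a)^2 + ((c - ell$cc) / ell$b)^2)
}

#' Generate a synthetic ventilation-MRI phantom
#'
#' Builds the image stack described by a [phantom_spec()] together with its
#' ground truth. Background pixels are i.i.d. draws from the adjusted
#' Rayleigh model (inverse transform, clipped at 0); lung and airway pixels
#' are their class level plus Gaussian jitter; defect pockets are disks
#' inside the lungs re-filled with background noise. The truth mask contains
#' the lung pixels of the low/intermediate/high classes (negligible
#' ventilation and defects are excluded); the airway mask is disjoint from it
#' by construction.
#'
#' @param spec a `phantom_spec`.
#' @return a list with `image` (`image_stack`), `truth` (`mask_stack` of
#'   ventilated airspace), `truth_airway` (`mask_stack`), `truth_labels`
#'   (list of integer matrices, 0 = background/defect, 1..4 = ventilation
#'   class), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- phantom_lung_geometry(spec)
  nr <- spec$n_rows
  nc <- spec$n_cols
  for (g in geom) {
    for (ell in g) {
      if (ell$cr - ell$a < 1 || ell$cr + ell$a > nr ||
          ell$cc - ell$b < 1 || ell$cc + ell$b > nc) {
        stop("lung ellipse exceeds image bounds; enlarge the slice or shrink the lungs",
             call. = FALSE)
      }
    }
  }
  # concentric class bands: area within rho <= t scales as t^2
  fr <- spec$class_fractions
  t_high <- sqrt(fr[4L])
  t_int <- sqrt(fr[4L] + fr[3L])
  t_low <- sqrt(fr[4L] + fr[3L] + fr[2L])

  tube_cols <- seq.int(floor((nc - spec$trachea_width) / 2) + 1L,
                       length.out = spec$trachea_width)
  tube_rows <- seq.int(max(2L, round(0.10 * nr)), round(0.45 * nr))

  with_local_seed(spec$seed, {
    images <- vector("list", spec$n_slices)
    truth <- vector("list", spec$n_slices)
    airway <- vector("list", spec$n_slices)
    labels <- vector("list", spec$n_slices)
    for (k in seq_len(spec$n_slices)) {
      bg <- matrix(rayleigh_noise(nr * nc, spec$noise_sigma, spec$noise_alpha,
                                  spec$noise_delta), nr, nc)
      lab <- matrix(0L, nr, nc)
      signal <- matrix(0, nr, nc)
      for (ell in geom[[k]]) {
        rho <- elliptic_rho(nr, nc, ell)
        cls <- matrix(0L, nr, nc)
        cls[rho <= 1] <- 1L                 # negligible rim
        cls[rho <= t_low] <- 2L
        cls[rho <= t_int] <- 3L
        cls[rho <= t_high] <- 4L
        sel <- cls > 0L
        lab[sel] <- cls[sel]
        signal[sel] <- spec$class_levels[cls[sel]]
      }
      aw <- matrix(0L, nr, nc)
      if (k %in% spec$trachea_slices) {
        aw[tube_rows, tube_cols] <- 1L
        aw <- add_bronchi_stubs(aw, lab, tube_rows, tube_cols)
        signal[aw == 1L] <- spec$trachea_level
      }
      # defect pockets: background-filled disks fully inside the ventilated zone
      defect <- matrix(FALSE, nr, nc)
      if (spec$defect_n > 0L && k %in% spec$trachea_slices) {
        defect <- place_defects(lab, spec$defect_n, spec$defect_radius, nr, nc)
      }
      in_signal <- (lab > 0L | aw == 1L) & !defect
      img <- bg
      img[in_signal] <- signal[in_signal] +
        rnorm(sum(in_signal), 0, spec$jitter_sd)
      img <- pmax(img, 0)
      if (spec$blur_sigma > 0) img <- gaussian_blur(img, spec$blur_sigma)
      lab[defect | aw == 1L] <- 0L
      images[[k]] <- matrix(img, nr, nc)
      truth[[k]] <- matrix(as.integer(lab >= 2L), nr, nc)
      airway[[k]] <- aw
      labels[[k]] <- lab
    }
    list(
      image = image_stack(images, in_plane_mm = spec$in_plane_mm,
                          slice_thickness_mm = spec$slice_thickness_mm,
                          slice_gap_mm = spec$slice_gap_mm),
      truth = mask_stack(truth, in_plane_mm = spec$in_plane_mm,
                         slice_thickness_mm = spec$slice_thickness_mm,
                         slice_gap_mm = spec$slice_gap_mm),
      truth_airway = mask_stack(airway, in_plane_mm = spec$in_plane_mm,
                                slice_thickness_mm = spec$slice_thickness_mm,
                                slice_gap_mm = spec$slice_gap_mm),
      truth_labels = labels,
      spec = spec
    )
  })
}

# horizontal main-stem stubs from the tube bottom toward (but never touching)
# each lung: they stop 3 px short of the nearest lung pixel in their rows
add_bronchi_stubs <- function(aw, lab, tube_rows, tube_cols) {
  stub_rows <- tail(tube_rows, 3L)
  lung_cols <- which(colSums(lab[stub_rows, , drop = FALSE] > 0L) > 0L)
  if (!length(lung_cols)) return(aw)
  left_edge <- max(lung_cols[lung_cols < min(tube_cols)], -Inf)
  right_edge <- min(lung_cols[lung_cols > max(tube_cols)], Inf)
  if (is.finite(left_edge)) {
    aw[stub_rows, (left_edge + 3L):(min(tube_cols) - 1L)] <- 1L
  }
  if (is.finite(right_edge)) {
    aw[stub_rows, (max(tube_cols) + 1L):(right_edge - 3L)] <- 1L
  }
  aw
}

place_defects <- function(lab, n_defects, radius_range, nr, nc) {
  defect <- matrix(FALSE, nr, nc)
  # candidate centres: deep enough inside the ventilated zone for the disk
  candidates <- which(lab >= 3L)
  for (i in seq_len(n_defects)) {
    rad <- if (radius_range[1L] == radius_range[2L]) radius_range[1L] else
      sample(seq.int(radius_range[1L], radius_range[2L]), 1L)
    disk <- disk_element(rad)$offsets
    for (try in 1:50) {
      ctr <- candidates[sample.int(length(candidates), 1L)]
      r0 <- ((ctr - 1L) %% nr) + 1L
      c0 <- ((ctr - 1L) %/% nr) + 1L
      rr <- r0 + disk[, 1L]
      cc <- c0 + disk[, 2L]
      if (any(rr < 1L | rr > nr | cc < 1L | cc > nc)) next
      idx <- (cc - 1L) * nr + rr
      if (all(lab[idx] >= 2L) && !any(defect[idx])) {
        defect[idx] <- TRUE
        break
      }
    }
  }
  defect
}

gaussian_blur <- function(img, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  kern <- dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  pad_conv <- function(m, k) {
    # separable 1-D convolution along rows with edge replication
    n <- nrow(m)
    idx <- pmin(pmax(outer(seq_len(n), -half:half, "+"), 1L), n)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * m[idx[, j], , drop = FALSE]
    out
  }
  t(pad_conv(t(pad_conv(img, kern)), kern))
}

#' Bundled end-to-end phantom fixtures
#'
#' Three preset phantoms with matching airway seed specifications, used to
#' exercise the full pipeline:
#'
#' * `easy`: clean conditions — class levels (30, 80, 140, 200), background
#'   Rayleigh sigma 5, jitter SD 4, no defects.
#' * `realistic`: levels (55, 100, 150, 210), sigma 10, jitter SD 7, three
#'   defect pockets of radius 4-6 px on the airway-bearing slices.
#' * `hard`: low SNR — levels (40, 70, 100, 140), sigma 18, jitter SD 12,
#'   six defects.
#'
#' All presets are 10 slices of 256 x 256 at the default voxel geometry. The
#' seed specs place one seed at the tube centre of each airway-bearing slice
#' with a bounding box around the airway (tube plus stubs) with a 4-px
#' margin.
#'
#' @param level `"easy"`, `"realistic"` or `"hard"`.
#' @param seed integer seed.
#' @return a list: the [generate_phantom()] output plus `seeds` (a list of
#'   [seed_spec()]).
#' @export
end_to_end_fixture <- function(level = c("easy", "realistic", "hard"),
                               seed = 42) {
  level <- match.arg(level)
  spec <- switch(level,
    easy = phantom_spec(class_levels = c(30, 80, 140, 200), noise_sigma = 5,
                        jitter_sd = 4, defect_n = 0, seed = seed),
    realistic = phantom_spec(class_levels = c(55, 100, 150, 210),
                             noise_sigma = 10, jitter_sd = 7, defect_n = 3,
                             defect_radius = c(4, 6), seed = seed),
    hard = phantom_spec(class_levels = c(40, 70, 100, 140), noise_sigma = 18,
                        jitter_sd = 12, defect_n = 6, defect_radius = c(4, 6),
                        seed = seed)
  )
  ph <- generate_phantom(spec)
  ph$seeds <- phantom_seed_specs(ph)
  ph
}

#' Seed specifications matching a phantom's airway
#'
#' One [seed_spec()] per airway-bearing slice: the seed sits at the centroid
#' of the tube column band in a middle tube row, and the bounding box is the
#' airway's bounding box padded by 4 px (clipped to the image).
#'
#' @param phantom output of [generate_phantom()].
#' @return list of `seed_spec` objects.
#' @export
phantom_seed_specs <- function(phantom) {
  specs <- list()
  nr <- phantom$image$n_rows
  nc <- phantom$image$n_cols
  for (k in seq_len(n_slices(phantom$truth_airway))) {
    aw <- phantom$truth_airway$slices[[k]]
    on <- which(aw == 1L)
    if (!length(on)) next
    r <- ((on - 1L) %% nr) + 1L
    c <- ((on - 1L) %/% nr) + 1L
    bbox <- c(max(1L, min(r) - 4L), max(1L, min(c) - 4L),
              min(nr, max(r) + 4L), min(nc, max(c) + 4L))
    seed_rc <- c(round(quantile(r, 0.25, names = FALSE)), round(mean(range(c))))
    specs[[length(specs) + 1L]] <- seed_spec(k, seed_rc, bbox)
  }
  specs
}
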