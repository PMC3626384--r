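#' Seed specification for airway removal
#'
#' One per slice in which the trachea or main-stem bronchi are visible: a
#' manually chosen seed pixel inside the airway and a bounding box limiting
#' the region-growing search space. All coordinates are 1-based `(row, col)`
#' with the box given inclusively as `(row_min, col_min, row_max, col_max)`.
#' The seed must lie strictly inside the box.
#'
#' @param slice 1-based slice index.
#' @param seed length-2 integer vector `(row, col)`.
#' @param bbox length-4 integer vector `(row_min, col_min, row_max, col_max)`.
#' @return an object of class `seed_spec`.
#' @export
seed_spec <- function(slice, seed, bbox) {
  slice <- as.integer(slice)
  seed <- as.integer(seed)
  bbox <- as.integer(bbox)
  stopifnot(length(seed) == 2L, length(bbox) == 4L, slice >= 1L)
  if (!(bbox[1L] <= bbox[3L] && bbox[2L] <= bbox[4L])) {
    stop("bbox must satisfy row_min <= row_max and col_min <= col_max", call. = FALSE)
  }
  if (!(seed[1L] > bbox[1L] && seed[1L] < bbox[3L] &&
        seed[2L] > bbox[2L] && seed[2L] < bbox[4L])) {
    stop("seed must lie strictly inside bbox", call. = FALSE)
  }
  structure(list(slice = slice, seed = seed, bbox = bbox), class = "seed_spec")
}

#' Read and write seed/bounding-box sidecar files
#'
#' JSON schema: an array of objects
#' `{"slice": int, "seed": [row, col], "bbox": [row_min, col_min, row_max, col_max]}`,
#' all indices 1-based inclusive.
#'
#' @param path JSON file path.
#' @return `read_seed_specs()`: a list of [seed_spec()] objects.
#' @export
read_seed_specs <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(raw, function(x) seed_spec(x$slice, unlist(x$seed), unlist(x$bbox)))
}

#' @rdname read_seed_specs
#' @param specs a list of `seed_spec` objects.
#' @export
write_seed_specs <- function(specs, path) {
  payload <- lapply(specs, function(s) {
    list(slice = s$slice, seed = s$seed, bbox = s$bbox)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE)
  invisible(path)
}

#' Seeded region growing
#'
#' Adams-Bischof growth restricted to the bounding box of `spec`: starting
#' from the seed pixel, the frontier pixel `z` (4- or 8-neighbour of the
#' region, inside the box) with the smallest difference from the region's
#' running mean gray value, `delta(z) = |g(z) - mean(A)|`, is admitted and the
#' mean updated, until the frontier is empty or the minimal difference
#' exceeds the stopping bound. Frontier ties are broken by 1-based
#' `(row, col)` lexicographic order, so the algorithm is deterministic.
#'
#' The stopping bound is `stop_delta` when supplied. When `stop_delta` is
#' `NULL`, an adaptive bound `max(0.2 * mean(A), 2 * sigma)` is used (the
#' airway lumen is nearly homogeneous in signal, so a generous homogeneity
#' bound relative to the running mean and the background-noise scale
#' suffices); `sigma` defaults to 0, reducing the adaptive rule to
#' `0.2 * mean(A)`.
#'
#' @param slice numeric matrix (grayscale slice; pass a 0/1 matrix to grow on
#'   a binary image instead).
#' @param spec a [seed_spec()] (its `slice` index is not consulted here).
#' @param stop_delta non-negative stopping bound, or `NULL` for the adaptive
#'   rule.
#' @param sigma background-noise scale used by the adaptive rule.
#' @param connectivity 4 (default, conservative against diagonal leaks) or 8.
#' @return binary matrix of the same shape: the admitted region (contains the
#'   seed, connected, confined to the box).
#' @export
region_grow <- function(slice, spec, stop_delta = NULL, sigma = 0,
                        connectivity = 4) {
  stopifnot(is.matrix(slice), inherits(spec, "seed_spec"))
  nr <- nrow(slice)
  nc <- ncol(slice)
  bb <- spec$bbox
  if (bb[1L] < 1L || bb[2L] < 1L || bb[3L] > nr || bb[4L] > nc) {
    stop("bbox exceeds image bounds", call. = FALSE)
  }
  if (!is.null(stop_delta) && stop_delta < 0) {
    stop("stop_delta must be >= 0", call. = FALSE)
  }
  nb <- neighbour_offsets(connectivity)
  seed_idx <- (spec$seed[2L] - 1L) * nr + spec$seed[1L]

  in_box <- function(r, c) r >= bb[1L] & r <= bb[3L] & c >= bb[2L] & c <= bb[4L]
  region <- matrix(FALSE, nr, nc)
  region[seed_idx] <- TRUE
  total <- slice[seed_idx]
  count <- 1L

  # frontier kept as linear indices; delta recomputed against the running mean
  frontier <- integer(0)
  add_neighbours <- function(idx, frontier, region) {
    r <- ((idx - 1L) %% nr) + 1L
    c <- ((idx - 1L) %/% nr) + 1L
    for (i in seq_len(nrow(nb))) {
      rr <- r + nb[i, 1L]
      cc <- c + nb[i, 2L]
      if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc && in_box(rr, cc)) {
        j <- (cc - 1L) * nr + rr
        if (!region[j] && !(j %in% frontier)) frontier <- c(frontier, j)
      }
    }
    frontier
  }
  frontier <- add_neighbours(seed_idx, frontier, region)

  while (length(frontier)) {
    mu <- total / count
    delta <- abs(slice[frontier] - mu)
    bound <- if (is.null(stop_delta)) max(0.2 * mu, 2 * sigma) else stop_delta
    dmin <- min(delta)
    if (dmin > bound) break
    cand <- frontier[delta == dmin]
    # (row, col) lexicographic tie-break
    r <- ((cand - 1L) %% nr) + 1L
    c <- ((cand - 1L) %/% nr) + 1L
    z <- cand[order(r, c)][1L]
    frontier <- frontier[frontier != z]
    region[z] <- TRUE
    total <- total + slice[z]
    count <- count + 1L
    frontier <- add_neighbours(z, frontier, region)
  }
  matrix(as.integer(region), nr, nc)
}

neighbour_offsets <- function(connectivity) {
  connectivity <- as.integer(connectivity)
  if (connectivity == 4L) {
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  } else if (connectivity == 8L) {
    cbind(rep(-1:1, each = 3L), rep(-1:1, 3L))[-5L, , drop = FALSE]
  } else {
    stop("connectivity must be 4 or 8", call. = FALSE)
  }
}

#' Connected-component labelling
#'
#' Labels the connected foreground components of a binary raster `1..K` in
#' order of first appearance in a row-major scan (background stays 0).
#' Components are found with an undirected pixel-adjacency graph
#' ([igraph::components()]).
#'
#' @param mask binary matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix of labels.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  nr <- nrow(mask)
  nc <- ncol(mask)
  fg <- which(mask != 0)
  out <- matrix(0L, nr, nc)
  if (!length(fg)) return(out)
  id <- matrix(0L, nr, nc)
  id[fg] <- seq_along(fg)
  offs <- neighbour_offsets(connectivity)
  # forward offsets only (each undirected edge once)
  offs <- offs[offs[, 1L] > 0L | (offs[, 1L] == 0L & offs[, 2L] > 0L), , drop = FALSE]
  edges <- integer(0)
  m <- mask != 0
  for (i in seq_len(nrow(offs))) {
    dr <- offs[i, 1L]
    dc <- offs[i, 2L]
    sh <- shift_matrix(m, -dr, -dc, FALSE)  # sh[r,c] = m[r+dr, c+dc]
    both <- which(m & sh)
    if (length(both)) {
      edges <- c(edges, rbind(id[both], id[both + dr + dc * nr]))
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership
  # renumber components by first row-major occurrence
  rm_order <- order(((fg - 1L) %% nr) + 1L, ((fg - 1L) %/% nr) + 1L)
  first_seen <- comp[rm_order][!duplicated(comp[rm_order])]
  relabel <- integer(max(comp))
  relabel[first_seen] <- seq_along(first_seen)
  out[fg] <- relabel[comp]
  out
}

#' Remove small connected components
#'
#' Keeps the components with at least `min_area` pixels; components of fewer
#' than `min_area` pixels are removed (strict "fewer than" semantics, so with
#' the default `min_area = 50` a 50-pixel component survives). Idempotent.
#'
#' @param mask binary matrix.
#' @param min_area minimum surviving component area, >= 1.
#' @param connectivity 4 or 8 (default 8).
#' @return binary matrix.
#' @export
area_filter <- function(mask, min_area = 50, connectivity = 8) {
  stopifnot(min_area >= 1)
  lab <- label_components(mask, connectivity)
  if (max(lab) == 0L) return(matrix(0L, nrow(mask), ncol(mask)))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= min_area)
  matrix(as.integer(lab %in% keep), nrow(mask), ncol(mask))
}

#' Binary subtraction of an airway mask
#'
#' `mask AND NOT airway`: removes the airway pixels from the ventilation
#' mask. Airway pixels outside the mask are ignored; the result is always a
#' subset of `mask`.
#'
#' @param mask,airway binary matrices of the same shape.
#' @return binary matrix.
#' @export
subtract_airway <- function(mask, airway) {
  if (!all(dim(mask) == dim(airway))) {
    stop("mask and airway shapes differ", call. = FALSE)
  }
  matrix(as.integer(mask != 0 & airway == 0), nrow(mask), ncol(mask))
}

#' Template box for the morphological cleanup
#'
#' The box centred at the mask centroid extending one quarter of the mask's
#' maximum width horizontally and one half of its maximum height vertically
#' (half-extents W/4 and H/2), rounded to the enclosed integer box and
#' clipped to the image bounds (a 100 x 100 solid square thus yields a
#' 50 x 100 box about its centre, and a single-pixel mask a 1 x 1 box).
#' Morphological operations are confined to this box to maximize
#' removal of airways attached near the mediastinum while minimizing
#' distortion along the lung boundary.
#'
#' @param mask nonempty binary matrix.
#' @return integer vector `(row_min, col_min, row_max, col_max)`, 1-based
#'   inclusive.
#' @export
compute_template <- function(mask) {
  on <- which(mask != 0)
  if (!length(on)) stop("cannot compute a template for an empty mask", call. = FALSE)
  nr <- nrow(mask)
  r <- ((on - 1L) %% nr) + 1L
  c <- ((on - 1L) %/% nr) + 1L
  cen_r <- mean(r)
  cen_c <- mean(c)
  H <- diff(range(r)) + 1L
  W <- diff(range(c)) + 1L
  box <- c(max(1L, ceiling(cen_r - H / 2)), max(1L, ceiling(cen_c - W / 4)),
           min(nr, floor(cen_r + H / 2)), min(ncol(mask), floor(cen_c + W / 4)))
  if (box[1L] > box[3L]) box[c(1L, 3L)] <- round(cen_r)
  if (box[2L] > box[4L]) box[c(2L, 4L)] <- round(cen_c)
  as.integer(box)
}

#' Templated morphological cleanup
#'
#' Discards weakly connected residual airway structure: binary erosion, then
#' connected-component labelling with an area filter (components of fewer
#' than `min_area` pixels removed), then binary dilation. Erosion and
#' dilation act only inside the template box (see [compute_template()]);
#' pixels outside the box pass through unchanged. With the same element used
#' for erosion and dilation the in-box result is an area-filtered
#' morphological opening, so the output never exceeds the input inside the
#' box.
#'
#' @param mask binary matrix.
#' @param se structuring element (default disk of radius 2, about 3.6 mm at
#'   1.8 mm/pixel).
#' @param min_area area-filter threshold (default 50 pixels).
#' @param template optional `(row_min, col_min, row_max, col_max)` box;
#'   computed from `mask` when `NULL`.
#' @param connectivity labelling connectivity for the area filter.
#' @return binary matrix.
#' @export
morphological_cleanup <- function(mask, se = disk_element(2), min_area = 50,
                                  template = NULL, connectivity = 8) {
  if (all(mask == 0L)) return(matrix(0L, nrow(mask), ncol(mask)))
  tpl <- template %||% compute_template(mask)
  inside <- matrix(FALSE, nrow(mask), ncol(mask))
  inside[tpl[1L]:tpl[3L], tpl[2L]:tpl[4L]] <- TRUE

  splice <- function(processed, original) {
    out <- original
    out[inside] <- processed[inside]
    matrix(as.integer(out), nrow(original), ncol(original))
  }
  eroded <- splice(binary_erode(mask, se), mask)
  filtered <- area_filter(eroded, min_area, connectivity)
  # dilate the template-interior content only: dilating the spliced raster
  # would let un-eroded out-of-box pixels spill across the box edge, breaking
  # the opening bound (output subset of input) inside the template
  interior <- matrix(as.integer(filtered & inside), nrow(mask), ncol(mask))
  splice(binary_dilate(interior, se), filtered)
}

#' Remove the trachea and main-stem bronchi from a refined mask
#'
#' Per slice with a [seed_spec()]: grow the airway region from the seed
#' inside its bounding box on the grayscale slice ([region_grow()]), keep the
#' grown component containing the seed and drop fragments smaller than
#' `min_area` ([label_components()] / [area_filter()]), subtract the isolated
#' airway from the refined mask ([subtract_airway()]), then run the templated
#' [morphological_cleanup()]. Slices without a spec pass through the
#' morphological cleanup only. The output is always a subset of `refined`.
#'
#' @param stack the source `image_stack` (gray values drive region growing).
#' @param refined the refined `mask_stack` (after [refine_mask()]).
#' @param specs list of `seed_spec` objects (may be empty).
#' @param stop_delta region-growing stopping bound; `NULL` (default) uses the
#'   adaptive rule of [region_grow()] with the per-slice `sigmas`.
#' @param sigmas optional numeric vector of per-slice background-noise scales
#'   (e.g. `vapply(fit_noise(stack), function(f) f$sigma, numeric(1))`).
#' @param se structuring element for the cleanup.
#' @param min_area area-filter threshold (pixels).
#' @param grow_connectivity connectivity for region growing (default 4).
#' @param label_connectivity connectivity for labelling/area filters
#'   (default 8).
#' @return a list with `mask` (the final `mask_stack`) and `airway` (a
#'   `mask_stack` of the removed airway pixels).
#' @export
remove_airways <- function(stack, refined, specs = list(), stop_delta = NULL,
                           sigmas = NULL, se = disk_element(2), min_area = 50,
                           grow_connectivity = 4, label_connectivity = 8) {
  stopifnot(inherits(stack, "image_stack"), inherits(refined, "mask_stack"))
  if (!same_geometry(stack, refined)) {
    stop("stack and refined mask geometry differ", call. = FALSE)
  }
  ns <- n_slices(stack)
  spec_slice <- vapply(specs, function(s) s$slice, integer(1L))
  if (length(spec_slice) && (max(spec_slice) > ns || min(spec_slice) < 1L)) {
    stop("seed spec references a nonexistent slice", call. = FALSE)
  }
  if (!is.null(sigmas) && length(sigmas) != ns) {
    stop(sprintf("got %d sigmas for %d slices", length(sigmas), ns), call. = FALSE)
  }
  out <- vector("list", ns)
  airway <- vector("list", ns)
  for (k in seq_len(ns)) {
    m <- refined$slices[[k]]
    airway_k <- matrix(0L, nrow(m), ncol(m))
    for (s in specs[spec_slice == k]) {
      grown <- region_grow(stack$slices[[k]], s, stop_delta = stop_delta,
                           sigma = if (is.null(sigmas)) 0 else sigmas[k],
                           connectivity = grow_connectivity)
      lab <- label_components(grown, label_connectivity)
      seed_lab <- lab[s$seed[1L], s$seed[2L]]
      isolated <- matrix(as.integer(lab == seed_lab & seed_lab > 0L),
                         nrow(m), ncol(m))
      isolated <- area_filter(isolated, min_area, label_connectivity)
      airway_k <- matrix(as.integer(airway_k | isolated), nrow(m), ncol(m))
    }
    m2 <- subtract_airway(m, airway_k)
    if (any(m2 != 0L)) {
      m2 <- morphological_cleanup(m2, se = se, min_area = min_area,
                                  connectivity = label_connectivity)
    }
    out[[k]] <- m2
    airway[[k]] <- matrix(as.integer(airway_k & m), nrow(m), ncol(m))
  }
  list(mask = mask_stack(out, like = refined),
       airway = mask_stack(airway, like = refined))
}
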