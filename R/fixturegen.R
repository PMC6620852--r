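# Synthetic muscle-histology fixture generator.
#
# Real muscle cross-sections show tightly packed, convex-ish fibres separated
# by thin connective-tissue bands that are often pale, noisy and locally
# broken. The generator emulates exactly that structure: a Lloyd-relaxed
# Voronoi tessellation gives packed polygonal fibres, cells are separated by
# a label-0 band, and the renderer paints an H&E-like image with per-fibre
# stain jitter, texture noise, sparse nuclei and a configurable fraction of
# boundary pixels recoloured as fibre interior ("broken" boundaries).

#' Stain and artifact parameters for the synthetic renderer
#'
#' @param fiber_color,boundary_color,nuclei_color base RGB triples in
#'   `[0, 1]` for fibre interior (eosin pink), inter-fibre band (pale
#'   endomysium) and nuclei (hematoxylin purple).
#' @param hue_jitter per-fibre additive RGB jitter half-range.
#' @param brightness_jitter per-fibre multiplicative brightness half-range.
#' @param texture_noise standard deviation of per-pixel Gaussian noise.
#' @param boundary_break_rate fraction of boundary-band pixels recoloured as
#'   fibre interior, in `[0, 1]`; emulates unclear/broken fibre boundaries.
#' @param nuclei_density expected nuclei per pixel.
#' @return an object of class `stain_params`.
#' @export
stain_params <- function(fiber_color = c(0.85, 0.56, 0.64),
                         boundary_color = c(0.93, 0.89, 0.93),
                         nuclei_color = c(0.30, 0.17, 0.45),
                         hue_jitter = 0.06,
                         brightness_jitter = 0.10,
                         texture_noise = 0.035,
                         boundary_break_rate = 0.15,
                         nuclei_density = 5e-4) {
  stopifnot(length(fiber_color) == 3, length(boundary_color) == 3,
            length(nuclei_color) == 3,
            is.finite(hue_jitter), is.finite(brightness_jitter),
            is.finite(texture_noise), is.finite(nuclei_density),
            boundary_break_rate >= 0, boundary_break_rate <= 1)
  structure(list(fiber_color = fiber_color, boundary_color = boundary_color,
                 nuclei_color = nuclei_color, hue_jitter = hue_jitter,
                 brightness_jitter = brightness_jitter,
                 texture_noise = texture_noise,
                 boundary_break_rate = boundary_break_rate,
                 nuclei_density = nuclei_density),
            class = "stain_params")
}

#' Generate a packed-fibre layout
#'
#' Builds a label image of `n_fibers` convex-ish fibre regions by Lloyd-relaxed
#' Voronoi tessellation (2 relaxation iterations); every pair of touching
#' cells is separated by a label-0 band of about `boundary_width` pixels and
#' the image border carries a label-0 margin. Deterministic given `seed`.
#'
#' @param n_fibers number of fibres (>= 1).
#' @param height,width image size in pixels.
#' @param boundary_width width of the separating band in pixels (>= 1).
#' @param seed integer seed.
#' @return an object of class `fiber_layout`: list with `label_image`
#'   (integer matrix; 0 = band/background, k >= 1 = fibre id), `n_fibers`,
#'   `seed` and `boundary_width`.
#' @export
generate_layout <- function(n_fibers, height, width, boundary_width = 3,
                            seed = 1) {
  stopifnot(n_fibers >= 1, boundary_width >= 1, height >= 8, width >= 8)
  min_area <- (2 * boundary_width + 4)^2
  if (n_fibers * min_area > height * width)
    stop(sprintf(
      "cannot pack %d fibres into a %dx%d image with boundary width %g",
      n_fibers, height, width, boundary_width), call. = FALSE)
  margin <- ceiling(boundary_width / 2)
  with_seed(seed, {
    sy <- runif(n_fibers, margin + 2, height - margin - 1)
    sx <- runif(n_fibers, margin + 2, width - margin - 1)
    iy <- seq_len(height); ix <- seq_len(width)
    assign_nearest <- function(sy, sx) {
      d1 <- matrix(Inf, height, width); d2 <- d1
      id <- matrix(0L, height, width)
      for (k in seq_len(n_fibers)) {
        dk <- outer((iy - sy[k])^2, (ix - sx[k])^2, `+`)
        better1 <- dk < d1
        d2 <- ifelse(better1, d1, pmin(d2, dk))
        d1[better1] <- dk[better1]
        id[better1] <- k
      }
      list(d1 = d1, d2 = d2, id = id)
    }
    a <- assign_nearest(sy, sx)
    for (it in 1:2) {       # Lloyd relaxation
      idv <- as.vector(a$id)
      cy <- tapply(row(a$id), idv, mean)
      cx <- tapply(col(a$id), idv, mean)
      keep <- as.integer(names(cy))
      sy[keep] <- cy; sx[keep] <- cx
      a <- assign_nearest(sy, sx)
    }
    lab <- a$id
    band <- (sqrt(a$d2) - sqrt(a$d1)) < boundary_width
    lab[band] <- 0L
    lab[c(seq_len(margin), height - seq_len(margin) + 1L), ] <- 0L
    lab[, c(seq_len(margin), width - seq_len(margin) + 1L)] <- 0L
    # enforce 8-connectivity: keep the largest component of each fibre
    for (k in sort(unique(lab[lab > 0]))) {
      comp <- cpp_label8(matrix(as.integer(lab == k), height, width))
      if (max(comp) > 1) {
        sizes <- tabulate(comp[comp > 0])
        keep <- which.max(sizes)
        lab[comp > 0 & comp != keep] <- 0L
      }
    }
    ids <- sort(unique(lab[lab > 0]))
    relab <- integer(max(c(ids, 1L)))
    relab[ids] <- seq_along(ids)
    lab[lab > 0] <- relab[lab[lab > 0]]
    structure(list(label_image = lab, n_fibers = length(ids), seed = seed,
                   boundary_width = boundary_width),
              class = "fiber_layout")
  })
}

#' @export
print.fiber_layout <- function(x, ...) {
  cat(sprintf("<fiber_layout> %d x %d, %d fibres, boundary width %g, seed %d\n",
              nrow(x$label_image), ncol(x$label_image), x$n_fibers,
              x$boundary_width, x$seed))
  invisible(x)
}

#' Ground-truth mask and boundary map of a layout
#'
#' `layout_mask` returns the binary fibre mask (fibre interior = 1, band and
#' background = 0). `layout_boundary` returns the binary boundary map: the
#' label-0 band pixels lying within `boundary_width` pixels of a fibre. The
#' two maps are mutually exclusive per pixel by construction.
#'
#' @param layout a `fiber_layout`.
#' @return integer 0/1 matrix.
#' @export
layout_mask <- function(layout) {
  stopifnot(inherits(layout, "fiber_layout"))
  lab <- layout$label_image
  matrix(as.integer(lab > 0), nrow(lab), ncol(lab))
}

#' @rdname layout_mask
#' @export
layout_boundary <- function(layout) {
  stopifnot(inherits(layout, "fiber_layout"))
  mask <- layout_mask(layout)
  d <- sqrt(cpp_sqedt(mask))
  matrix(as.integer(mask == 0 & d <= max(2, layout$boundary_width)),
         nrow(mask), ncol(mask))
}

# Fill label-0 pixels with the label of a nearby fibre by iterative
# 8-neighbour dilation (deterministic neighbour priority). Pixels further
# than max_iter steps from any fibre keep label 0.
grow_labels <- function(lab, max_iter = 8) {
  H <- nrow(lab); W <- ncol(lab)
  shifts <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  for (it in seq_len(max_iter)) {
    if (!any(lab == 0)) break
    for (s in shifts) {
      src_r <- clamp(seq_len(H) + s[1], 1, H)
      src_c <- clamp(seq_len(W) + s[2], 1, W)
      nb <- lab[src_r, src_c, drop = FALSE]
      fill <- lab == 0 & nb > 0
      lab[fill] <- nb[fill]
    }
  }
  lab
}

#' Render an H&E-like image from a layout
#'
#' Paints fibre interiors with per-fibre jittered eosin-pink, the label-0
#' band with pale endomysium colour, adds sparse dark nuclei and Gaussian
#' texture noise, and "breaks" the boundary by recolouring a
#' `boundary_break_rate` fraction of boundary-band pixels with the colour of
#' the nearest fibre. Deterministic given `seed`.
#'
#' @param layout a `fiber_layout`.
#' @param params a [stain_params()] object.
#' @param seed integer seed.
#' @return numeric `H x W x 3` array in `[0, 1]`.
#' @export
render_image <- function(layout, params = stain_params(), seed = 1) {
  stopifnot(inherits(layout, "fiber_layout"), inherits(params, "stain_params"))
  lab <- layout$label_image
  H <- nrow(lab); W <- ncol(lab)
  K <- layout$n_fibers
  with_seed(seed, {
    bright <- 1 + runif(max(K, 1), -1, 1) * params$brightness_jitter
    shift <- matrix(runif(3 * max(K, 1), -1, 1) * params$hue_jitter, ncol = 3)
    cols <- matrix(0, max(K, 1), 3)
    for (k in seq_len(max(K, 1)))
      cols[k, ] <- clamp(params$fiber_color * bright[k] + shift[k, ], 0, 1)
    colmap <- rbind(params$boundary_color, cols)  # row 1 = label 0
    img <- array(0, c(H, W, 3))
    for (ch in 1:3) img[, , ch] <- matrix(colmap[lab + 1L, ch], H, W)
    # broken boundaries: recolour a fraction of band pixels as fibre interior
    bnd <- layout_boundary(layout)
    bidx <- which(bnd == 1)
    if (length(bidx) > 0 && params$boundary_break_rate > 0) {
      broken <- bidx[runif(length(bidx)) < params$boundary_break_rate]
      if (length(broken) > 0) {
        owner <- grow_labels(lab)
        ok <- pmax(owner[broken], 1L)
        for (ch in 1:3) {
          pl <- img[, , ch]
          pl[broken] <- cols[ok, ch]
          img[, , ch] <- pl
        }
      }
    }
    # nuclei: small dark discs, biased to the boundary neighbourhood
    n_nuc <- rpois(1, params$nuclei_density * H * W)
    if (n_nuc > 0) {
      cand <- which(sqrt(cpp_sqedt(matrix(as.integer(lab == 0), H, W))) <= 3)
      if (length(cand) > 0) {
        ctr <- sample(cand, min(n_nuc, length(cand)))
        ci <- (ctr - 1) %% H + 1; cj <- (ctr - 1) %/% H + 1
        for (t in seq_along(ctr)) {
          ri <- clamp((ci[t] - 1):(ci[t] + 1), 1, H)
          rj <- clamp((cj[t] - 1):(cj[t] + 1), 1, W)
          for (ch in 1:3) img[ri, rj, ch] <- params$nuclei_color[ch]
        }
      }
    }
    if (params$texture_noise > 0)
      img <- img + array(rnorm(length(img), 0, params$texture_noise), dim(img))
    clamp(img, 0, 1)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` image/mask/boundary triples plus a TSV manifest with a
#' train/test split. Image side lengths are drawn uniformly from
#' `size_range` (the defaults match typical muscle-biopsy patch sizes of
#' 500 to 1500 pixels); the fibre count per image is set from a per-image
#' characteristic fibre diameter drawn from `fiber_diameter_range`.
#' Deterministic given `seed`: a rerun with identical arguments reproduces
#' every file byte for byte.
#'
#' @param n_images number of images.
#' @param size_range integer range of side lengths in pixels.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param split_ratio fraction of images assigned to the training split.
#' @param boundary_width separating band width in pixels.
#' @param fiber_diameter_range range of characteristic fibre diameters (px).
#' @param params a [stain_params()] object.
#' @return the manifest data frame (paths relative to `out_dir`), invisibly;
#'   the manifest is also written to `out_dir/manifest.tsv`.
#' @export
make_dataset <- function(n_images, size_range = c(500, 1500), out_dir,
                         seed = 1, split_ratio = 0.8, boundary_width = 3,
                         fiber_diameter_range = c(30, 80),
                         params = stain_params()) {
  stopifnot(n_images >= 1, length(size_range) == 2)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n_train <- round(n_images * split_ratio)
  with_seed(seed, {
    sub_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_images)
    hh <- round(runif(n_images, size_range[1], size_range[2]))
    ww <- round(runif(n_images, size_range[1], size_range[2]))
    dd <- runif(n_images, fiber_diameter_range[1], fiber_diameter_range[2])
    rows <- vector("list", n_images)
    for (i in seq_len(n_images)) {
      n_fib <- max(1, round(hh[i] * ww[i] / dd[i]^2))
      layout <- generate_layout(n_fib, hh[i], ww[i], boundary_width,
                                seed = sub_seeds[2 * i - 1])
      img <- render_image(layout, params, seed = sub_seeds[2 * i])
      fi <- sprintf("img_%04d.png", i)
      fm <- sprintf("mask_%04d.png", i)
      fb <- sprintf("boundary_%04d.png", i)
      write_image(img, file.path(out_dir, fi))
      write_mask(layout_mask(layout), file.path(out_dir, fm))
      write_mask(layout_boundary(layout), file.path(out_dir, fb))
      rows[[i]] <- data.frame(
        path_image = fi, path_mask = fm, path_boundary = fb,
        split = if (i <= n_train) "train" else "test",
        stringsAsFactors = FALSE)
    }
    manifest <- do.call(rbind, rows)
    write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
    invisible(manifest)
  })
}
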