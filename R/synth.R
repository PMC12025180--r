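# Synthetic OCTA-like data: star-convex FAZ shapes with radial-harmonic
# irregularity, branching random-walk vessel trees, speckle noise,
# dual-annotator masks with systematic bias and boundary jitter, and a
# photocoagulation-style fundus pretraining set. Emulates the structure of a
# clinical multi-condition cohort (imbalanced per-condition counts, 1-2 eyes
# per patient) so the whole pipeline is exercisable without clinical data.

#' Condition profile
#'
#' Morphology and cohort parameters of one disease condition. Disease is
#' expressed as FAZ enlargement (`faz_radius_mean`), boundary irregularity
#' (amplitude of radial harmonics) and reduced capillary density.
#'
#' @param name condition label.
#' @param faz_radius_mean,faz_radius_sd FAZ radius distribution in pixels.
#' @param irregularity in `[0, 1]`: relative amplitude of radial harmonics.
#' @param vessel_density in `(0, 1]`: density of the vessel texture.
#' @param n_eyes number of eyes sampled for this condition.
#' @return an object of class `faz_condition_profile`.
#' @export
condition_profile <- function(name, faz_radius_mean, faz_radius_sd = 0,
                              irregularity = 0, vessel_density = 0.8,
                              n_eyes = 1L) {
  if (faz_radius_mean <= 0) stop("faz_radius_mean must be > 0")
  if (irregularity < 0 || irregularity > 1) stop("irregularity must be in [0, 1]")
  if (vessel_density <= 0 || vessel_density > 1) stop("vessel_density must be in (0, 1]")
  if (n_eyes < 1) stop("n_eyes must be >= 1")
  structure(list(name = name, faz_radius_mean = faz_radius_mean,
                 faz_radius_sd = faz_radius_sd, irregularity = irregularity,
                 vessel_density = vessel_density, n_eyes = as.integer(n_eyes)),
            class = "faz_condition_profile")
}

#' Annotator model
#'
#' A synthetic human annotator: a signed systematic dilation/erosion bias
#' plus smooth Gaussian jitter of the mask boundary.
#'
#' @param dilation_bias signed pixels (positive dilates).
#' @param boundary_jitter_sd standard deviation of boundary displacement in
#'   pixels (must be `>= 0`).
#' @param seed annotator-specific seed component.
#' @return an object of class `faz_annotator_model`.
#' @export
annotator_model <- function(dilation_bias = 0, boundary_jitter_sd = 0, seed = 0L) {
  if (boundary_jitter_sd < 0) stop("boundary_jitter_sd must be >= 0")
  structure(list(dilation_bias = dilation_bias,
                 boundary_jitter_sd = boundary_jitter_sd, seed = as.integer(seed)),
            class = "faz_annotator_model")
}

#' Default condition profiles
#'
#' Four conditions mirroring the structure of a multi-condition OCTA cohort:
#' healthy aging eyes plus Alzheimer's disease (ALZ), age-related macular
#' degeneration (AMD) and diabetic retinopathy (DR), with eye counts
#' 17/33/31/21 (102 in total). Disease progressively enlarges the FAZ,
#' roughens its boundary and thins the vasculature; the parameter values are
#' illustrative, not calibrated to any cohort.
#'
#' @param image_size image side in pixels (radii scale with it).
#' @return list of [condition_profile()] objects.
#' @export
default_condition_profiles <- function(image_size = 64L) {
  s <- image_size
  list(
    condition_profile("Healthy", 0.140 * s, 0.015 * s, irregularity = 0.08,
                      vessel_density = 0.90, n_eyes = 17L),
    condition_profile("ALZ", 0.155 * s, 0.018 * s, irregularity = 0.18,
                      vessel_density = 0.75, n_eyes = 33L),
    condition_profile("AMD", 0.165 * s, 0.020 * s, irregularity = 0.30,
                      vessel_density = 0.65, n_eyes = 31L),
    condition_profile("DR", 0.185 * s, 0.022 * s, irregularity = 0.45,
                      vessel_density = 0.55, n_eyes = 21L)
  )
}

#' Synthetic dataset specification
#'
#' @param image_size square image side in pixels (>= 32).
#' @param profiles list of [condition_profile()]s (>= 1).
#' @param annotators list of [annotator_model()]s.
#' @param noise_sd additive Gaussian speckle standard deviation (gray levels
#'   in `[0, 1]`).
#' @param seed master seed; every sample derives its own stream from it.
#' @return an object of class `faz_synth_spec`.
#' @export
synth_dataset_spec <- function(image_size = 64L,
                               profiles = default_condition_profiles(image_size),
                               annotators = list(
                                 annotator_model(0, 0.5, seed = 1L),
                                 annotator_model(1, 1.0, seed = 2L)
                               ),
                               noise_sd = 0.05, seed = 0L) {
  if (image_size < 32) stop("image_size must be >= 32")
  if (length(profiles) < 1) stop("at least one condition profile is required")
  structure(list(image_size = as.integer(image_size), profiles = profiles,
                 annotators = annotators, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "faz_synth_spec")
}

#' Generate a star-convex FAZ shape
#'
#' The FAZ boundary is a radial-harmonic curve `r(theta) = max(1, R + sum_k
#' A_k cos(k theta + phi_k))` with `R ~ Normal(faz_radius_mean,
#' faz_radius_sd)` and harmonic amplitudes scaled by the profile's
#' irregularity, rasterized about a point near the image center. With zero
#' irregularity the region is a disk; increasing irregularity lowers its
#' circularity, as seen in diseased eyes.
#'
#' @param profile a [condition_profile()].
#' @param image_size image side in pixels.
#' @param rng_seed integer seed.
#' @return binary `image_size x image_size` matrix (values 0/1), a single
#'   connected star-convex region. If the sampled radius is degenerate
#'   (`<= 0`) it is clamped to 1 pixel with a warning.
#' @export
make_faz_shape <- function(profile, image_size, rng_seed) {
  stopifnot(inherits(profile, "faz_condition_profile"))
  with_seed(derive_seed(rng_seed, "shape"), {
    R <- stats::rnorm(1, profile$faz_radius_mean, profile$faz_radius_sd)
    if (R <= 0) {
      warning("sampled FAZ radius <= 0; clamped to 1 pixel")
      R <- 1
    }
    ks <- 2:5
    amps <- profile$irregularity * R * stats::runif(length(ks), 0.08, 0.22)
    phis <- stats::runif(length(ks), 0, 2 * pi)
    cx <- image_size / 2 + 0.5 + stats::runif(1, -0.04, 0.04) * image_size
    cy <- image_size / 2 + 0.5 + stats::runif(1, -0.04, 0.04) * image_size
    xs <- matrix(rep(seq_len(image_size), each = image_size), image_size) - cx
    ys <- matrix(rep(seq_len(image_size), times = image_size), image_size) - cy
    th <- atan2(ys, xs)
    rr <- sqrt(xs^2 + ys^2)
    rb <- R
    for (i in seq_along(ks)) rb <- rb + amps[i] * cos(ks[i] * th + phis[i])
    rb <- pmax(rb, 1)
    mask <- (rr <= rb) * 1
    storage.mode(mask) <- "double"
    mask
  })
}

#' Render a vessel-texture OCTA image around a FAZ
#'
#' Bright branching curvilinear structures (recursive biased random walks
#' started at the image border) over a dark background, blurred lightly;
#' intensity inside the FAZ mask is suppressed to background level, so the
#' capillary-free zone is visibly darker than its surround.
#'
#' @param faz_mask binary mask from [make_faz_shape()].
#' @param vessel_density in `(0, 1]`; scales the number of vessel walks.
#' @param rng_seed integer seed.
#' @return grayscale matrix in `[0, 1]`.
#' @export
render_vessels <- function(faz_mask, vessel_density, rng_seed) {
  if (vessel_density <= 0) stop("vessel_density must be > 0")
  n <- nrow(faz_mask)
  with_seed(derive_seed(rng_seed, "vessels"), {
    canvas <- matrix(0, n, n)
    n_walks <- max(3L, round(26 * vessel_density))
    cx <- n / 2; cy <- n / 2
    stack <- list()
    for (i in seq_len(n_walks)) {
      side <- sample.int(4L, 1L)
      pos <- switch(side,
                    c(1, stats::runif(1, 1, n)),
                    c(n, stats::runif(1, 1, n)),
                    c(stats::runif(1, 1, n), 1),
                    c(stats::runif(1, 1, n), n))
      stack[[length(stack) + 1L]] <- list(pos = pos, dir = atan2(cy - pos[2], cx - pos[1]),
                                          len = round(stats::runif(1, 0.5, 1.1) * n), depth = 0L)
    }
    while (length(stack) > 0L) {
      wk <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      pos <- wk$pos; dir <- wk$dir
      for (step in seq_len(wk$len)) {
        dir <- dir + stats::rnorm(1, 0, 0.25)
        # gentle pull toward the fovea keeps trees converging like the
        # perifoveal capillary network
        pull <- atan2(cy - pos[2], cx - pos[1])
        d <- ((pull - dir + pi) %% (2 * pi)) - pi
        dir <- dir + 0.08 * d
        pos <- pos + c(cos(dir), sin(dir))
        ix <- round(pos[1]); iy <- round(pos[2])
        if (ix < 1 || ix > n || iy < 1 || iy > n) break
        canvas[iy, ix] <- 1
        if (wk$depth < 3L && stats::runif(1) < 0.02 * vessel_density * 2) {
          stack[[length(stack) + 1L]] <- list(
            pos = pos, dir = dir + sample(c(-1, 1), 1) * stats::runif(1, 0.4, 1.1),
            len = round(wk$len * 0.5), depth = wk$depth + 1L)
        }
      }
    }
    img <- as.matrix(EBImage::gblur(EBImage::as.Image(canvas), sigma = 0.6))
    img <- 0.12 + 0.95 * img / max(max(img), 1e-8)
    img[faz_mask > 0] <- 0.12
    pmin(pmax(img, 0), 1)
  })
}

#' Apply a synthetic annotator to a mask
#'
#' Applies the annotator's signed morphological bias (disc dilation or
#' erosion of `|dilation_bias|` pixels) followed by smooth Gaussian boundary
#' jitter, implemented by thresholding the signed distance transform at a
#' spatially smooth random field whose pointwise standard deviation is
#' `boundary_jitter_sd` pixels.
#'
#' @param mask non-empty binary mask.
#' @param annotator an [annotator_model()].
#' @param rng_seed integer seed combined with the annotator's own seed.
#' @return binary mask of the same size. If the perturbation empties the
#'   mask, a 1-pixel mask at the original centroid is returned with a
#'   warning.
#' @export
annotate <- function(mask, annotator, rng_seed = 0L) {
  stopifnot(inherits(annotator, "faz_annotator_model"))
  if (sum(mask) == 0) stop("annotate() requires a non-empty mask")
  out <- mask
  d <- round(annotator$dilation_bias)
  if (d != 0) {
    brush <- EBImage::makeBrush(2L * abs(d) + 1L, shape = "disc")
    img <- EBImage::as.Image(out)
    out <- as.matrix(if (d > 0) EBImage::dilate(img, brush) else EBImage::erode(img, brush))
  }
  if (annotator$boundary_jitter_sd > 0) {
    sd_in <- as.matrix(EBImage::distmap(EBImage::as.Image(out)))
    sd_out <- as.matrix(EBImage::distmap(EBImage::as.Image(1 - out)))
    signed <- sd_in - sd_out
    field <- with_seed(derive_seed(rng_seed, "annot", annotator$seed), {
      raw <- matrix(stats::rnorm(length(mask)), nrow(mask))
      sm <- as.matrix(EBImage::gblur(EBImage::as.Image(raw), sigma = 3))
      sm / stats::sd(sm)
    })
    out <- (signed > field * annotator$boundary_jitter_sd) * 1
  }
  if (sum(out) == 0) {
    warning("annotation emptied the mask; returning a 1-pixel mask at the centroid")
    ij <- round(c(mean(which(mask > 0, arr.ind = TRUE)[, 1]),
                  mean(which(mask > 0, arr.ind = TRUE)[, 2])))
    out <- mask * 0
    out[ij[1], ij[2]] <- 1
  }
  storage.mode(out) <- "double"
  out
}

#' Circularity of a binary region
#'
#' `4 * pi * Area / Perimeter^2` (1 for a perfect disk). The perimeter is
#' estimated from the traced 8-connected boundary chain with
#' Vossepoel-Smeulders corner-corrected step weights, which removes the
#' systematic upward bias of naive boundary-pixel counting on digital
#' circles.
#'
#' @param mask binary matrix with a single region.
#' @return scalar circularity.
#' @export
mask_circularity <- function(mask) {
  area <- sum(mask > 0)
  oc <- EBImage::ocontour(EBImage::as.Image(mask))[[1]]
  st <- rbind(diff(oc), oc[1, ] - oc[nrow(oc), ])
  axial <- sum(abs(st[, 1]) + abs(st[, 2]) == 1)
  diag <- sum(abs(st[, 1]) == 1 & abs(st[, 2]) == 1)
  ang <- atan2(st[, 2], st[, 1])
  turns <- sum(abs(((diff(c(ang, ang[1])) + pi) %% (2 * pi)) - pi) > 1e-9)
  per <- 0.980 * axial + 1.406 * diag - 0.091 * turns
  4 * pi * area / per^2
}

synth_sample <- function(spec, profile, sample_seed) {
  gt <- make_faz_shape(profile, spec$image_size, sample_seed)
  img <- render_vessels(gt, profile$vessel_density, sample_seed)
  if (spec$noise_sd > 0) {
    img <- with_seed(derive_seed(sample_seed, "noise"), {
      pmin(pmax(img + stats::rnorm(length(img), 0, spec$noise_sd), 0), 1)
    })
    img <- matrix(img, spec$image_size)
  }
  masks <- lapply(spec$annotators, function(a) annotate(gt, a, sample_seed))
  list(image = img, gt = gt, masks = masks)
}

#' Generate a synthetic multi-condition FAZ dataset
#'
#' One sample per eye and condition profile; synthetic patients own 1-2 eyes
#' so cross-validation can split at patient level without leakage. With
#' `out_dir = NULL` the dataset is returned in memory; otherwise 8-bit
#' grayscale PNG images, one `{0, 255}` PNG mask per annotator, and a
#' tab-separated manifest are written and the manifest is returned.
#'
#' @param spec a [synth_dataset_spec()].
#' @param out_dir output directory or `NULL`.
#' @return a list with `manifest` (data.frame with columns `sample_id`,
#'   `image_path`, `mask_paths`, `condition`, `patient_id`, `eye`,
#'   `annotator_ids`, `split`) and, in memory mode, `images`, `masks` and
#'   `gt` lists indexed like the manifest rows.
#' @export
generate_dataset <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "faz_synth_spec"))
  write_files <- !is.null(out_dir)
  if (write_files) {
    dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  }
  rows <- list()
  images <- list()
  masks <- list()
  gts <- list()
  pid <- 0L
  for (profile in spec$profiles) {
    # assign eyes to synthetic patients, 1-2 eyes each
    eyes_left <- profile$n_eyes
    assignment <- with_seed(derive_seed(spec$seed, "patients", profile$name), {
      out <- integer(0)
      while (sum(out) < eyes_left) {
        out <- c(out, if (eyes_left - sum(out) == 1L) 1L else sample(1:2, 1))
      }
      out
    })
    eye_i <- 0L
    for (k in seq_along(assignment)) {
      pid <- pid + 1L
      for (e in seq_len(assignment[k])) {
        eye_i <- eye_i + 1L
        sid <- sprintf("%s_%03d", profile$name, eye_i)
        sample_seed <- derive_seed(spec$seed, "sample", profile$name, eye_i)
        smp <- synth_sample(spec, profile, sample_seed)
        idx <- length(rows) + 1L
        ann_ids <- vapply(seq_along(spec$annotators), function(a) paste0("A", a), character(1))
        if (write_files) {
          ipath <- file.path("images", paste0(sid, ".png"))
          mpaths <- vapply(seq_along(smp$masks), function(a) {
            file.path("masks", sprintf("%s_A%d.png", sid, a))
          }, character(1))
          write_image(smp$image, file.path(out_dir, ipath))
          for (a in seq_along(smp$masks)) write_mask(smp$masks[[a]], file.path(out_dir, mpaths[a]))
        } else {
          ipath <- sid
          mpaths <- paste0(sid, "_", ann_ids)
          images[[idx]] <- smp$image
          masks[[idx]] <- smp$masks
          gts[[idx]] <- smp$gt
        }
        rows[[idx]] <- data.frame(
          sample_id = sid, image_path = ipath,
          mask_paths = paste(mpaths, collapse = ";"),
          condition = profile$name, patient_id = sprintf("P%03d", pid),
          eye = if (e == 1L) "OD" else "OS",
          annotator_ids = paste(ann_ids, collapse = ";"), split = "",
          stringsAsFactors = FALSE)
      }
    }
  }
  manifest <- do.call(rbind, rows)
  if (write_files) {
    write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
    list(manifest = manifest, dir = out_dir)
  } else {
    list(manifest = manifest, images = images, masks = masks, gt = gts)
  }
}

#' Generate a photocoagulation-style pretraining set
#'
#' Fundus-like single-channel images (smooth radial gradient plus vessel
#' texture) carrying 1-30 bright elliptical lesion blobs per image, with the
#' blob union as mask; emulates a laser-photocoagulation treatment-region
#' segmentation dataset of 298 images.
#'
#' @param n_images number of image/mask pairs (default 298).
#' @param spec a [synth_dataset_spec()] (provides image size, noise, seed).
#' @param out_dir output directory or `NULL` for in-memory.
#' @param force_blob_count optional fixed blob count (0 allowed; all-zero
#'   masks are flagged in the manifest column `empty_mask`).
#' @return list with `manifest` and, in memory mode, `images` and `masks`.
#' @export
generate_pc_set <- function(n_images = 298L, spec = synth_dataset_spec(),
                            out_dir = NULL, force_blob_count = NULL) {
  if (n_images < 1) stop("n_images must be >= 1")
  n <- spec$image_size
  write_files <- !is.null(out_dir)
  if (write_files) {
    dir.create(file.path(out_dir, "pc_images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "pc_masks"), recursive = TRUE, showWarnings = FALSE)
  }
  rows <- list()
  images <- list()
  masks <- list()
  xs <- matrix(rep(seq_len(n), each = n), n) / n - 0.5
  ys <- matrix(rep(seq_len(n), times = n), n) / n - 0.5
  for (i in seq_len(n_images)) {
    seed_i <- derive_seed(spec$seed, "pc", i)
    out <- with_seed(seed_i, {
      bg <- 0.45 - 0.5 * (xs^2 + ys^2) + 0.05 * xs
      tex <- render_vessels(matrix(0, n, n), 0.4, derive_seed(seed_i, "tex"))
      img <- pmin(pmax(bg + 0.25 * (tex - 0.12), 0), 1)
      nb <- if (!is.null(force_blob_count)) force_blob_count else sample.int(30L, 1L)
      mask <- matrix(0, n, n)
      if (nb > 0) {
        for (b in seq_len(nb)) {
          ccx <- stats::runif(1, 0.12 * n, 0.88 * n)
          ccy <- stats::runif(1, 0.12 * n, 0.88 * n)
          a <- stats::runif(1, 0.015 * n, 0.05 * n)
          bb <- a * stats::runif(1, 0.6, 1.4)
          phi <- stats::runif(1, 0, pi)
          u <- (col(mask) - ccx) * cos(phi) + (row(mask) - ccy) * sin(phi)
          v <- -(col(mask) - ccx) * sin(phi) + (row(mask) - ccy) * cos(phi)
          mask[(u / a)^2 + (v / bb)^2 <= 1] <- 1
        }
      }
      img[mask > 0] <- pmax(img[mask > 0], 0.82)
      if (spec$noise_sd > 0) {
        img <- pmin(pmax(img + stats::rnorm(length(img), 0, spec$noise_sd), 0), 1)
        img <- matrix(img, n)
      }
      list(img = img, mask = mask, nb = nb)
    })
    sid <- sprintf("PC_%03d", i)
    if (write_files) {
      ipath <- file.path("pc_images", paste0(sid, ".png"))
      mpath <- file.path("pc_masks", paste0(sid, ".png"))
      write_image(out$img, file.path(out_dir, ipath))
      write_mask(out$mask, file.path(out_dir, mpath))
    } else {
      ipath <- sid
      mpath <- sid
      images[[i]] <- out$img
      masks[[i]] <- out$mask
    }
    rows[[i]] <- data.frame(sample_id = sid, image_path = ipath, mask_paths = mpath,
                            condition = "PC", patient_id = sid, eye = "NA",
                            annotator_ids = "A1", split = "",
                            empty_mask = out$nb == 0, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  if (write_files) {
    write_manifest(manifest, file.path(out_dir, "pc_manifest.tsv"))
    list(manifest = manifest, dir = out_dir)
  } else {
    list(manifest = manifest, images = images, masks = masks)
  }
}
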