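# Synthetic OCTA generator: FAZ morphology, vessel rendering, annotator
# models, dataset assembly, and the photocoagulation pretraining set.

test_that("a zero-irregularity shape is a disk and generation is deterministic", {
  pr <- condition_profile("t", faz_radius_mean = 20, faz_radius_sd = 0,
                          irregularity = 0, vessel_density = 0.8)
  m <- make_faz_shape(pr, 64, rng_seed = 1)
  expect_setequal(unique(as.numeric(m)), c(0, 1))
  expect_equal(sum(m), pi * 400, tolerance = 0.02)
  expect_gte(mask_circularity(m), 0.95)
  expect_identical(m, make_faz_shape(pr, 64, rng_seed = 1))
  expect_false(identical(m, make_faz_shape(pr, 64, rng_seed = 2)))
})

test_that("irregularity strictly lowers mean circularity", {
  pr0 <- condition_profile("t", 20, 0, irregularity = 0, vessel_density = 0.8)
  pr5 <- condition_profile("t", 20, 0, irregularity = 0.5, vessel_density = 0.8)
  c0 <- mean(vapply(1:40, function(s) mask_circularity(make_faz_shape(pr0, 64, s)),
                    numeric(1)))
  c5 <- mean(vapply(1:40, function(s) mask_circularity(make_faz_shape(pr5, 64, s)),
                    numeric(1)))
  expect_lt(c5, c0)
})

test_that("degenerate sampled radius is clamped with a warning", {
  pr <- condition_profile("t", 1e-3, 0, 0, 0.8)
  pr$faz_radius_mean <- -5  # force a negative draw past construction checks
  expect_warning(m <- make_faz_shape(pr, 32, 1), "clamped")
  expect_gte(sum(m), 1)
})

test_that("vessel rendering is darker inside the FAZ and denser with density", {
  pr <- condition_profile("t", 9, 0, 0, 0.8)
  mk <- make_faz_shape(pr, 64, 3)
  v <- render_vessels(mk, 0.8, 3)
  expect_true(all(v >= 0 & v <= 1))
  expect_lt(mean(v[mk > 0]), mean(v[mk == 0]))
  v1 <- render_vessels(mk, 1.0, 3)
  v2 <- render_vessels(mk, 0.2, 3)
  expect_gt(mean(v1 > 0.5), mean(v2 > 0.5))
  expect_error(render_vessels(mk, 0, 3), "vessel_density")
})

test_that("annotator model applies bias and jitter as specified", {
  pr <- condition_profile("t", 20, 0, 0, 0.8)
  m <- make_faz_shape(pr, 64, 1)
  ident <- annotate(m, annotator_model(0, 0), 1)
  expect_identical(ident, m)

  dil <- annotate(m, annotator_model(2, 0), 1)
  expect_gt(sum(dil), sum(m))
  # Dice against the original equals the two-disk formula up to rasterization
  expect_equal(2 * sum(m * dil) / (sum(m) + sum(dil)),
               2 * pi * 20^2 / (pi * 20^2 + pi * 22^2), tolerance = 0.02)

  jit <- annotate(m, annotator_model(0, 1.5), 1)
  expect_lt(dice_index(jit, m), 1)
  expect_setequal(unique(as.numeric(jit)), c(0, 1))

  # erosion that wipes out a tiny mask returns a single-pixel centroid mask
  tiny <- matrix(0, 32, 32); tiny[16, 16] <- 1
  expect_warning(res <- annotate(tiny, annotator_model(-3, 0), 1), "1-pixel")
  expect_equal(sum(res), 1)
  expect_error(annotate(matrix(0, 8, 8), annotator_model(0, 0)), "non-empty")
})

test_that("the default cohort has 102 eyes with the configured imbalance", {
  ds <- memo("default_102", function() {
    generate_dataset(synth_dataset_spec(image_size = 64, seed = 0))
  })
  man <- ds$manifest
  expect_equal(nrow(man), 102L)
  expect_equal(as.numeric(table(man$condition)[c("Healthy", "ALZ", "AMD", "DR")]),
               c(17, 33, 31, 21))
  # patients own 1-2 eyes
  expect_true(all(table(man$patient_id) %in% 1:2))
  # two annotators, two masks each, binary, image-sized
  expect_true(all(lengths(ds$masks) == 2L))
  expect_true(all(vapply(ds$masks, function(mm) {
    all(vapply(mm, function(m) all(m %in% c(0, 1)) && all(dim(m) == 64L), logical(1)))
  }, logical(1))))
  # mean FAZ area ranks follow the configured radius ranks
  areas <- tapply(vapply(ds$gt, sum, numeric(1)), man$condition, mean)
  expect_true(areas["Healthy"] < areas["ALZ"] &&
                areas["ALZ"] < areas["AMD"] && areas["AMD"] < areas["DR"])
})

test_that("written datasets are byte-reproducible from the seed", {
  spec <- synth_dataset_spec(
    image_size = 32,
    profiles = list(condition_profile("Healthy", 4.5, 0.4, 0.1, 0.9, n_eyes = 3L),
                    condition_profile("DR", 6, 0.5, 0.4, 0.6, n_eyes = 2L)),
    seed = 42)
  d1 <- file.path(tempdir(), "synth_a")
  d2 <- file.path(tempdir(), "synth_b")
  unlink(c(d1, d2), recursive = TRUE)
  generate_dataset(spec, out_dir = d1)
  generate_dataset(spec, out_dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  # every manifest path resolves; 2 annotators -> 2 mask files per image
  man <- read_manifest(file.path(d1, "manifest.tsv"))
  expect_true(all(file.exists(file.path(d1, man$image_path))))
  mask_files <- strsplit(man$mask_paths, ";")
  expect_true(all(lengths(mask_files) == 2L))
  expect_true(all(file.exists(file.path(d1, unlist(mask_files)))))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the photocoagulation set has bright lesions over the background", {
  spec <- synth_dataset_spec(image_size = 48, seed = 2)
  pc <- generate_pc_set(12, spec)
  expect_equal(nrow(pc$manifest), 12L)
  for (i in seq_len(12)) {
    img <- pc$images[[i]]
    msk <- pc$masks[[i]]
    expect_true(all(msk %in% c(0, 1)))
    if (sum(msk) > 0) {
      expect_true(all(img[msk > 0] > stats::median(img[msk == 0])))
    }
  }
  # forced zero blob count is allowed and flagged
  pc0 <- generate_pc_set(2, spec, force_blob_count = 0)
  expect_true(all(vapply(pc0$masks, sum, numeric(1)) == 0))
  expect_true(all(pc0$manifest$empty_mask))
  expect_error(generate_pc_set(0, spec), "n_images")
})

test_that("the default photocoagulation set size is 298", {
  expect_equal(eval(formals(generate_pc_set)$n_images), 298L)
  # generating the full default set stays cheap enough to verify directly
  spec <- synth_dataset_spec(image_size = 32, seed = 3)
  pc <- generate_pc_set(spec = spec)
  expect_equal(nrow(pc$manifest), 298L)
})
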