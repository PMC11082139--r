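# Synthetic fundus-like image generator with controllable subgroup structure.
#
# The generator emulates the attribute structure of a large diabetic
# retinopathy screening dataset: categorical patient/image attributes with
# realistic marginal prevalences, and image appearance that depends on those
# attributes with configurable effect amplitudes. An extra "insufficient"
# image-quality class is reserved for an out-of-distribution pool that is
# never sampled into the source distribution.

SEX_LEVELS <- c("female", "male", "other")
ETHNICITY_LEVELS <- c("african", "asian", "white", "indian",
                      "latin_american", "multiracial", "native_american")
QUALITY_LEVELS <- c("insufficient", "adequate", "good", "excellent")

#' Default attribute marginals
#'
#' Marginal prevalences of the categorical attributes in the emulated
#' screening population: patient sex roughly 60/40 female/male with a small
#' "other" group, a predominantly Latin-American ethnicity mix, image quality
#' split over adequate/good/excellent, a 10% co-morbidity prevalence, and a
#' heavily imbalanced retinopathy grade distribution with 79% healthy
#' (grade 0) images. The "insufficient" quality level carries probability 0
#' here; it exists only in the out-of-distribution pool.
#'
#' @return Named list of named probability vectors, one per attribute.
#' @export
default_marginals <- function() {
  norm <- function(x) x / sum(x)
  list(
    sex = norm(c(female = 0.597, male = 0.400, other = 0.003)),
    ethnicity = norm(c(african = 8, asian = 6, white = 11, indian = 5,
                       latin_american = 69, multiracial = 1,
                       native_american = 1)),
    quality = norm(c(adequate = 40, good = 41, excellent = 18)),
    comorbidity = c("FALSE" = 0.9, "TRUE" = 0.1),
    dr_grade = norm(c("0" = 79, "1" = 7, "2" = 13, "3" = 1, "4" = 1))
  )
}

#' Generator specification for synthetic fundus images
#'
#' Bundles everything that defines the synthetic image distribution: image
#' size, attribute marginals, how strongly each attribute alters the rendered
#' image, the lesion model linking retinopathy grade to lesion count/size/
#' contrast, the blur level associated with each image-quality grade, and the
#' additive sensor-noise scale.
#'
#' Effect amplitudes are nonnegative scalars per attribute. The sex amplitude
#' defaults to a small value: the corresponding appearance difference is not
#' visible by eye but remains statistically detectable with enough data,
#' mirroring the regime reported for real fundus images.
#'
#' @param image_size Pixels per side (square images), default 64.
#' @param marginals Named list of attribute probability tables; see
#'   [default_marginals()].
#' @param effect_amplitudes Named nonnegative numerics for `sex`,
#'   `ethnicity`, `comorbidity`, `quality` (scales the blur mapping and the
#'   extra degradation of insufficient-quality images) and `dr_grade`
#'   (scales lesion contrast). Setting every amplitude to 0 with
#'   `noise_sd = 0` yields an attribute-independent renderer.
#' @param lesion_model List with `count_per_grade`, `radius` (fraction of the
#'   half-width), `contrast`.
#' @param quality_blur Named numeric: Gaussian blur sd in pixels (at 64 px
#'   reference scale) per quality level. `insufficient` must be strictly above
#'   every in-distribution level.
#' @param noise_sd Additive Gaussian noise sd on pixel values in \[0,1\].
#' @param seed Integer seed used by [generate_dataset()].
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(image_size = 64,
                           marginals = default_marginals(),
                           effect_amplitudes = c(sex = 0.003,
                                                 ethnicity = 0.08,
                                                 comorbidity = 0.25,
                                                 quality = 1.0,
                                                 dr_grade = 1.0),
                           lesion_model = list(count_per_grade = 4,
                                               radius = 0.055,
                                               contrast = 0.40),
                           quality_blur = c(excellent = 0, good = 0.4,
                                            adequate = 0.9,
                                            insufficient = 2.8),
                           noise_sd = 0.02,
                           seed = 1L) {
  stopifnot(image_size >= 8, image_size %% 8 == 0)
  required <- c("sex", "ethnicity", "quality", "comorbidity", "dr_grade")
  for (a in required) {
    p <- marginals[[a]]
    if (is.null(p) || any(!is.finite(p)) || any(p < 0) || sum(p) <= 0) {
      stop("invalid marginals for attribute '", a, "'", call. = FALSE)
    }
    marginals[[a]] <- p / sum(p)
  }
  amp <- c(sex = 0.003, ethnicity = 0.08, comorbidity = 0.25,
           quality = 1.0, dr_grade = 1.0)
  unknown <- setdiff(names(effect_amplitudes), names(amp))
  if (length(unknown) > 0) {
    stop("unknown effect amplitude(s): ", paste(unknown, collapse = ", "))
  }
  amp[names(effect_amplitudes)] <- effect_amplitudes
  effect_amplitudes <- amp
  if (any(effect_amplitudes < 0)) stop("effect amplitudes must be >= 0")
  if ("insufficient" %in% names(marginals$quality) &&
      marginals$quality[["insufficient"]] > 0) {
    stop("invalid marginals for attribute 'quality': the insufficient level ",
         "belongs to the OOD pool and cannot appear in-distribution")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (quality_blur[["insufficient"]] <=
      max(quality_blur[c("adequate", "good", "excellent")])) {
    stop("insufficient-quality blur must exceed all in-distribution levels")
  }
  structure(list(image_size = as.integer(image_size),
                 marginals = marginals,
                 effect_amplitudes = effect_amplitudes,
                 lesion_model = lesion_model,
                 quality_blur = quality_blur,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "generator_spec")
}

#' @export
print.generator_spec <- function(x, ...) {
  cat("Synthetic fundus generator spec\n")
  cat("  image size:", x$image_size, "x", x$image_size, "\n")
  cat("  noise sd:  ", x$noise_sd, "\n")
  cat("  amplitudes:",
      paste(names(x$effect_amplitudes), signif(x$effect_amplitudes, 3),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Sample attribute records from the configured marginals
#'
#' Attributes are drawn independently per record from the marginal tables in
#' `spec`. For `fold = "ood"`, every record gets `quality = "insufficient"`
#' and a missing retinopathy grade (such images cannot be graded); for all
#' other folds quality is drawn from the in-distribution levels only.
#'
#' @param spec A [generator_spec()].
#' @param n Number of records, `>= 1`.
#' @param seed Integer seed; same seed reproduces the same records.
#' @param fold One of `"train"`, `"val"`, `"test"`, `"ood"`.
#' @return A data.frame with columns `patient_id`, `sex`, `ethnicity`,
#'   `quality` (ordered factor), `comorbidity` (logical), `dr_grade`
#'   (integer, NA only when quality is insufficient).
#' @export
sample_attributes <- function(spec, n, seed = spec$seed, fold = "test") {
  stopifnot(inherits(spec, "generator_spec"), n >= 1)
  fold <- match.arg(fold, c("train", "val", "test", "ood"))
  m <- spec$marginals
  with_seed(seed, {
    sex <- sample(names(m$sex), n, replace = TRUE, prob = m$sex)
    eth <- sample(names(m$ethnicity), n, replace = TRUE, prob = m$ethnicity)
    com <- sample(c(FALSE, TRUE), n, replace = TRUE,
                  prob = m$comorbidity[c("FALSE", "TRUE")])
    if (fold == "ood") {
      qual <- rep("insufficient", n)
      grade <- rep(NA_integer_, n)
    } else {
      qual <- sample(names(m$quality), n, replace = TRUE, prob = m$quality)
      grade <- as.integer(sample(names(m$dr_grade), n, replace = TRUE,
                                 prob = m$dr_grade))
    }
    data.frame(
      patient_id = seq_len(n),
      sex = factor(sex, levels = SEX_LEVELS),
      ethnicity = factor(eth, levels = ETHNICITY_LEVELS),
      quality = factor(qual, levels = QUALITY_LEVELS, ordered = TRUE),
      comorbidity = com,
      dr_grade = grade,
      stringsAsFactors = FALSE
    )
  })
}

# Relative pigmentation level per ethnicity (arbitrary stand-in ordering;
# scaled by the ethnicity effect amplitude).
ETHNICITY_PIGMENT <- c(african = 1.0, asian = 0.45, white = -0.8,
                       indian = 0.6, latin_american = 0.0,
                       multiracial = 0.2, native_american = 0.4)

#' Render a synthetic fundus image for one attribute record
#'
#' Deterministically renders a circular bright fundus field on a dark
#' background and composes attribute-dependent effects: retinopathy grade
#' adds lesion-like dark-red spots growing in number and contrast with grade;
#' co-morbidity adds a diffuse whitish haze patch; ethnicity shifts the
#' global pigmentation; sex adds a low-amplitude smooth shading asymmetry;
#' lower image quality adds blur and extra noise, with the insufficient
#' level adding heavy blur, dimming and a partial occlusion beyond any
#' in-distribution quality. Pixels are clipped to \[0,1\] and snapped to the
#' 8-bit grid so that PNG round trips are lossless.
#'
#' @param attrs One attribute record (single row of [sample_attributes()]
#'   output, or an equivalent list).
#' @param spec A [generator_spec()].
#' @param seed Integer seed controlling lesion/haze placement and noise.
#' @return List with `pixels` (size x size x 3 array in \[0,1\]) and `attrs`.
#' @export
render_image <- function(attrs, spec, seed = spec$seed) {
  stopifnot(inherits(spec, "generator_spec"))
  if (is.data.frame(attrs)) {
    stopifnot(nrow(attrs) == 1L)
    attrs <- as.list(attrs)
  }
  s <- spec$image_size
  amp <- spec$effect_amplitudes
  g <- coord_grid(s)
  r <- sqrt(g$x^2 + g$y^2)
  disc <- clip01((0.95 - r) / 0.08)

  quality <- as.character(attrs$quality)
  sex <- as.character(attrs$sex)
  eth <- as.character(attrs$ethnicity)
  grade <- attrs$dr_grade
  if (is.null(grade) || is.na(grade)) grade <- 0L
  if (!grade %in% 0:4) stop("dr_grade must be in 0..4")

  pig <- 1 - amp[["ethnicity"]] * ETHNICITY_PIGMENT[[eth]]
  base <- c(0.82, 0.46, 0.19) * pig

  img <- with_seed(seed, {
    R <- matrix(base[1], s, s); G <- matrix(base[2], s, s)
    B <- matrix(base[3], s, s)

    # optic disc: bright spot towards the nasal side
    od <- 0.30 * exp(-((g$x - 0.45)^2 + g$y^2) / 0.015)
    R <- R + od; G <- G + 0.9 * od; B <- B + 0.5 * od

    # smooth radial shading typical of fundus photographs
    shade <- 1 - 0.25 * r^2
    R <- R * shade; G <- G * shade; B <- B * shade

    # sex: low-amplitude low-frequency shading asymmetry
    ssign <- switch(sex, female = 1, male = -1, other = 0)
    if (ssign != 0 && amp[["sex"]] > 0) {
      sx <- amp[["sex"]] * ssign * cos(pi * g$x / 2) * sin(pi * g$y / 2)
      R <- R + sx; G <- G + sx; B <- B + sx
    }

    # lesions: dark red-brown spots, count and contrast grow with grade
    if (grade > 0 && amp[["dr_grade"]] > 0) {
      lm <- spec$lesion_model
      n_les <- lm$count_per_grade * grade
      contr <- amp[["dr_grade"]] * lm$contrast * (0.6 + 0.2 * grade)
      rad <- lm$radius * (1 + 0.15 * grade)
      theta <- stats::runif(n_les, 0, 2 * pi)
      rho <- sqrt(stats::runif(n_les)) * 0.75
      for (i in seq_len(n_les)) {
        cx <- rho[i] * cos(theta[i]); cy <- rho[i] * sin(theta[i])
        bump <- exp(-((g$x - cx)^2 + (g$y - cy)^2) / (2 * rad^2))
        R <- R - 0.25 * contr * bump
        G <- G - 1.00 * contr * bump
        B <- B - 0.60 * contr * bump
      }
    }

    # co-morbidity: one diffuse whitish haze patch
    if (isTRUE(attrs$comorbidity) && amp[["comorbidity"]] > 0) {
      hx <- stats::runif(1, -0.4, 0.4); hy <- stats::runif(1, -0.4, 0.4)
      haze <- amp[["comorbidity"]] * exp(-((g$x - hx)^2 + (g$y - hy)^2) / 0.18)
      R <- R + 0.9 * haze; G <- G + haze; B <- B + haze
    }

    img <- array(c(R, G, B), dim = c(s, s, 3))
    for (c in 1:3) img[, , c] <- img[, , c] * disc

    # image quality: blur (scaled to image size), extra degradation for the
    # out-of-distribution insufficient level
    aq <- amp[["quality"]]
    sigma <- spec$quality_blur[[quality]] * aq * s / 64
    extra_noise <- 0
    if (quality == "insufficient" && aq > 0) {
      ox <- stats::runif(1, -0.5, 0.5); oy <- stats::runif(1, -0.5, 0.5)
      occ <- pmin(0.8, 0.5 * aq) * exp(-((g$x - ox)^2 + (g$y - oy)^2) / 0.3)
      dim_f <- 1 - pmin(0.9, 0.2 * aq)
      for (c in 1:3) img[, , c] <- img[, , c] * (dim_f - occ) * (occ < dim_f)
      extra_noise <- 0.05 * aq
    }
    img <- blur_image(img, sigma)

    sd_tot <- spec$noise_sd + extra_noise
    if (sd_tot > 0) {
      img <- img + array(stats::rnorm(length(img), 0, sd_tot), dim = dim(img))
    }
    img
  })

  if (all(img >= 1) || all(img <= 0)) {
    warning("rendered image is fully saturated; clipping to [0,1]")
  }
  list(pixels = quantize8(clip01(img)), attrs = attrs)
}

#' Generate a labeled synthetic dataset
#'
#' Composes [sample_attributes()] and [render_image()] into a dataset object
#' holding all pixel data (flattened, one row per image) plus the attribute
#' sheet. Deterministic given `(spec, n, fold, seed)`.
#'
#' @inheritParams sample_attributes
#' @return An object of class `fundus_dataset` with elements `pixels`
#'   (n x (size^2*3) matrix), `attrs` (data.frame including `image_id` and
#'   `fold`), `image_size`, and an internal cache environment.
#' @export
generate_dataset <- function(spec, n, fold = "test", seed = spec$seed) {
  stopifnot(inherits(spec, "generator_spec"), n >= 1)
  fold <- match.arg(fold, c("train", "val", "test", "ood"))
  attrs <- sample_attributes(spec, n, seed = seed, fold = fold)
  attrs$image_id <- sprintf("%s%06d", substr(fold, 1, 2), seq_len(n))
  attrs$fold <- fold
  img_seeds <- derive_seeds(seed + 1L, n)
  s <- spec$image_size
  px <- matrix(0, nrow = n, ncol = s * s * 3)
  for (i in seq_len(n)) {
    px[i, ] <- as.vector(render_image(attrs[i, ], spec, img_seeds[i])$pixels)
  }
  new_fundus_dataset(px, attrs, s)
}

new_fundus_dataset <- function(pixels, attrs, image_size) {
  stopifnot(nrow(pixels) == nrow(attrs))
  rownames(attrs) <- NULL
  structure(list(pixels = pixels, attrs = attrs,
                 image_size = as.integer(image_size),
                 cache = new.env(parent = emptyenv())),
            class = "fundus_dataset")
}

#' @export
print.fundus_dataset <- function(x, ...) {
  cat(sprintf("fundus_dataset: %d images, %dx%d px, fold(s): %s\n",
              nrow(x$pixels), x$image_size, x$image_size,
              paste(unique(x$attrs$fold), collapse = ", ")))
  invisible(x)
}

#' Number of images in a dataset
#' @param ds A `fundus_dataset`.
#' @export
n_images <- function(ds) nrow(ds$pixels)

#' Extract one image as a size x size x 3 array
#' @param ds A `fundus_dataset`.
#' @param i Image index.
#' @export
get_image <- function(ds, i) {
  s <- ds$image_size
  array(ds$pixels[i, ], dim = c(s, s, 3))
}

#' Write a dataset to disk as PNG files plus an attribute sheet
#'
#' Creates `<dir>/<image_id>.png` for every image and `<dir>/attributes.csv`
#' with header `image_id,patient_id,sex,ethnicity,quality,comorbidity,
#' dr_grade,fold` (`dr_grade` written as the empty string when missing).
#' Because rendered pixels sit on the 8-bit grid, [read_dataset()] recovers
#' them bit-exactly.
#'
#' @param ds A `fundus_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cols <- c("image_id", "patient_id", "sex", "ethnicity", "quality",
            "comorbidity", "dr_grade", "fold")
  utils::write.csv(ds$attrs[, cols], file.path(dir, "attributes.csv"),
                   row.names = FALSE, na = "")
  for (i in seq_len(n_images(ds))) {
    png::writePNG(get_image(ds, i),
                  file.path(dir, paste0(ds$attrs$image_id[i], ".png")))
  }
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#' @param dir Directory containing `attributes.csv` and the PNG files.
#' @return A `fundus_dataset`.
#' @export
read_dataset <- function(dir) {
  attrs <- utils::read.csv(file.path(dir, "attributes.csv"),
                           stringsAsFactors = FALSE)
  attrs$sex <- factor(attrs$sex, levels = SEX_LEVELS)
  attrs$ethnicity <- factor(attrs$ethnicity, levels = ETHNICITY_LEVELS)
  attrs$quality <- factor(attrs$quality, levels = QUALITY_LEVELS,
                          ordered = TRUE)
  attrs$comorbidity <- as.logical(attrs$comorbidity)
  attrs$dr_grade <- suppressWarnings(as.integer(attrs$dr_grade))
  first <- png::readPNG(file.path(dir, paste0(attrs$image_id[1], ".png")))
  s <- dim(first)[1]
  px <- matrix(0, nrow = nrow(attrs), ncol = s * s * 3)
  px[1, ] <- as.vector(first)
  for (i in seq_len(nrow(attrs))[-1]) {
    px[i, ] <- as.vector(png::readPNG(
      file.path(dir, paste0(attrs$image_id[i], ".png"))))
  }
  new_fundus_dataset(px, attrs, s)
}
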