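test_that("attribute marginals are recovered within multinomial noise", {
  spec <- tiny_spec()
  n <- 10000
  attrs <- sample_attributes(spec, n, seed = 5)
  emp <- list(
    sex = table(attrs$sex) / n,
    ethnicity = table(attrs$ethnicity) / n,
    quality = table(droplevels(attrs$quality)) / n,
    dr_grade = table(attrs$dr_grade) / n
  )
  for (a in names(emp)) {
    p <- spec$marginals[[a]]
    for (lev in names(p)) {
      se <- sqrt(p[[lev]] * (1 - p[[lev]]) / n)
      expect_lt(abs(emp[[a]][[lev]] - p[[lev]]), 3 * se + 1e-12,
                label = paste(a, lev))
    }
  }
  expect_lt(abs(mean(attrs$comorbidity) - 0.1), 3 * sqrt(0.1 * 0.9 / n))
  # headline prevalences of the emulated population
  expect_equal(unname(emp$sex[["female"]]), 0.60, tolerance = 0.02)
  expect_equal(unname(emp$dr_grade[["0"]]), 0.79, tolerance = 0.02)
})

test_that("attribute and pixel generation is deterministic under a seed", {
  spec <- tiny_spec()
  a1 <- sample_attributes(spec, 50, seed = 9)
  a2 <- sample_attributes(spec, 50, seed = 9)
  expect_identical(a1, a2)
  d1 <- generate_dataset(spec, 8, fold = "val", seed = 21)
  d2 <- generate_dataset(spec, 8, fold = "val", seed = 21)
  expect_identical(d1$pixels, d2$pixels)
  im1 <- render_image(a1[1, ], spec, seed = 3)
  im2 <- render_image(a1[1, ], spec, seed = 3)
  expect_identical(im1$pixels, im2$pixels)
})

test_that("invalid generator configuration errors name the attribute", {
  m <- default_marginals()
  m$sex <- c(female = -0.2, male = 1.2, other = 0)
  expect_error(generator_spec(marginals = m), "sex")
  m <- default_marginals()
  m$quality <- c(insufficient = 0.2, adequate = 0.8)
  expect_error(generator_spec(marginals = m), "quality")
  expect_error(generator_spec(effect_amplitudes = c(bogus = 1)), "bogus")
  expect_error(
    generator_spec(quality_blur = c(excellent = 0, good = 1, adequate = 2,
                                    insufficient = 1.5)),
    "insufficient")
})

test_that("renderer with zero amplitudes and zero noise ignores attributes", {
  spec <- tiny_spec(effect_amplitudes = c(sex = 0, ethnicity = 0,
                                          comorbidity = 0, quality = 0,
                                          dr_grade = 0),
                    noise_sd = 0)
  a <- sample_attributes(tiny_spec(), 12, seed = 4)
  a$quality[1] <- "insufficient"  # even OOD quality renders identically
  imgs <- lapply(seq_len(nrow(a)),
                 function(i) render_image(a[i, ], spec, seed = 99)$pixels)
  for (i in 2:length(imgs)) expect_identical(imgs[[i]], imgs[[1]])
})

test_that("comorbidity changes pixels only in the haze region", {
  spec <- tiny_spec(noise_sd = 0)
  a <- sample_attributes(spec, 1, seed = 6)
  a$quality <- factor("excellent", levels = levels(a$quality), ordered = TRUE)
  a$dr_grade <- 0L
  b <- a
  b$comorbidity <- TRUE
  a$comorbidity <- FALSE
  ia <- render_image(a, spec, seed = 13)$pixels
  ib <- render_image(b, spec, seed = 13)$pixels
  diffmap <- abs(ib - ia)
  expect_gt(mean(diffmap), 0)           # the haze is really there
  changed <- apply(diffmap, c(1, 2), max) > 0
  expect_lt(mean(changed), 0.6)         # and it is localized, not global
  # background corners (outside the fundus disc) are untouched
  expect_identical(diffmap[1:3, 1:3, ], ia[1:3, 1:3, ] * 0)
})

test_that("insufficient quality maps to a strictly larger blur width", {
  spec <- tiny_spec()
  expect_gt(spec$quality_blur[["insufficient"]],
            spec$quality_blur[["adequate"]])
  expect_gt(spec$quality_blur[["adequate"]], spec$quality_blur[["good"]])
})

test_that("ood fold contains only ungradeable insufficient-quality images", {
  ood <- ood_pool()
  expect_true(all(ood$attrs$quality == "insufficient"))
  expect_true(all(is.na(ood$attrs$dr_grade)))
  ind <- base_dataset()
  expect_false(any(ind$attrs$quality == "insufficient"))
  expect_false(anyNA(ind$attrs$dr_grade))
})

test_that("datasets round-trip bit-exactly through PNG + CSV", {
  spec <- tiny_spec()
  ds <- generate_dataset(spec, 6, fold = "test", seed = 31)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  rd <- read_dataset(dir)
  expect_identical(rd$pixels, ds$pixels)
  expect_identical(as.character(rd$attrs$quality),
                   as.character(ds$attrs$quality))
  expect_identical(rd$attrs$dr_grade, ds$attrs$dr_grade)
  expect_identical(rd$attrs$comorbidity, ds$attrs$comorbidity)
  # dr_grade is the empty string on disk for ungradeable images
  ood <- generate_dataset(spec, 3, fold = "ood", seed = 32)
  dir2 <- withr::local_tempdir()
  write_dataset(ood, dir2)
  sheet <- readLines(file.path(dir2, "attributes.csv"))
  expect_true(all(grepl("\"insufficient\",(TRUE|FALSE),,", sheet[-1])))
  expect_true(all(is.na(read_dataset(dir2)$attrs$dr_grade)))
})

test_that("attribute separability ordering matches detection difficulty", {
  spec <- tiny_spec()
  # linear probe accuracy on pixel-derived features, per attribute contrast
  # few-shot probe: 15 training images per class keeps the easy contrasts
  # from all saturating at accuracy 1
  probe_acc <- function(ds_a, ds_b) {
    xa <- pool_features(ds_a); xb <- pool_features(ds_b)
    n <- min(nrow(xa), nrow(xb))
    tr <- seq_len(15)
    x <- rbind(xa[tr, ], xb[tr, ])
    y <- rep(0:1, each = length(tr))
    fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                          lambda = 0.05)
    te <- setdiff(seq_len(n), tr)
    px <- predict(fit, rbind(xa[te, ], xb[te, ]), type = "response")
    mean((px > 0.5) == rep(0:1, each = length(te)))
  }
  filt <- function(ds, keep) {
    idx <- which(keep)
    fundusshift:::new_fundus_dataset(ds$pixels[idx, , drop = FALSE],
                                     ds$attrs[idx, , drop = FALSE],
                                     ds$image_size)
  }
  mk <- function(fold, n, seed) generate_dataset(spec, n, fold, seed)
  big <- mk("test", 1200, 61)
  acc_quality <- probe_acc(filt(big, big$attrs$quality == "adequate"),
                           mk("ood", 250, 62))
  acc_com <- probe_acc(filt(big, !big$attrs$comorbidity),
                       filt(big, big$attrs$comorbidity))
  acc_sex <- probe_acc(filt(big, big$attrs$sex == "female"),
                       filt(big, big$attrs$sex == "male"))
  expect_gt(acc_quality, acc_com)
  expect_gt(acc_com, acc_sex)
})
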