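ref_from <- function(mu, sigma) {
  structure(list(matched_ids = "ctrl", point_mean = mu, point_sd = sigma),
            class = "control_reference")
}

test_that("signature weight follows the normalized sum-of-squares formula", {
  mu <- matrix(0, 50, 3)
  sg <- matrix(1, 50, 3)
  expect_equal(compute_signature(mu, ref_from(mu, sg))$weight, 0)
  # one point displaced by (3 sd, 4 sd, 0): weight is the 3-4-5 hypotenuse
  P <- mu
  P[17, ] <- c(3, 4, 0)
  expect_equal(compute_signature(P, ref_from(mu, sg))$weight, 5)
  expect_error(compute_signature(P[1:10, ], ref_from(mu, sg)), "dimension")
})

test_that("signature weight matches the brute-force loop on random fields", {
  set.seed(10)
  for (i in 1:5) {
    mu <- matrix(rnorm(120), 40, 3)
    sg <- matrix(runif(120, 0.5, 2), 40, 3)
    P <- mu + matrix(rnorm(120), 40, 3) * sg
    w <- compute_signature(P, ref_from(mu, sg))$weight
    expect_equal(w, ref_signature_weight(P, mu, sg), tolerance = 1e-12)
  }
})

test_that("weight is permutation-invariant and scales linearly", {
  set.seed(11)
  mu <- matrix(rnorm(90), 30, 3)
  sg <- matrix(runif(90, 0.5, 2), 30, 3)
  P <- mu + matrix(rnorm(90), 30, 3)
  w <- compute_signature(P, ref_from(mu, sg))$weight
  perm <- sample(30)
  w_perm <- compute_signature(P[perm, ], ref_from(mu[perm, ], sg[perm, ]))$weight
  expect_equal(w_perm, w, tolerance = 1e-12)
  P2 <- mu + 2 * (P - mu)
  expect_equal(compute_signature(P2, ref_from(mu, sg))$weight, 2 * w,
               tolerance = 1e-12)
})

test_that("control matching filters by gender and widens the age window", {
  set.seed(12)
  controls <- tibble::tibble(
    subject_id = sprintf("c%02d", 1:40),
    age = rep(c(20, 30, 40, 60), 10),
    gender = rep(c("F", "M"), 20))
  fields <- lapply(setNames(controls$subject_id, controls$subject_id),
                   function(i) matrix(rnorm(30), 10, 3))
  ref <- matched_controls(list(age = 40, gender = "F"), controls, fields,
                          age_window = 5, min_n = 3)
  matched <- controls[controls$subject_id %in% ref$matched_ids, ]
  expect_true(all(matched$gender == "F"))
  expect_true(all(abs(matched$age - 40) <= ref$age_window_used))
  # widening: female controls exist only at ages 20 and 40 (10 each), so a
  # 15-strong match must widen the window until the age-20 stratum enters
  ref2 <- matched_controls(list(age = 40, gender = "F"), controls, fields,
                           age_window = 5, widen_step = 5, min_n = 15)
  expect_gte(ref2$age_window_used, 20)
  expect_gte(length(ref2$matched_ids), 15)
  expect_error(
    matched_controls(list(age = 40, gender = "F"), controls, fields, min_n = 100),
    "matched control")
})

test_that("identical controls floor the pointwise SD", {
  controls <- tibble::tibble(subject_id = sprintf("c%d", 1:25),
                             age = 40, gender = "F")
  same <- matrix(1, 10, 3)
  fields <- lapply(setNames(controls$subject_id, controls$subject_id),
                   function(i) same)
  ref <- matched_controls(list(age = 40, gender = "F"), controls, fields,
                          min_n = 20, sd_floor = 0.01)
  expect_true(all(ref$point_sd == 0.01))
  expect_equal(ref$point_mean, same)
})

test_that("estimated pointwise SD converges to the generating SD", {
  set.seed(13)
  sigma <- matrix(runif(60, 0.5, 3), 20, 3)
  controls <- tibble::tibble(subject_id = sprintf("c%03d", 1:200),
                             age = runif(200, 30, 50), gender = "F")
  fields <- lapply(setNames(controls$subject_id, controls$subject_id),
                   function(i) matrix(rnorm(60), 20, 3) * sigma)
  ref <- matched_controls(list(age = 40, gender = "F"), controls, fields,
                          age_window = 50, min_n = 150)
  # sampling error of an SD at n = 200 is about sigma/sqrt(2n) ~ 5%
  expect_lt(max(abs(ref$point_sd / sigma - 1)), 0.2)
  expect_lt(mean(abs(ref$point_sd / sigma - 1)), 0.05)
})

test_that("a subject from the control distribution has weight^2 near 3M", {
  set.seed(14)
  M <- 500
  controls <- tibble::tibble(subject_id = sprintf("c%03d", 1:200),
                             age = 40, gender = "F")
  fields <- lapply(setNames(controls$subject_id, controls$subject_id),
                   function(i) matrix(rnorm(3 * M), M, 3))
  ref <- matched_controls(list(age = 40, gender = "F"), controls, fields,
                          min_n = 150)
  w2 <- replicate(30, compute_signature(matrix(rnorm(3 * M), M, 3), ref)$weight^2)
  expect_lt(abs(mean(w2) / (3 * M) - 1), 0.05)
})

test_that("heat maps extract per-axis and normal components with colors", {
  tmpl <- cached_template(600)
  M <- nrow(tmpl$vertices)
  mu <- matrix(0, M, 3)
  sg <- matrix(1, M, 3)
  zero <- compute_signature(mu, ref_from(mu, sg))
  hm0 <- heat_map(zero, axis = "x")
  expect_true(all(hm0$scalars == 0))
  expect_true(all(hm0$colors[, "green"] == 255L))
  expect_true(all(hm0$colors[, "red"] == 0L & hm0$colors[, "blue"] == 0L))
  # a single +x displacement appears only on the x map
  P <- mu
  P[101, 1] <- 2.5
  sig <- compute_signature(P, ref_from(mu, sg))
  expect_equal(heat_map(sig, axis = "x")$scalars[101], 2.5)
  expect_equal(heat_map(sig, axis = "y")$scalars[101], 0)
  expect_equal(heat_map(sig, axis = "z")$scalars[101], 0)
  expect_error(heat_map(sig, axis = "w"), "axis")
  expect_error(heat_map(sig, axis = "normal"), "base mesh")
})

test_that("an outward bump shows positive normal-axis scalars over the bump", {
  tmpl <- cached_template(600)
  v <- tmpl$vertices
  nrm <- facesym:::vertex_normals(v, tmpl$triangles)
  bump_w <- exp(-((v[, 1] - 15)^2 + (v[, 2] + 5)^2) / 200)
  mu <- matrix(0, nrow(v), 3)
  sg <- matrix(1, nrow(v), 3)
  sig <- compute_signature(mu + nrm * (3 * bump_w), ref_from(mu, sg))
  hm <- heat_map(sig, axis = "normal", base = tmpl)
  inside <- bump_w > 0.5
  outside <- bump_w < 0.01
  expect_true(all(hm$scalars[inside] > 1))
  expect_lt(max(abs(hm$scalars[outside])), 0.1)
})

test_that("heat maps export to CSV and colored PLY", {
  tmpl <- cached_template(600)
  M <- nrow(tmpl$vertices)
  sig <- compute_signature(matrix(rnorm(3 * M), M, 3),
                           ref_from(matrix(0, M, 3), matrix(1, M, 3)))
  hm <- heat_map(sig, axis = "z")
  csv <- withr::local_tempfile(fileext = ".csv")
  ply <- withr::local_tempfile(fileext = ".ply")
  write_heat_map(hm, tmpl, csv)
  got <- read.csv(csv)
  expect_equal(got$scalar, hm$scalars, tolerance = 1e-12)
  write_heat_map(hm, tmpl, ply)
  expect_true(any(grepl("property uchar red", readLines(ply, n = 12))))
})
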