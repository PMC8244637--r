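#' Synthetic symmetric face template
#'
#' A smooth, face-like parametric surface: a triangulated height field
#' z = f(x, y) over a rectangular grid spanning roughly an adult face
#' (x lateral in [-85, 85] mm, y vertical in [-95, 65] mm), with a nasal
#' ridge, eye sockets, brow, lips and chin so anthropometric distances are
#' meaningful. The grid has an odd number of x columns and f is even in x,
#' so the surface is *exactly* symmetric about x = 0; the 22 canonical
#' landmarks are snapped to grid vertices at exactly mirrored positions
#' (midline landmarks on the x = 0 column).
#'
#' The vertex count is `nu * nv` for an odd number of columns `nu`; when `M`
#' has an odd divisor near the natural grid aspect the count is exactly `M`
#' (e.g. M = 2000 is the 25 x 80 grid), otherwise the nearest feasible grid
#' is used and the actual count is reported by the object.
#'
#' @param M Target vertex count (>= 500 for full-face models).
#' @return A `base_mesh` (also a `face_surface`): subject "template", with
#'   attributes `mirror_index` (the vertex permutation realizing x-mirror
#'   symmetry) and `landmark_vertex` (landmark name -> vertex index).
#' @export
make_template <- function(M = 1000) {
  if (M < 500) abort(glue::glue("template needs M >= 500 vertices, got {M}"))
  dims <- template_grid_dims(M)
  nu <- dims[1]; nv <- dims[2]
  xs <- seq(-85, 85, length.out = nu)
  xs <- (xs - rev(xs)) / 2 # force exact antisymmetry of the column coordinates
  ys <- seq(-95, 65, length.out = nv)
  g <- expand.grid(ix = seq_len(nu), iy = seq_len(nv))
  x <- xs[g$ix]; y <- ys[g$iy]
  z <- face_height(x, y)
  vertices <- cbind(x = x, y = y, z = z)
  triangles <- grid_triangles(nu, nv)
  mirror_index <- (g$iy - 1L) * nu + (nu + 1L - g$ix)

  lm_xy <- template_landmark_targets()
  lm_vertex <- snap_landmarks(lm_xy, xs, ys, nu)
  lms <- landmark_set(
    structure(vertices[lm_vertex, , drop = FALSE],
              dimnames = list(names(lm_vertex), NULL)))
  base <- face_surface("template", vertices, triangles, lms)
  attr(base, "mirror_index") <- mirror_index
  attr(base, "landmark_vertex") <- lm_vertex
  attr(base, "grid_dims") <- c(nu = nu, nv = nv)
  class(base) <- c("base_mesh", class(base))
  base
}

# odd nu dividing M and close to the natural aspect; else nearest grid
template_grid_dims <- function(M) {
  target_nu <- sqrt(M * 170 / 160)
  divs <- which(M %% seq_len(M) == 0)
  odd <- divs[divs %% 2 == 1 & divs >= 9 & divs <= M / 9]
  if (length(odd) > 0) {
    nu <- odd[which.min(abs(odd - target_nu))]
    return(c(nu, M %/% nu))
  }
  nu <- 2 * round((target_nu - 1) / 2) + 1
  c(nu, max(9L, round(M / nu)))
}

face_height <- function(x, y) {
  dome <- 55 * sqrt(pmax(0, 1 - (x / 120)^2 - ((y + 10) / 140)^2))
  nose <- 16 * exp(-(x / 10)^2 - ((y - 2) / 26)^2)
  sockets <- -5 * exp(-((abs(x) - 32) / 11)^2 - ((y - 38) / 9)^2)
  brow <- 3 * exp(-((abs(x) - 30) / 22)^2 - ((y - 52) / 7)^2)
  lips <- 2 * exp(-(x / 20)^2 - ((y + 24) / 6)^2)
  mouth <- -2.5 * exp(-(x / 24)^2 - ((y + 32) / 4)^2)
  chin <- 3 * exp(-(x / 18)^2 - ((y + 70) / 12)^2)
  dome + nose + sockets + brow + lips + mouth + chin
}

template_landmark_targets <- function() {
  rbind(
    glabella = c(0, 55), nasion = c(0, 45), pronasale = c(0, 2),
    subnasale = c(0, -8), labiale_superius = c(0, -24),
    labiale_inferius = c(0, -40), sublabiale = c(0, -52), gnathion = c(0, -85),
    exocanthion_L = c(45, 38), endocanthion_L = c(18, 38),
    alare_L = c(12, -6), cheilion_L = c(26, -32), zygion_L = c(65, 20),
    tragion_L = c(78, 5), gonion_L = c(55, -55)
  )
}

snap_landmarks <- function(lm_xy, xs, ys, nu) {
  out <- integer(0)
  for (nm in rownames(lm_xy)) {
    ix <- which.min(abs(xs - lm_xy[nm, 1]))
    iy <- which.min(abs(ys - lm_xy[nm, 2]))
    if (lm_xy[nm, 1] == 0) ix <- (nu + 1L) / 2L
    out[nm] <- (iy - 1L) * nu + ix
    if (grepl("_L$", nm)) { # exact mirrored partner for the right side
      out[sub("_L$", "_R", nm)] <- (iy - 1L) * nu + (nu + 1L - ix)
    }
  }
  out[canonical_landmark_names()]
}

grid_triangles <- function(nu, nv) {
  i <- rep(seq_len(nu - 1), nv - 1)
  j <- rep(seq_len(nv - 1), each = nu - 1)
  v00 <- (j - 1L) * nu + i
  v10 <- v00 + 1L
  v01 <- v00 + nu
  v11 <- v01 + 1L
  rbind(cbind(v00, v10, v11), cbind(v00, v11, v01))
}

#' Mirror permutation of a template's vertices
#' @param base A [make_template()] mesh.
#' @return Integer vector p with vertex i's x-mirror partner p\[i\].
#' @export
mirror_index <- function(base) {
  attr(base, "mirror_index") %||% abort("mesh has no mirror index (not a template)")
}

# reflect-and-relabel a per-vertex field (n x 3) living on the template
reflect_field <- function(field, mi) {
  out <- field[mi, , drop = FALSE]
  out[, 1] <- -out[, 1]
  out
}

# smooth random vertex field: superposition of Gaussian bumps, then
# symmetrized (+1) or antisymmetrized (-1) under reflect-and-relabel and
# scaled to unit RMS displacement
random_mode_field <- function(base, parity, n_bumps = 6, length_scale = 25) {
  v <- base$vertices
  mi <- mirror_index(base)
  field <- matrix(0, nrow(v), 3)
  for (b in seq_len(n_bumps)) {
    ctr <- v[sample.int(nrow(v), 1), ]
    dir <- rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    w <- exp(-rowSums(sweep(v, 2, ctr)^2) / (2 * length_scale^2))
    field <- field + outer(w, dir)
  }
  field <- (field + parity * reflect_field(field, mi)) / 2
  field / sqrt(mean(rowSums(field^2)))
}

#' Simulation configuration for a synthetic face cohort
#'
#' Defaults emulate the study conditions the pipeline is designed for:
#' cohort group sizes at one third of the clinical cohort (CTRL 68, FS 61,
#' FC 48, IGE 17), adult age range 18-77, a small number of shared symmetric
#' shape modes plus antisymmetric (asymmetry) modes, a 2 mm extra asymmetry
#' amplitude in the FS group only, and 0.2 mm sensor noise (typical
#' stereophotogrammetry repeatability).
#'
#' @param M Template vertex count.
#' @param n_per_group Named integer vector of group sizes.
#' @param sym_sd SDs (mm RMS) of the symmetric mode coefficients.
#' @param asym_sd SDs (mm RMS) of the antisymmetric mode coefficients.
#' @param delta Named extra asymmetry amplitude (mm) added to every
#'   antisymmetric mode SD, per group.
#' @param noise_sd Sensor noise SD per coordinate (mm).
#' @param age_range Uniform age range (years).
#' @param female_frac Fraction of female subjects.
#' @param duration_coupling Slope (years per mm) coupling epilepsy duration
#'   to the subject's total asymmetric-mode amplitude; 0 for none.
#' @param pose_sd Random pose jitter: rotation SD (degrees) and translation
#'   SD (mm) applied per face, exercised by the alignment step.
#' @param injury_frac Probability of the facial-injury flag.
#' @param seed Master seed; the whole cohort is reproducible from it.
#' @return A `face_sim_config` list.
#' @export
face_sim_config <- function(M = 1000,
                            n_per_group = c(CTRL = 68, FS = 61, FC = 48, IGE = 17),
                            sym_sd = c(3, 2, 1),
                            asym_sd = c(0.4, 0.25),
                            delta = c(CTRL = 0, FC = 0, FS = 2, IGE = 0),
                            noise_sd = 0.2,
                            age_range = c(18, 77),
                            female_frac = 0.55,
                            duration_coupling = 0,
                            pose_sd = c(rotation = 3, translation = 5),
                            injury_frac = 0.17,
                            seed = 1) {
  stopifnot(all(sym_sd >= 0), all(asym_sd >= 0), all(n_per_group >= 0),
            noise_sd >= 0, all(is.finite(delta)))
  if (!all(names(n_per_group) %in% c("CTRL", "FC", "FS", "IGE"))) {
    abort("group names must be among CTRL, FC, FS, IGE")
  }
  structure(list(M = M, n_per_group = n_per_group, sym_sd = sym_sd,
                 asym_sd = asym_sd, delta = delta, noise_sd = noise_sd,
                 age_range = age_range, female_frac = female_frac,
                 duration_coupling = duration_coupling, pose_sd = pose_sd,
                 injury_frac = injury_frac, seed = seed),
            class = "face_sim_config")
}

#' Simulate a landmarked face cohort with planted group asymmetry
#'
#' Each face is the symmetric template deformed by shared shape modes:
#' symmetric modes (invariant under reflect-and-relabel) model ordinary
#' face-shape variation; antisymmetric modes (negated by
#' reflect-and-relabel) model facial asymmetry. Mode coefficients are
#' Gaussian, with the antisymmetric SD inflated by the group's `delta`, so a
#' positive `delta` plants a group asymmetry effect. Sensor noise and a
#' random rigid pose complete the face; ages, genders, durations, injury
#' flags and lesion sides are drawn per the configuration.
#'
#' @param cfg A [face_sim_config()].
#' @param template Optional pre-built [make_template()] (must match `cfg$M`).
#' @return List: `faces` (list of [face_surface()]), `cohort` (tibble),
#'   `template`, `modes` (list of `sym`/`asym` unit fields).
#' @export
simulate_faces <- function(cfg = face_sim_config(), template = NULL) {
  set.seed(cfg$seed)
  base <- template %||% make_template(cfg$M)
  lm_vertex <- attr(base, "landmark_vertex")
  n <- sum(cfg$n_per_group)
  groups <- rep(names(cfg$n_per_group), cfg$n_per_group)
  ids <- sprintf("S%03d", seq_len(n))

  sym_modes <- lapply(seq_along(cfg$sym_sd), function(i) random_mode_field(base, +1))
  asym_modes <- lapply(seq_along(cfg$asym_sd), function(i) random_mode_field(base, -1))

  age <- round(runif(n, cfg$age_range[1], cfg$age_range[2]), 1)
  gender <- sample(c("F", "M"), n, replace = TRUE,
                   prob = c(cfg$female_frac, 1 - cfg$female_frac))
  a_coef <- matrix(rnorm(n * length(cfg$sym_sd)), n) %*% diag(cfg$sym_sd, length(cfg$sym_sd))
  b_sd <- outer(cfg$delta[groups], rep(1, length(cfg$asym_sd))) +
    outer(rep(1, n), cfg$asym_sd)
  b_coef <- matrix(rnorm(n * length(cfg$asym_sd)), n) * b_sd

  faces <- vector("list", n)
  for (i in seq_len(n)) {
    disp <- matrix(0, nrow(base$vertices), 3)
    for (k in seq_along(sym_modes)) disp <- disp + a_coef[i, k] * sym_modes[[k]]
    for (k in seq_along(asym_modes)) disp <- disp + b_coef[i, k] * asym_modes[[k]]
    if (cfg$noise_sd > 0) {
      disp <- disp + matrix(rnorm(length(disp), sd = cfg$noise_sd), nrow(disp))
    }
    v <- base$vertices + disp
    pose <- random_pose(cfg$pose_sd)
    v <- sweep(v %*% pose$R, 2, pose$t, "+")
    lms <- landmark_set(structure(v[lm_vertex, , drop = FALSE],
                                  dimnames = list(names(lm_vertex), NULL)))
    faces[[i]] <- face_surface(ids[i], v, base$triangles, lms, validate = FALSE)
  }

  asym_total <- sqrt(rowSums(b_coef^2))
  duration <- ifelse(groups == "CTRL", NA_real_,
                     pmin(pmax(runif(n, 0, 1) * (age - cfg$age_range[1]) +
                                 cfg$duration_coupling * asym_total, 0),
                          age))
  cohort <- tibble(
    subject_id = ids, age = age, gender = gender, group = groups,
    duration = round(duration, 1),
    facial_injury = runif(n) < cfg$injury_frac,
    lesion_side = ifelse(groups == "FS",
                         sample(c("left", "right"), n, replace = TRUE), "none")
  )
  list(faces = faces, cohort = cohort, template = base,
       modes = list(sym = sym_modes, asym = asym_modes))
}

random_pose <- function(pose_sd) {
  ang <- rnorm(3, sd = pose_sd[["rotation"]]) * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]), 0, -sin(ang[1]), cos(ang[1])), 3)
  Ry <- matrix(c(cos(ang[2]), 0, -sin(ang[2]), 0, 1, 0, sin(ang[2]), 0, cos(ang[2])), 3)
  Rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0, -sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3)
  list(R = Rx %*% Ry %*% Rz, t = rnorm(3, sd = pose_sd[["translation"]]))
}
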