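# Synthetic brain phantoms. Real training data (registered T1 volumes) is
# access-restricted, so the package ships a seeded generator of small 3D
# "brains" whose morphology encodes a known age and sex. The recoverable
# signal is monotone and documented: the central dark "ventricle" radius
# strictly INCREASES with age and the bright cortical rim thickness strictly
# DECREASES with age, mimicking the gross atrophy pattern of ageing; sex
# scales the whole head. These phantoms validate the pipeline end to end;
# they do not emulate the texture, contrast or anatomy of real MRI.

#' Phantom cohort configuration
#'
#' @param shape volume shape in voxels; every dimension must be a multiple of
#'   32 so the unmodified five-pool network runs on it. The default
#'   32x64x32 grid is a scaled-down head; full-size 160x192x160 is
#'   supported but not default.
#' @param n_subjects number of subjects to generate.
#' @param age_range years, ages drawn uniformly over it by default.
#' @param ventricle_coef growth of the ventricle radius, voxels/year.
#' @param rim_coef shrinkage of the cortical rim thickness, voxels/year.
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (tissue intensities are 0.1 / 0.5 / 1.0 on a zero background).
#' @param sex_effect relative head-size difference between the sexes; head
#'   semi-axes are scaled by `1 + sex_effect * (sex - 0.5)`.
#' @param age_dist `"uniform"`, or `"skewed"` (a right-heavy Beta(5, 1.5)
#'   shape) to exercise the bias-correction motivation of a non-Gaussian
#'   label distribution.
#' @param seed integer seed; regeneration with the same config is
#'   bit-identical.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(shape = c(32L, 64L, 32L), n_subjects = 100L,
                           age_range = c(42, 82), ventricle_coef = 0.1,
                           rim_coef = 0.05, noise_sd = 0.05,
                           sex_effect = 0.1,
                           age_dist = c("uniform", "skewed"), seed = 1L) {
  shape <- as.integer(shape)
  age_dist <- match.arg(age_dist)
  if (length(shape) != 3L || any(shape %% 32L != 0L))
    stop("shape must be 3 integers, each divisible by 32")
  if (min(shape) < 32L) stop("shape too small to render the phantom")
  if (age_range[2] <= age_range[1]) stop("invalid age_range")
  structure(list(shape = shape, n_subjects = as.integer(n_subjects),
                 age_range = age_range, ventricle_coef = ventricle_coef,
                 rim_coef = rim_coef, noise_sd = noise_sd,
                 sex_effect = sex_effect, age_dist = age_dist,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Deterministic phantom geometry for one subject (no noise).
# Regions by normalized ellipsoidal radius r: r > 1 background (0);
# 1 - rim < r <= 1 cortical rim (1.0); vent < r <= 1 - rim tissue (0.5);
# r <= vent ventricle (0.1).
render_phantom <- function(shape, age, sex, cfg) {
  scale_sex <- 1 + cfg$sex_effect * (sex - 0.5)
  semi <- 0.45 * shape * scale_sex
  ctr <- (shape + 1) / 2
  min_semi <- min(semi)
  years <- age - cfg$age_range[1]
  vent_r <- (2 + cfg$ventricle_coef * years) / min_semi
  rim_t <- (4 - cfg$rim_coef * years) / min_semi
  rim_t <- max(rim_t, 0.5 / min_semi)

  u1 <- (seq_len(shape[1]) - ctr[1]) / semi[1]
  u2 <- (seq_len(shape[2]) - ctr[2]) / semi[2]
  u3 <- (seq_len(shape[3]) - ctr[3]) / semi[3]
  r2 <- outer(outer(u1^2, u2^2, `+`), u3^2, `+`)
  r <- sqrt(r2)

  vol <- array(0, shape)
  vol[r <= 1] <- 0.5
  vol[r <= 1 & r > 1 - rim_t] <- 1.0
  vol[r <= vent_r] <- 0.1
  vol
}

#' Generate a phantom cohort
#'
#' Draws each subject's age (uniform or skewed over `age_range`) and sex
#' (Bernoulli 0.5), renders the concentric-ellipsoid phantom with
#' age-dependent geometry and sex-dependent scale, and adds Gaussian
#' intensity noise. With `dir` given, volumes are written as gzipped NIfTI
#' and a tab-separated participants table (columns `participant_id`, `age`,
#' `sex`, `path`, `split`, `modality`) is written alongside — the same table
#' format the training tools consume.
#'
#' @param cfg a [phantom_config()].
#' @param dir optional output directory for NIfTI files + `participants.tsv`.
#' @param split_fractions named fractions for train/val/test assignment
#'   (deterministic given the seed); `NULL` leaves the column `NA`.
#' @return a list with `participants` (data frame), `volumes` (named list of
#'   3D arrays) and `config`.
#' @export
generate_cohort <- function(cfg, dir = NULL,
                            split_fractions = c(train = 0.7, val = 0.15,
                                                test = 0.15)) {
  stopifnot(inherits(cfg, "phantom_config"))
  res <- with_seed(cfg$seed, {
    n <- cfg$n_subjects
    ages <- switch(cfg$age_dist,
      uniform = runif(n, cfg$age_range[1], cfg$age_range[2]),
      skewed = cfg$age_range[1] +
        diff(cfg$age_range) * stats::rbeta(n, 5, 1.5))
    sexes <- stats::rbinom(n, 1, 0.5)
    ids <- sprintf("sub-%04d", seq_len(n))
    vols <- vector("list", n)
    for (i in seq_len(n)) {
      v <- render_phantom(cfg$shape, ages[i], sexes[i], cfg)
      if (cfg$noise_sd > 0)
        v <- v + array(rnorm(length(v), sd = cfg$noise_sd), dim(v))
      vols[[i]] <- v
    }
    names(vols) <- ids
    split <- if (is.null(split_fractions)) rep(NA_character_, n) else {
      k <- round(cumsum(split_fractions) / sum(split_fractions) * n)
      s <- rep(names(split_fractions), times = diff(c(0, k)))
      sample(s, n)  # shuffle assignment
    }
    list(ages = ages, sexes = sexes, ids = ids, vols = vols, split = split)
  })
  paths <- rep(NA_character_, cfg$n_subjects)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(dir, paste0(res$ids, "_T1w.nii.gz"))
    for (i in seq_along(paths)) save_volume(res$vols[[i]], paths[i])
  }
  participants <- data.frame(participant_id = res$ids,
                             age = res$ages, sex = res$sexes,
                             path = paths, split = res$split,
                             modality = "raw", stringsAsFactors = FALSE)
  if (!is.null(dir))
    write_participants(participants, file.path(dir, "participants.tsv"))
  list(participants = participants, volumes = res$vols, config = cfg)
}

#' Derive pseudo-modalities from a phantom volume
#'
#' Stand-ins for the distinct preprocessing channels of real pipelines
#' (linear/nonlinear registration, grey/white-matter segmentations): `raw`
#' (unchanged), `smoothed` (normalized 3x3x3 box filter, intensity
#' preserving for content away from the boundary), `edge` (central-difference
#' gradient magnitude, zero on constant volumes) and `tissue_mask` (integer
#' labels: 0 background, 1 tissue, 2 rim — exactly two foreground labels).
#' All channels preserve shape, and each transform is deterministic.
#'
#' @param volume a 3D array.
#' @return a named list of four 3D arrays.
#' @export
derive_modalities <- function(volume) {
  d <- dim(volume)
  if (length(d) != 3L) stop("volume must be a 3D array")
  w <- array(1 / 27, c(3L, 3L, 3L, 1L, 1L))
  x <- volume; dim(x) <- c(d, 1L, 1L)
  smoothed <- .conv3d_fwd(x, w, NULL, 1L, 1L)
  dim(smoothed) <- d

  shift_ax <- function(v, a, o) {
    idx <- pmin(pmax(seq_len(d[a]) + o, 1L), d[a])  # replicate edges
    switch(a, v[idx, , , drop = FALSE], v[, idx, , drop = FALSE],
           v[, , idx, drop = FALSE])
  }
  g1 <- (shift_ax(volume, 1L, 1L) - shift_ax(volume, 1L, -1L)) / 2
  g2 <- (shift_ax(volume, 2L, 1L) - shift_ax(volume, 2L, -1L)) / 2
  g3 <- (shift_ax(volume, 3L, 1L) - shift_ax(volume, 3L, -1L)) / 2
  edge <- sqrt(g1^2 + g2^2 + g3^2)

  mask <- array(0L, d)
  mask[volume > 0.05] <- 1L
  mask[volume > 0.75] <- 2L
  list(raw = volume, smoothed = smoothed, edge = edge, tissue_mask = mask)
}

#' Count ventricle voxels of a phantom
#'
#' The dark central region (intensity near 0.1) inside the head; its voxel
#' count is the strictly increasing morphological age signal the generator
#' plants, usable as a network-free oracle regressor.
#'
#' @param volume a 3D phantom array.
#' @param lo,hi intensity window classifying a voxel as ventricle.
#' @return integer voxel count.
#' @export
count_ventricle_voxels <- function(volume, lo = 0.02, hi = 0.3) {
  sum(volume > lo & volume < hi)
}
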