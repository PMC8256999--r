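#' Stokes-level measurement noise model
#'
#' Gaussian noise applied to the six output Stokes vectors before Mueller
#' reconstruction. Each reconstruction pair of input states (LIN0/LIN90,
#' LIN45/LIN135, RHC/LHC) gets, per Stokes component, a *common-mode*
#' channel (the same draw added to both outputs of the pair) and a
#' *differential* channel (added to one, subtracted from the other).
#' Because reconstruction forms sums and differences of pair members, the
#' common channel of the LIN0/LIN90 pair feeds column 1 of the matrix and
#' the differential channels feed columns 2-4 — so each matrix element's
#' repeat-measurement spread can be set independently.
#'
#' The defaults place the heavy channels on elements
#' `m12, m13, m14, m21, m24, m34` (the circular-state column and the
#' intensity-coupled terms, which scattering tissue perturbs most) and keep
#' the remaining elements quiet, giving within-slice standard deviations of
#' roughly `sigma_wide` for the former and under 0.01 for the latter.
#'
#' @param sigma_wide Standard deviation of the heavy channels (default 0.055).
#' @param sigma_narrow Standard deviation of the quiet channels (default 0.004).
#' @return An object of class `stokes_noise_model`: per-pair lists of
#'   4-vectors `common` and `differential` (indexed by Stokes component).
#' @export
stokes_noise_model <- function(sigma_wide = 0.055, sigma_narrow = 0.004) {
  stopifnot(sigma_wide >= 0, sigma_narrow >= 0)
  w <- sigma_wide; n <- sigma_narrow
  structure(list(
    common = list(
      lin0_90   = c(n, w, n, n),  # feeds m11, m21, m31, m41
      lin45_135 = c(n, n, n, n),  # cancels in reconstruction
      circular  = c(n, n, n, n)   # cancels in reconstruction
    ),
    differential = list(
      lin0_90   = c(w, n, n, n),  # feeds m12, m22, m32, m42
      lin45_135 = c(w, n, n, n),  # feeds m13, m23, m33, m43
      circular  = c(w, w, w, n)   # feeds m14, m24, m34, m44
    )
  ), class = "stokes_noise_model")
}

# perturb a six-state measurement set in place; uses the ambient RNG stream
add_stokes_noise <- function(ms, noise) {
  stopifnot(inherits(noise, "stokes_noise_model"))
  for (pair in names(.state_pairs)) {
    eta_c <- stats::rnorm(4L, sd = noise$common[[pair]])
    eta_d <- stats::rnorm(4L, sd = noise$differential[[pair]])
    ab <- .state_pairs[[pair]]
    ms[[ab[1]]] <- ms[[ab[1]]] + eta_c + eta_d
    ms[[ab[2]]] <- ms[[ab[2]]] + eta_c - eta_d
  }
  ms
}

# mean optical parameters of the four simulated tissue classes; artifact
# choices calibrated to give class-distinct distributions at similar element
# magnitudes (melanoma strongly depolarizing, carcinomas intermediate)
.class_param_means <- function() {
  list(
    BCC      = optical_params(d = 0.25, theta_d = 0.52, cd = -0.10,
                              delta = 0.90, theta_r = 0.70, psi = -0.15,
                              a = 0.55, b = 0.50, c = 0.35),
    melanoma = optical_params(d = 0.15, theta_d = 1.22, cd = 0.30,
                              delta = 0.60, theta_r = 1.40, psi = 0.25,
                              a = 0.35, b = 0.30, c = 0.15),
    normal   = optical_params(d = 0.10, theta_d = 0.17, cd = 0.05,
                              delta = 0.40, theta_r = 0.35, psi = 0.10,
                              a = 0.75, b = 0.70, c = 0.60),
    SCC      = optical_params(d = 0.30, theta_d = 0.87, cd = -0.18,
                              delta = 1.20, theta_r = 1.05, psi = -0.22,
                              a = 0.50, b = 0.45, c = 0.28)
  )
}

# between-sample and between-slice parameter jitter (sd per parameter)
.default_sample_sd <- c(d = 0.03, theta_d = 0.05, cd = 0.03, delta = 0.08,
                        theta_r = 0.05, psi = 0.04, a = 0.04, b = 0.04,
                        c = 0.04)

#' Per-class tissue specification for the generator
#'
#' @param label One of [tissue_classes()].
#' @param params Mean [optical_params()] of the class.
#' @param sample_sd Named per-parameter standard deviation of the
#'   between-sample draw.
#' @param slice_sd Between-slice perturbation sd (default `sample_sd / 4`).
#' @return An object of class `tissue_class_spec`.
#' @export
tissue_class_spec <- function(label, params,
                              sample_sd = .default_sample_sd,
                              slice_sd = sample_sd / 4) {
  stopifnot(label %in% tissue_classes(), inherits(params, "optical_params"))
  stopifnot(all(names(params) %in% names(sample_sd)))
  structure(list(label = label, params = params,
                 sample_sd = sample_sd, slice_sd = slice_sd),
            class = "tissue_class_spec")
}

#' Default tissue class specifications
#'
#' The shipped class-conditional generator settings. `separation` scales
#' every class mean towards (`separation = 0`) or away from the grand mean:
#' at 0 all four classes are identically distributed (a chance-level
#' control), at 1 (default) they are well separated.
#'
#' @param separation Non-negative class-separation multiplier.
#' @return Named list of four [tissue_class_spec()] objects.
#' @export
default_tissue_specs <- function(separation = 1) {
  stopifnot(is.numeric(separation), length(separation) == 1L, separation >= 0)
  means <- .class_param_means()
  pm <- sapply(means, unlist)          # 9 x 4 parameter matrix
  grand <- rowMeans(pm)
  out <- lapply(names(means), function(lab) {
    p <- grand + separation * (pm[, lab] - grand)
    tissue_class_spec(lab, do.call(optical_params, as.list(p)))
  })
  names(out) <- names(means)
  out
}

# default measurement layouts: per class, a list of per-sample integer
# vectors giving points per slice. Totals reproduce the study design
# (train 282/231/52/42, test 30/23/3/6; one held-out sample per class).
.default_layouts <- function() {
  list(
    BCC = list(
      train = c(rep(list(rep(5L, 5)), 10), list(c(5L, 5L, 5L, 5L, 6L, 6L))),
      test = list(rep(5L, 6))
    ),
    melanoma = list(
      train = list(c(4L, 4L, 4L, 5L), c(4L, 4L, 4L, 5L), c(4L, 4L, 5L, 5L)),
      test = list(3L)
    ),
    normal = list(
      train = rep(list(c(4L, 5L, 5L)), 3),
      test = list(6L)
    ),
    SCC = list(
      train = c(rep(list(rep(4L, 5)), 10), list(c(4L, 5L, 5L, 5L, 6L, 6L))),
      test = list(c(4L, 4L, 5L, 5L, 5L))
    )
  )
}

#' Configuration of a synthetic measurement campaign
#'
#' @param specs Named list of [tissue_class_spec()]s (default
#'   [default_tissue_specs()]).
#' @param layouts Per-class sampling layout: for each class, `train` and
#'   `test` lists of per-sample integer vectors of points per slice. The
#'   default reproduces the study design: 607 training and 62 testing
#'   feature vectors with per-class counts 282/52/42/231 (BCC/melanoma/
#'   normal/SCC) and 30/3/6/23, one held-out sample per class.
#' @param noise A [stokes_noise_model()] (or `NULL` for noiseless data).
#' @param seed Integer RNG seed; the whole campaign is deterministic given it.
#' @return An object of class `dataset_config`.
#' @export
dataset_config <- function(specs = default_tissue_specs(),
                           layouts = .default_layouts(),
                           noise = stokes_noise_model(),
                           seed = 1L) {
  stopifnot(setequal(names(specs), tissue_classes()),
            setequal(names(layouts), tissue_classes()))
  for (lab in names(layouts)) {
    lay <- layouts[[lab]]
    stopifnot(all(c("train", "test") %in% names(lay)))
    cnt <- unlist(lay)
    if (!length(cnt) || any(cnt < 1L)) {
      stop("layout for class ", lab, " must have positive point counts")
    }
  }
  structure(list(specs = specs, layouts = layouts, noise = noise,
                 seed = as.integer(seed)),
            class = "dataset_config")
}

#' Configuration of the chance-level control campaign
#'
#' A negative-control study design: class separation is set to zero (all
#' four classes identically distributed) and the held-out panel is widened
#' to `test_samples` independent samples per class of `points_per_sample`
#' measurement points each. Because points of one sample are strongly
#' correlated, the effective unit of the test-accuracy estimate is the
#' sample; the default 40 samples per class give the estimate a standard
#' error of about 0.035, small enough to resolve chance level (0.25) for
#' four balanced classes.
#'
#' @param seed RNG seed.
#' @param test_samples Held-out samples per class (default 40).
#' @param points_per_sample Points in each held-out sample (default 3).
#' @return A [dataset_config()] with zero-separation specs.
#' @export
chance_level_config <- function(seed = 1L, test_samples = 40L,
                                points_per_sample = 3L) {
  lay <- .default_layouts()
  for (lab in names(lay)) {
    lay[[lab]]$test <- rep(list(as.integer(points_per_sample)), test_samples)
  }
  dataset_config(specs = default_tissue_specs(0), layouts = lay, seed = seed)
}

# jitter a parameter vector and clamp it back into the valid domain
.jitter_params <- function(p, sd) {
  v <- unlist(p)
  v <- v + stats::rnorm(length(v), sd = sd[names(v)])
  v["d"] <- min(max(v["d"], 0), 0.95)
  v["cd"] <- min(max(v["cd"], -0.95), 0.95)
  tot <- sqrt(v["d"]^2 + v["cd"]^2)
  if (tot > 0.98) {
    v["d"] <- v["d"] * 0.98 / tot
    v["cd"] <- v["cd"] * 0.98 / tot
  }
  for (nm in c("a", "b", "c")) v[nm] <- min(max(v[nm], 0.02), 1)
  do.call(optical_params, as.list(v))
}

#' Simulate the raw six-state Stokes measurements of a campaign
#'
#' Hierarchical generation mirroring the physical sampling design: a
#' per-sample parameter draw around the class mean, a smaller per-slice
#' perturbation, and per-point Stokes measurement noise. Each measurement
#' point contributes six rows (one per input state).
#'
#' @param cfg A [dataset_config()].
#' @return A data frame with columns `partition` (train/test), `sample_id`,
#'   `slice_id`, `point_id`, `label`, `state`, `s0..s3`.
#' @export
generate_measurements <- function(cfg) {
  stopifnot(inherits(cfg, "dataset_config"))
  set.seed(cfg$seed)
  states <- names(input_states())
  rows <- list()
  for (lab in tissue_classes()) {
    spec <- cfg$specs[[lab]]
    lay <- cfg$layouts[[lab]]
    for (part in c("train", "test")) {
      samples <- lay[[part]]
      for (si in seq_along(samples)) {
        sid <- if (part == "test") {
          sprintf("%s_test%02d", lab, si)
        } else {
          sprintf("%s_s%02d", lab, si)
        }
        p_sample <- .jitter_params(spec$params, spec$sample_sd)
        for (sl in seq_along(samples[[si]])) {
          p_slice <- .jitter_params(p_sample, spec$slice_sd)
          m <- compose_sample_matrix(p_slice)
          for (pt in seq_len(samples[[si]][sl])) {
            ms <- measure_all_states(m, noise = cfg$noise)
            sv <- do.call(rbind, ms[states])
            rows[[length(rows) + 1L]] <- data.frame(
              partition = part, sample_id = sid, slice_id = sl,
              point_id = pt, label = lab, state = states,
              s0 = sv[, 1], s1 = sv[, 2], s2 = sv[, 3], s3 = sv[, 4],
              stringsAsFactors = FALSE, row.names = NULL
            )
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate a labeled synthetic feature dataset
#'
#' Runs [generate_measurements()] and reconstructs and normalizes every
#' measurement point into a 15-element feature vector (see
#' [reconstruct_from_measurements()]).
#'
#' @param cfg A [dataset_config()].
#' @return List with `train` and `test` feature data frames (columns
#'   `sample_id`, `slice_id`, `point_id`, `label`, then
#'   [mm_feature_names()]), plus the `measurements` data frame.
#' @export
generate_dataset <- function(cfg = dataset_config()) {
  meas <- generate_measurements(cfg)
  feats <- reconstruct_from_measurements(meas, quiet = TRUE)
  split_col <- meas$partition[match(
    paste(feats$sample_id, feats$slice_id, feats$point_id),
    paste(meas$sample_id, meas$slice_id, meas$point_id)
  )]
  list(
    train = feats[split_col == "train", , drop = FALSE],
    test = feats[split_col == "test", , drop = FALSE],
    measurements = meas
  )
}

# elements whose repeat-point spread the generator makes wide
.wide_band_elements <- c("m12", "m13", "m14", "m21", "m24", "m34")

#' Check the within-slice variability bands of a dataset
#'
#' For every normalized Mueller element, computes the mean over slices of the
#' within-slice (repeat measurement point) standard deviation, and compares
#' it against the expected bands: `[wide_lo, wide_hi]` for the six
#' high-variability elements `m12, m13, m14, m21, m24, m34` and below
#' `narrow_max` for the other nine.
#'
#' @param features Feature data frame as produced by [generate_dataset()].
#' @param wide_lo,wide_hi Band for the high-variability elements (default
#'   0.03-0.1).
#' @param narrow_max Upper bound for the remaining elements (default 0.01).
#' @return Data frame with one row per element: `element`, `band`,
#'   `mean_within_slice_sd`, `pass`; attribute `"pass"` gives the overall
#'   verdict.
#' @export
calibrate_noise_bands <- function(features, wide_lo = 0.03, wide_hi = 0.1,
                                  narrow_max = 0.01) {
  stopifnot(all(mm_feature_names() %in% names(features)))
  key <- interaction(features$sample_id, features$slice_id, drop = TRUE)
  sizes <- table(key)
  if (!any(sizes >= 2L)) {
    stop("need at least one slice with >= 2 measurement points")
  }
  keep <- key %in% names(sizes)[sizes >= 2L]
  out <- lapply(mm_feature_names(), function(el) {
    sds <- tapply(features[[el]][keep], droplevels(key[keep]), stats::sd)
    msd <- mean(sds)
    wide <- el %in% .wide_band_elements
    data.frame(
      element = el,
      band = if (wide) "wide" else "narrow",
      mean_within_slice_sd = msd,
      pass = if (wide) msd >= wide_lo && msd <= wide_hi else msd < narrow_max,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  attr(out, "pass") <- all(out$pass)
  out
}
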