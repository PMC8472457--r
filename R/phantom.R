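# Synthetic hepatic ischemia-reperfusion phantoms.
#
# The generator emulates the statistical structure the pipeline assumes:
# liver vs background spectra separable through haemoglobin absorption
# features, perfusion states spanning control / ischemia / reperfusion,
# specular highlights, an undecidable blur ring at the organ border, and
# biomarkers negatively coupled to oxygenation. Optics are deliberately
# simple - Gaussian chromophore bands under a Beer-Lambert exponential with
# a power-law scatter baseline - because the pipeline only relies on the
# *contrasts* between tissue states, not on absolute spectra.

#' Gaussian chromophore model for phantom spectra
#'
#' Haemoglobin optics are approximated by Gaussian absorption components at
#' the canonical oxyhaemoglobin (542, 577 nm) and deoxyhaemoglobin
#' (556, 760 nm) features, on top of a decreasing power-law scatter baseline.
#' Absorbance of a pixel with blood volume fraction `blood` and oxygen
#' fraction `f` is
#' `path_scale * blood * (f * eps_oxy + (1 - f) * eps_deoxy) + scatter`.
#'
#' @param oxy_peaks,deoxy_peaks Matrices with columns `center` (nm),
#'   `width` (nm), `amplitude` (a.u.), one row per Gaussian component.
#' @param scatter_slope Power-law exponent of the baseline.
#' @param scatter_amp Baseline amplitude at 500 nm.
#' @param path_scale Effective optical path factor.
#' @return A `chromophore_model`.
#' @export
chromophore_model <- function(
    oxy_peaks = rbind(c(542, 12, 1.00), c(577, 13, 0.95)),
    deoxy_peaks = rbind(c(556, 14, 1.05), c(760, 38, 0.35)),
    scatter_slope = 1.3, scatter_amp = 0.25, path_scale = 1.0) {
  for (pk in list(oxy_peaks, deoxy_peaks)) {
    if (any(pk[, 2] <= 0) || any(pk[, 3] < 0))
      lhsi_stop("peak widths must be > 0 and amplitudes >= 0",
                "lhsi_parameter_error")
  }
  structure(list(oxy_peaks = oxy_peaks, deoxy_peaks = deoxy_peaks,
                 scatter_slope = scatter_slope, scatter_amp = scatter_amp,
                 path_scale = path_scale),
            class = "chromophore_model")
}

gaussian_bands <- function(wl, peaks) {
  out <- numeric(length(wl))
  for (i in seq_len(nrow(peaks)))
    out <- out + peaks[i, 3] * exp(-(wl - peaks[i, 1])^2 / (2 * peaks[i, 2]^2))
  out
}

# Unit extinction spectra and scatter baseline on a wavelength vector.
model_spectra <- function(model, wl) {
  list(
    eps_oxy = gaussian_bands(wl, model$oxy_peaks),
    eps_deoxy = gaussian_bands(wl, model$deoxy_peaks),
    scatter = model$scatter_amp * (wl / 500)^(-model$scatter_slope)
  )
}

#' Perfusion state of a phantom subject at one timepoint
#'
#' Encodes the haemoglobin oxygen fraction and a congestion level driving the
#' biomarker surrogates. Injury trajectories ramp the liver from perfused
#' (control) down through 90 min of ischemia, transiently recover on early
#' reperfusion, then deteriorate again towards 5 h (reperfusion injury); the
#' recovery trajectory stays perfused throughout reperfusion.
#'
#' @param name One of `"control"`, `"isch30"`, `"isch60"`, `"isch90"`,
#'   `"rep1h"` ... `"rep5h"`.
#' @param trajectory `"injury"` or `"recovery"`; only affects reperfusion
#'   timepoints.
#' @return A `perfusion_state` with fields `name`, `oxygen_fraction`,
#'   `congestion`.
#' @export
perfusion_state <- function(name, trajectory = c("injury", "recovery")) {
  trajectory <- match.arg(trajectory)
  # no state sits at the 0.5 tissue-truth threshold: with the +/-0.06
  # spatial oxygen field, every state is unambiguously perfused (> 0.56)
  # or ischemic (< 0.47), so ground-truth labels are never knife-edge
  tab <- list(
    control = c(0.95, 0.0), isch30 = c(0.40, 1.0),
    isch60 = c(0.30, 1.5), isch90 = c(0.15, 2.0),
    rep1h = c(0.85, 0.5), rep2h = c(0.65, 1.0), rep3h = c(0.40, 1.5),
    rep4h = c(0.30, 2.0), rep5h = c(0.18, 2.5)
  )
  if (!name %in% names(tab))
    lhsi_stop(paste("unknown perfusion state:", name), "lhsi_parameter_error")
  v <- tab[[name]]
  if (trajectory == "recovery" && startsWith(name, "rep"))
    v <- c(0.90, 0.2)
  structure(list(name = name, trajectory = trajectory,
                 oxygen_fraction = v[1], congestion = v[2]),
            class = "perfusion_state")
}

#' Biomarker surrogates for a perfusion state
#'
#' Capillary lactate follows the linear model
#' `lactate = 8 - 7 * oxygen_fraction + eps`, `eps ~ N(0, noise_sd)`, clipped
#' below at 0.5 mmol/L (fully oxygenated tissue gives 1.0 mmol/L at zero
#' noise). The histological injury surrogate is
#' `round(4 * (1 - oxygen_fraction) + 0.25 * congestion + eta)` clipped to
#' `[0, 4]`, with `eta ~ N(0, 0.25)`.
#'
#' @param state A [perfusion_state()].
#' @param noise_sd Lactate noise standard deviation in mmol/L (default 0.8).
#' @param seed RNG seed.
#' @return List with `lactate` (mmol/L) and `suzuki` (integer 0-4).
#' @export
biomarkers <- function(state, noise_sd = 0.8, seed = 1) {
  stopifnot(inherits(state, "perfusion_state"))
  if (noise_sd < 0)
    lhsi_stop("noise_sd must be >= 0", "lhsi_parameter_error")
  f <- state$oxygen_fraction
  with_local_seed(seed, {
    lactate <- max(0.5, 8 - 7 * f + rnorm(1, 0, noise_sd))
    eta <- if (noise_sd > 0) rnorm(1, 0, 0.25) else 0
    suzuki <- min(4L, max(0L,
      as.integer(round(4 * (1 - f) + 0.25 * state$congestion + eta))))
    list(lactate = lactate, suzuki = suzuki)
  })
}

# Run expr under a fixed seed without disturbing the caller's RNG stream.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Smooth low-frequency random field in [-1, 1]-ish range, H x W.
smooth_field <- function(H, W, n_modes = 4) {
  r <- matrix(rep(seq_len(H) / H, W), H, W)
  c <- matrix(rep(seq_len(W) / W, each = H), H, W)
  fld <- matrix(0, H, W)
  for (k in seq_len(n_modes)) {
    fr <- runif(2, 0.5, 2.5)
    ph <- runif(1, 0, 2 * pi)
    fld <- fld + rnorm(1, 0, 1) * sin(2 * pi * (fr[1] * r + fr[2] * c) + ph)
  }
  fld / sqrt(n_modes)
}

#' Generate one synthetic subject scene
#'
#' Builds a hypercube with a smooth random liver blob over a two-family
#' background (a blood-bearing bowel-like tissue and a pale fat-like tissue),
#' multiplicative speckle and additive sensor noise, saturated specular discs
#' inside and outside the organ, and aligned ground-truth masks. The organ
#' boundary carries a 0-labelled ring (default 2 px wide) emulating the
#' optical blur that makes border labels undecidable. The tissue
#' ground truth is +1 (ischemic) wherever the local oxygen fraction falls
#' below 0.5 and -1 (perfused) elsewhere within the organ.
#'
#' @param shape `c(H, W)` spatial size, both at least 32. Default 96 x 96:
#'   full-camera 640 x 480 frames are supported but not the default, which is
#'   sized for single-CPU experimentation.
#' @param state A [perfusion_state()] (or state name).
#' @param trajectory Trajectory used when `state` is given by name.
#' @param liver_fraction Target organ area fraction, in (0.05, 0.9).
#' @param seed RNG seed; scenes are bit-reproducible given the seed.
#' @param model A [chromophore_model()].
#' @param grid A [wavelength_grid()].
#' @param ring_width Width (px) of the 0-labelled border ring.
#' @param speckle_sd,additive_sd Noise levels (multiplicative, additive).
#' @param gain Global reflectance gain (per-subject offsets in cohorts).
#' @param subject_id Identifier stored in the cube.
#' @return A `phantom_scene`: list with `cube`, `liver_mask`, `tissue_mask`,
#'   `state`, `lactate`, `suzuki`, `mean_oxygen`, `seed`.
#' @export
make_scene <- function(shape = c(96, 96), state = "control",
                       trajectory = "injury",
                       liver_fraction = 0.30, seed = 1,
                       model = chromophore_model(),
                       grid = wavelength_grid(), ring_width = 2,
                       speckle_sd = 0.02, additive_sd = 0.004,
                       gain = 1.0, subject_id = "S1") {
  H <- shape[1]; W <- shape[2]
  if (H < 32 || W < 32)
    lhsi_stop("scene must be at least 32 x 32", "lhsi_parameter_error")
  if (liver_fraction <= 0.05 || liver_fraction >= 0.9)
    lhsi_stop("liver_fraction must lie in (0.05, 0.9)", "lhsi_parameter_error")
  if (is.character(state)) state <- perfusion_state(state, trajectory)
  wl <- wavelengths(grid)
  B <- grid$n_bands

  with_local_seed(seed, {
    sp <- model_spectra(model, wl)
    # --- liver blob: star-convex smooth random shape -----------------------
    cy <- H / 2 + runif(1, -0.05, 0.05) * H
    cx <- W / 2 + runif(1, -0.05, 0.05) * W
    bm <- rnorm(4, 0, 0.08); phm <- runif(4, 0, 2 * pi)
    shape_fun <- function(theta) {
      s <- rep(1, length(theta))
      for (m in 1:4) s <- s + bm[m] * cos(m * theta + phm[m])
      pmax(s, 0.3)
    }
    th_grid <- seq(0, 2 * pi, length.out = 721)[-721]
    mean_s2 <- mean(shape_fun(th_grid)^2)
    r0 <- sqrt(liver_fraction * H * W / (pi * mean_s2))
    r0_cap <- 0.47 * min(H, W) / max(shape_fun(th_grid))
    rr <- matrix(rep(seq_len(H), W), H, W) - cy
    cc <- matrix(rep(seq_len(W), each = H), H, W) - cx
    dist <- sqrt(rr^2 + cc^2)
    theta <- atan2(cc, rr)
    # calibrate r0 so the *labelled* positive fraction (ring excluded) hits
    # the target despite the 0-ring eating into the blob edge
    for (it in 1:3) {
      r0 <- min(r0, r0_cap)
      rboundary <- r0 * shape_fun(theta)
      inside <- dist <= rboundary
      ring <- abs(dist - rboundary) <= ring_width
      pos_frac <- sum(inside & !ring) / (H * W)
      if (r0 >= r0_cap || abs(pos_frac - liver_fraction) < 0.01) break
      r0 <- r0 * sqrt(max(liver_fraction, 1e-3) / max(pos_frac, 1e-3))
    }

    liver_lab <- matrix(-1L, H, W)
    liver_lab[inside] <- 1L
    liver_lab[ring] <- 0L

    # --- oxygenation field and tissue ground truth -------------------------
    oxy_field <- pmin(pmax(
      state$oxygen_fraction + 0.06 * smooth_field(H, W), 0), 1)
    tissue_lab <- matrix(0L, H, W)
    core <- inside & !ring                     # tissue truth excludes the ring
    tissue_lab[core] <- ifelse(oxy_field[core] < 0.5, 1L, -1L)

    # --- spectra ------------------------------------------------------------
    refl <- matrix(0, H * W, B)
    liv_idx <- which(inside)
    blood_liv <- 0.8 * (1 + 0.15 * smooth_field(H, W))
    fvec <- oxy_field[liv_idx]
    bl <- blood_liv[liv_idx]
    A_liv <- outer(bl * fvec, sp$eps_oxy) +
      outer(bl * (1 - fvec), sp$eps_deoxy)
    A_liv <- model$path_scale * A_liv +
      matrix(sp$scatter, length(liv_idx), B, byrow = TRUE)
    refl[liv_idx, ] <- exp(-A_liv)

    # background: family split by a smooth field
    bg_idx <- which(!inside)
    fam <- smooth_field(H, W) > 0
    bowel <- model_spectra(chromophore_model(
      scatter_slope = 1.0, scatter_amp = 0.30,
      path_scale = model$path_scale), wl)
    fat_peaks <- rbind(c(930, 25, 0.15))
    A_fat <- 0.15 * (wl / 500)^(-0.6) + gaussian_bands(wl, fat_peaks)
    for (grp in list(TRUE, FALSE)) {
      idx <- bg_idx[fam[bg_idx] == grp]
      if (!length(idx)) next
      if (isTRUE(grp)) {
        blood_bg <- 0.37 * (1 + 0.2 * runif(length(idx), -1, 1))
        A <- outer(blood_bg * 0.7, bowel$eps_oxy) +
          outer(blood_bg * 0.3, bowel$eps_deoxy) +
          matrix(bowel$scatter, length(idx), B, byrow = TRUE)
      } else {
        g <- 1 + 0.1 * runif(length(idx), -1, 1)
        A <- outer(g, A_fat)
      }
      refl[idx, ] <- exp(-A)
    }

    # --- noise ---------------------------------------------------------------
    refl <- refl * (1 + speckle_sd * matrix(rnorm(H * W * B), H * W, B))
    refl <- refl + additive_sd * matrix(rnorm(H * W * B), H * W, B)

    # --- specular highlights -------------------------------------------------
    n_spec <- sample(2:5, 1)                    # at least one in, one out
    centers <- matrix(0, n_spec, 2)
    centers[1, ] <- pick_pixel(inside)
    centers[2, ] <- pick_pixel(!inside)
    if (n_spec >= 3)
      for (k in 3:n_spec)
        centers[k, ] <- c(sample(H, 1), sample(W, 1))
    spec_mask <- matrix(FALSE, H, W)
    for (k in seq_len(n_spec)) {
      rad <- sample(1:3, 1)
      spec_mask <- spec_mask |
        ((matrix(rep(seq_len(H), W), H, W) - centers[k, 1])^2 +
           (matrix(rep(seq_len(W), each = H), H, W) - centers[k, 2])^2
         <= rad^2)
    }
    refl[which(spec_mask), ] <- 1.4

    refl <- pmin(pmax(refl * gain, 0), 1.5)
    cube <- hypercube(array(refl, c(H, W, B)), grid,
                      subject_id = subject_id, timepoint = state$name)
    bio <- biomarkers(state, noise_sd = 0.8, seed = seed + 31L)
    structure(list(
      cube = cube,
      liver_mask = label_mask(liver_lab),
      tissue_mask = label_mask(tissue_lab),
      state = state,
      lactate = bio$lactate, suzuki = bio$suzuki,
      mean_oxygen = mean(oxy_field[inside]),
      seed = seed
    ), class = "phantom_scene")
  })
}

pick_pixel <- function(mask) {
  idx <- which(mask)
  i <- idx[sample(length(idx), 1)]
  c((i - 1) %% nrow(mask) + 1, (i - 1) %/% nrow(mask) + 1)
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf(
    "<phantom_scene> %s/%s  %dx%d  f=%0.2f  lactate=%.2f  suzuki=%d\n",
    x$cube$subject_id, x$state$name, nrow(x$liver_mask), ncol(x$liver_mask),
    x$state$oxygen_fraction, x$lactate, x$suzuki))
  invisible(x)
}

#' Generate a synthetic cohort
#'
#' Each subject receives a random spectral offset (global gain, chromophore
#' peak-centre jitter, and optical path jitter) so that cross-subject
#' generalization is non-trivial, then one scene per requested timepoint.
#' By default the last subject follows the `"recovery"` trajectory, emulating
#' a benign course after reperfusion; all others follow `"injury"`.
#'
#' @param n_subjects Number of subjects (at least 2; leave-one-out is
#'   impossible below that).
#' @param timepoints Character vector of state names,
#'   e.g. `c("control", "isch30", "isch60", "isch90")` (the default).
#' @param trajectories Per-subject trajectory; default
#'   `c(rep("injury", n - 1), "recovery")`.
#' @param seed Cohort seed; every scene seed derives from it.
#' @param shape,liver_fraction,ring_width Passed to [make_scene()].
#' @return A `phantom_cohort`: list of subjects, each with `subject_id`,
#'   `trajectory`, `gain`, `model`, and `scenes` (named by timepoint).
#' @export
make_cohort <- function(n_subjects = 5,
                        timepoints = c("control", "isch30", "isch60", "isch90"),
                        trajectories = NULL, seed = 1,
                        shape = c(96, 96), liver_fraction = 0.30,
                        ring_width = 2) {
  if (n_subjects < 2)
    lhsi_stop("need at least 2 subjects for leave-one-out work",
              "lhsi_parameter_error")
  if (is.null(trajectories))
    trajectories <- c(rep("injury", n_subjects - 1), "recovery")
  stopifnot(length(trajectories) == n_subjects)
  base <- as.integer(seed) %% 100000L
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    subj_seed <- base * 10000L + s * 131L
    off <- with_local_seed(subj_seed, {
      list(gain = rnorm(1, 1, 0.02),
           jitter = rnorm(1, 0, 0.75),
           path = rnorm(1, 1, 0.04))
    })
    mdl <- chromophore_model()
    mdl$oxy_peaks[, 1] <- mdl$oxy_peaks[, 1] + off$jitter
    mdl$deoxy_peaks[, 1] <- mdl$deoxy_peaks[, 1] + off$jitter
    mdl$path_scale <- mdl$path_scale * off$path
    scenes <- list()
    for (t in seq_along(timepoints)) {
      scenes[[timepoints[t]]] <- make_scene(
        shape = shape,
        state = perfusion_state(timepoints[t], trajectories[s]),
        liver_fraction = liver_fraction,
        seed = subj_seed + t,
        model = mdl, ring_width = ring_width,
        gain = max(0.8, off$gain),
        subject_id = sprintf("S%d", s))
    }
    subjects[[s]] <- list(subject_id = sprintf("S%d", s),
                          trajectory = trajectories[s],
                          gain = off$gain, model = mdl, scenes = scenes)
  }
  structure(list(subjects = subjects, seed = seed,
                 timepoints = timepoints),
            class = "phantom_cohort")
}

#' @export
print.phantom_cohort <- function(x, ...) {
  cat(sprintf("<phantom_cohort> %d subjects x %d timepoints (seed %s)\n",
              length(x$subjects), length(x$timepoints), format(x$seed)))
  invisible(x)
}

#' Thin out a label mask for desk-scale training
#'
#' Keeps at most `n_per_class` randomly chosen pixels of each of the +1 and
#' -1 classes and sets every other pixel to 0 (ignored). Used to bound
#' single-CPU training cost; the without-replacement epoch semantics then
#' apply to the retained pixels.
#'
#' @param mask A [label_mask()].
#' @param n_per_class Maximum labelled pixels kept per class.
#' @param seed RNG seed.
#' @return A [label_mask()].
#' @export
label_subsample <- function(mask, n_per_class, seed = 1) {
  stopifnot(inherits(mask, "label_mask"))
  out <- matrix(0L, nrow(mask), ncol(mask))
  with_local_seed(seed, {
    for (cl in c(1L, -1L)) {
      idx <- which(mask == cl)
      if (length(idx) > n_per_class)
        idx <- sample(idx, n_per_class)
      out[idx] <- cl
    }
  })
  label_mask(out)
}
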