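#' Draw a class-conditional synthetic case specification
#'
#' Kinetic contrast follows the clinical enhancement patterns that drive the
#' benign/malignant distinction: malignant lesions show arterial
#' hyperenhancement (early onset, high peak, lognormal bolus) followed by
#' washout below the surrounding parenchyma in the late phase; benign
#' lesions enhance early and sustain (a near-flat slow gamma-variate), never
#' dropping below parenchyma. Parenchyma itself follows a sustained
#' gamma-variate of moderate amplitude in both classes.
#'
#' Default ranges (all uniform draws, intensities on the 0-255 grayscale):
#' onset 6-10 s; malignant peak 90-120 at 8-14 s post onset (lognormal sigma
#' 0.45-0.65); benign plateau 55-75 (gamma alpha 0.03-0.08, beta 3000-5000 s);
#' parenchyma plateau 30-45; baseline 1-5; speckle CV 0.05 plus a static
#' tissue texture CV 0.03; respiratory motion 1-3 px amplitude, 3-5 s
#' period; 3 out-of-plane dropout frames retaining 60% intensity.
#'
#' @param label `"benign"` or `"malignant"`.
#' @param seed RNG seed; the spec is a pure function of `(label, seed)`.
#' @param ... overrides for any spec field (e.g. `duration_s`,
#'   `frame_rate_hz`, `panel_shape`, `dropout`, `onset_range`,
#'   `speckle_cv`, `tex_cv`, `motion`).
#' @return An object of class `synthetic_spec`.
#' @export
sample_case_spec <- function(label = c("benign", "malignant"), seed = 1L,
                             ...) {
  label <- match.arg(label)
  overrides <- list(...)
  spec <- .with_seed(seed, {
    onset_range <- overrides$onset_range %||% c(6, 10)
    t0 <- stats::runif(1, onset_range[1], onset_range[2])
    baseline <- stats::runif(1, 1, 5)
    if (label == "malignant") {
      ttp <- stats::runif(1, 8, 14)
      sigma <- stats::runif(1, 0.45, 0.65)
      mu <- log(ttp) + sigma^2 # mode at ttp
      peak <- stats::runif(1, 90, 120)
      dmax <- stats::dlnorm(exp(mu - sigma^2), mu, sigma)
      lesion <- list(model_id = "lognormal",
                     params = list(t0 = t0, baseline = baseline,
                                   auc = peak / dmax, mu = mu, sigma = sigma))
    } else {
      alpha <- stats::runif(1, 0.03, 0.08)
      beta <- stats::runif(1, 3000, 5000)
      plateau <- stats::runif(1, 55, 75)
      lesion <- list(model_id = "gamma_variate",
                     params = .gamma_from_plateau(t0, baseline, alpha, beta,
                                                  plateau, at = 160))
    }
    bg_alpha <- stats::runif(1, 0.03, 0.08)
    bg_beta <- stats::runif(1, 3000, 5000)
    bg_plateau <- stats::runif(1, 30, 45)
    background <- list(model_id = "gamma_variate",
                       params = .gamma_from_plateau(t0 + stats::runif(1, 1, 3),
                                                    baseline, bg_alpha,
                                                    bg_beta, bg_plateau,
                                                    at = 160))
    panel <- overrides$panel_shape %||% c(192L, 256L)
    a <- stats::runif(1, 0.07, 0.11) * panel[2]
    b <- a * stats::runif(1, 0.65, 0.9)
    list(label = label,
         lesion_kinetics = lesion,
         background_kinetics = background,
         frame_rate_hz = 1,
         duration_s = 180,
         panel_shape = as.integer(panel),
         lesion_center = c(x = round(panel[2] / 2), y = round(panel[1] / 2)),
         lesion_axes_px = c(a = a, b = b),
         mm_per_px = 0.5,
         motion = list(amplitude_px = stats::runif(1, 1, 3),
                       period_s = stats::runif(1, 3, 5)),
         dropout = list(count = 3L, intensity_factor = 0.6),
         speckle_cv = 0.05,
         tex_cv = 0.03,
         seed = as.integer(seed))
  })
  keep <- setdiff(names(overrides), c("onset_range"))
  for (nm in keep) spec[[nm]] <- overrides[[nm]]
  structure(spec, class = "synthetic_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# gamma-variate params hitting a target plateau intensity at t' = at
.gamma_from_plateau <- function(t0, baseline, alpha, beta, plateau, at = 160) {
  A <- plateau / (at^alpha * exp(-at / beta))
  auc <- A * beta^(alpha + 1) * gamma(alpha + 1)
  list(t0 = t0, baseline = baseline, auc = auc, alpha = alpha, beta = beta)
}

# evaluate a kinetics element at times t
.kinetics_at <- function(k, t) model_curve(k$model_id, k$params, t)

#' Render a synthetic dual-panel CEUS loop
#'
#' Per frame, lesion-ellipse pixels follow the lesion kinetics and the rest
#' of the panel the parenchyma kinetics; the scene is multiplied by a static
#' tissue texture (fixed multiplicative pattern), translated vertically by a
#' sinusoidal respiratory offset, multiplied by temporal speckle (mean-1
#' Gaussian, CV `speckle_cv`), and dropout frames lose the stated fraction
#' of the whole contrast panel. The B-mode half is a static texture. Pixels
#' are quantised to 8-bit.
#'
#' @param spec a [sample_case_spec()] result.
#' @return `list(loop, annotation, truth)`: the [ceus_loop()], the
#'   marker-derived [lesion_annotation()], and a ground-truth list (true
#'   per-region TICs, true perfusion parameters, dropout frame indices,
#'   onset, an inner all-lesion box for exact TIC checks, label).
#' @export
render_loop <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  H <- spec$panel_shape[1L]; Wc <- spec$panel_shape[2L]
  cx <- spec$lesion_center[["x"]]; cy <- spec$lesion_center[["y"]]
  a <- spec$lesion_axes_px[["a"]]; b <- spec$lesion_axes_px[["b"]]
  if (cx - a < 1 || cx + a > Wc - 2 || cy - b < 1 || cy + b > H - 2)
    stop("lesion ellipse outside the CEUS panel")
  times <- seq(0, spec$duration_s, by = 1 / spec$frame_rate_hz)
  nf <- length(times)

  .with_seed(spec$seed + 7L, {
    les <- .kinetics_at(spec$lesion_kinetics, times)
    bg <- .kinetics_at(spec$background_kinetics, times)
    xs <- matrix(rep(0:(Wc - 1L), each = H), H)
    ys <- matrix(rep(0:(H - 1L), Wc), H)
    mask <- ((xs - cx) / a)^2 + ((ys - cy) / b)^2 <= 1
    tex <- 1 + spec$tex_cv * matrix(stats::rnorm(H * Wc), H)
    tex <- pmax(tex, 0.2)
    bmode <- matrix(stats::runif(H * Wc, 40, 200), H)

    onset <- spec$lesion_kinetics$params$t0
    eligible <- which(times > onset + 20)
    ndrop <- min(spec$dropout$count, length(eligible))
    drop_idx <- sort(sample(eligible, ndrop))

    amp <- spec$motion$amplitude_px; per <- spec$motion$period_s
    px <- array(0, c(H, 2L * Wc, nf))
    for (i in seq_len(nf)) {
      scene <- matrix(bg[i], H, Wc)
      scene[mask] <- les[i]
      scene <- scene * tex
      dy <- round(amp * sin(2 * pi * times[i] / per))
      if (dy != 0) { # vertical translation, edge replication
        if (dy > 0) scene <- scene[c(rep(1L, dy), 1:(H - dy)), ]
        else scene <- scene[c((1 - dy):H, rep(H, -dy)), ]
      }
      if (spec$speckle_cv > 0)
        scene <- scene * pmax(1 + spec$speckle_cv *
                                matrix(stats::rnorm(H * Wc), H), 0)
      if (i %in% drop_idx) scene <- scene * spec$dropout$intensity_factor
      frame <- cbind(scene, bmode)
      px[, , i] <- pmin(pmax(round(frame), 0), 255)
    }

    loop <- ceus_loop(px, times, layout = "ceus_left",
                      source_id = sprintf("synthetic_%s_%d", spec$label,
                                          spec$seed))
    ann_frame <- which.min(abs(times - (onset + 15)))
    markers <- rbind(c(cx - a, cy), c(cx + a, cy),
                     c(cx, cy - b), c(cx, cy + b))
    ann <- lesion_annotation(ann_frame - 1L, markers,
                             long_axis_mm = 2 * a * spec$mm_per_px,
                             short_axis_mm = 2 * b * spec$mm_per_px)
    true_fit <- new_perfusion_fit(spec$lesion_kinetics$model_id,
                                  spec$lesion_kinetics$params, 0,
                                  range(times))
    # axis-aligned box inscribed in the ellipse: every pixel is lesion
    ix0 <- ceiling(cx - a / sqrt(2))
    iy0 <- ceiling(cy - b / sqrt(2))
    inner <- roi_box(ix0, iy0,
                     max(floor(cx + a / sqrt(2)), ix0 + 1L),
                     max(floor(cy + b / sqrt(2)), iy0 + 1L))
    truth <- list(label = ifelse(spec$label == "malignant", 1L, 0L),
                  lesion_tic = les, background_tic = bg, times_s = times,
                  dropout_indices = drop_idx, onset_s = onset,
                  true_parameters = derive_parameters(true_fit,
                                                      2 * a * spec$mm_per_px),
                  inner_box = inner, spec = spec)
    list(loop = loop, annotation = ann, truth = truth)
  })
}

#' Generate a synthetic cohort on disk
#'
#' Writes one multiframe DICOM loop, one sidecar annotation JSON and one
#' ground-truth JSON per case, plus a manifest CSV. Fully reproducible: the
#' same seed yields byte-identical manifests and files.
#'
#' @param n_benign,n_malignant cases per class (>= 1).
#' @param out_dir output directory (created if needed).
#' @param seed master seed; per-case seeds derive from it.
#' @param ... spec overrides forwarded to [sample_case_spec()].
#' @return The manifest `data.frame` (invisibly written to
#'   `manifest.csv`).
#' @export
generate_dataset <- function(n_benign, n_malignant, out_dir, seed = 1L, ...) {
  stopifnot(n_benign >= 1L, n_malignant >= 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- n_benign + n_malignant
  labels <- rep(c("benign", "malignant"), c(n_benign, n_malignant))
  case_seeds <- .with_seed(seed, sample.int(2^30, n))
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    case_id <- sprintf("case_%03d", i)
    spec <- sample_case_spec(labels[i], seed = case_seeds[i], ...)
    r <- render_loop(spec)
    dcm <- file.path(out_dir, paste0(case_id, ".dcm"))
    annp <- file.path(out_dir, paste0(case_id, "_annotation.json"))
    trup <- file.path(out_dir, paste0(case_id, "_truth.json"))
    write_ceus_loop(r$loop, dcm,
                    instance_uid = paste0(.DICOM_UID_ROOT, ".2.", seed,
                                          ".", i))
    write_annotation(r$annotation, annp)
    tr <- r$truth
    jsonlite::write_json(
      list(label = tr$label, onset_s = tr$onset_s,
           dropout_indices = tr$dropout_indices,
           lesion_model = spec$lesion_kinetics$model_id,
           lesion_params = spec$lesion_kinetics$params,
           background_model = spec$background_kinetics$model_id,
           background_params = spec$background_kinetics$params,
           case_seed = case_seeds[i]),
      trup, auto_unbox = TRUE, digits = NA)
    rows[[i]] <- data.frame(case_id = case_id, label = tr$label,
                            class = labels[i], dicom = basename(dcm),
                            annotation = basename(annp),
                            truth = basename(trup),
                            case_seed = case_seeds[i])
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

# least-squares slope of the true lesion TIC over the late phase; used by
# tests of the class-conditional sampling ranges
.true_late_slope <- function(truth, lp_start_offset = 120) {
  t <- truth$times_s
  sel <- t >= truth$onset_s + lp_start_offset
  stats::coef(stats::lm(truth$lesion_tic[sel] ~ t[sel]))[[2L]]
}
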