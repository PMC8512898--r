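#' Default pipeline configuration
#'
#' Nested settings for every stage, in the shape accepted by the CLI's
#' config file. Flags and function arguments override these values.
#'
#' @return nested list of defaults.
#' @export
default_config <- function() {
  list(
    io = list(side = 192L, crop = "center"),
    clahe = list(tiles_x = 8L, tiles_y = 8L, clip_limit = 0.01, range = "full"),
    fag = list(gamma_min = 0.1, gamma_max = 10),
    fhh = list(hedge = 1.5),
    fusion = list(w0 = 0.5, alpha = 7, beta = 0.01, alpha_inside = FALSE),
    segmentation = list(sigma = 2, kernel_length = 9L, n_orientations = 12L,
                        c_thresh = 4.5, mean_window = 13L, min_object = 30L,
                        opening_radius = 0L)
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(override[[k]]) && is.list(base[[k]])) {
      base[[k]] <- merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Enhancement techniques known to the pipeline
#' @export
TECHNIQUES <- c("none", "clahe", "fhh", "agc", "fag", "wavg_fusion", "improved_fusion")

resolve_profile <- function(img, profile) {
  if (profile == "auto") classify_brightness(img)$label else profile
}

#' Apply an enhancement technique to one image
#'
#' Dispatches on `technique`. The fusion techniques run CLAHE and FAG on
#' the input independently and combine them; `improved_fusion` uses the
#' improved weighted average whose `alpha` depends on the brightness
#' profile (bright: 7, dark: 1), selected automatically when
#' `profile = "auto"`.
#'
#' @param img a `gray_image`.
#' @param technique one of `r paste0('\x60', TECHNIQUES, '\x60', collapse = ", ")`.
#' @param profile `"auto"` (classify by mean intensity), `"bright"` or
#'   `"dark"`.
#' @param config nested configuration (see [default_config()]); partial
#'   lists are merged over the defaults.
#' @return list with `image` (enhanced `gray_image`) and `settings` (the
#'   effective technique, profile and parameter values).
#' @export
enhance_image <- function(img, technique = "improved_fusion",
                          profile = c("auto", "bright", "dark"),
                          config = list()) {
  profile <- match.arg(profile)
  technique <- match.arg(technique, TECHNIQUES)
  cfg <- merge_config(default_config(), config)
  prof <- resolve_profile(img, profile)

  cp <- clahe_params(cfg$clahe$tiles_x, cfg$clahe$tiles_y,
                     cfg$clahe$clip_limit, cfg$clahe$range)
  # alpha follows the brightness profile unless the caller set it explicitly
  alpha <- if (!is.null(config$fusion$alpha)) cfg$fusion$alpha
           else if (prof == "bright") 7 else 1
  fuse_p <- fusion_params(w0 = cfg$fusion$w0, alpha = alpha,
                          beta = cfg$fusion$beta,
                          alpha_inside = cfg$fusion$alpha_inside)

  out <- switch(
    technique,
    none = img,
    clahe = apply_clahe(img, cp),
    fhh = apply_fhh(img, cfg$fhh$hedge),
    agc = apply_agc_gray(img, cfg$fag$gamma_min, cfg$fag$gamma_max),
    fag = apply_fag(img, cfg$fag$gamma_min, cfg$fag$gamma_max),
    wavg_fusion = weighted_average(
      apply_clahe(img, cp),
      apply_fag(img, cfg$fag$gamma_min, cfg$fag$gamma_max),
      w0 = cfg$fusion$w0),
    improved_fusion = improved_weighted_average(
      apply_clahe(img, cp),
      apply_fag(img, cfg$fag$gamma_min, cfg$fag$gamma_max),
      fuse_p)
  )
  settings <- list(technique = technique, profile = prof,
                   clahe = cfg$clahe, fag = cfg$fag, fhh = cfg$fhh,
                   fusion = list(w0 = fuse_p$w0, alpha = fuse_p$alpha,
                                 beta = fuse_p$beta,
                                 alpha_inside = fuse_p$alpha_inside))
  list(image = out, settings = settings)
}

seg_params_from_config <- function(cfg) {
  s <- cfg$segmentation
  mf_fodg_params(sigma = s$sigma, kernel_length = s$kernel_length,
                 n_orientations = s$n_orientations, c_thresh = s$c_thresh,
                 mean_window = s$mean_window, min_object = s$min_object,
                 opening_radius = s$opening_radius)
}

#' Enhance then segment one image
#'
#' @inheritParams enhance_image
#' @return list with `mask` (a `seg_mask`), `image` (the enhanced image)
#'   and `settings`.
#' @export
segment_image <- function(img, technique = "none",
                          profile = c("auto", "bright", "dark"),
                          config = list()) {
  cfg <- merge_config(default_config(), config)
  enh <- tryCatch(
    enhance_image(img, technique, profile, config),
    error = function(e) {
      if (grepl("degenerate input", conditionMessage(e))) {
        warning("constant image: enhancement skipped, input passed through")
        list(image = img,
             settings = list(technique = technique, profile = "n/a"))
      } else stop(e)
    })
  mask <- segment_veins(enh$image, seg_params_from_config(cfg))
  list(mask = mask, image = enh$image, settings = enh$settings)
}

#' Evaluate enhancement quality and segmentation scores for one image set
#'
#' @param original the original `gray_image`.
#' @param enhanced the enhanced `gray_image` (may equal `original`).
#' @param mask predicted `seg_mask` (or `NULL` to skip segmentation scores).
#' @param truth ground-truth `seg_mask` (or `NULL`).
#' @return one-row data.frame with columns `mse`, `psnr`, `ssim`, `se`,
#'   `acc`, `dice`.
#' @export
evaluate_pair <- function(original, enhanced, mask = NULL, truth = NULL) {
  q <- quality_metrics(original, enhanced)
  s <- if (!is.null(mask) && !is.null(truth)) seg_scores(confusion(mask, truth))
       else list(se = NA_real_, acc = NA_real_, dice = NA_real_)
  data.frame(mse = q$mse, psnr = q$psnr, ssim = q$ssim,
             se = s$se, acc = s$acc, dice = s$dice)
}
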