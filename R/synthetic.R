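#' Default configuration of a synthetic storage study
#'
#' Encodes the design of the emulated experiment: three open-storage
#' humidities (11, 32, 65% ERH) at 20 degC, three replicate trays, sorption
#' isotherm measured over a_w 0–0.9 in 0.1 steps, calorimetric T_g points at
#' the seven salt-solution humidities (1, 11, 23, 32, 43, 54, 65% ERH), and
#' per-condition kinetic parameters for moisture uptake (day^-1), dissolution
#' absorbance at 420 nm (s^-1) and brew pH decay (day^-1; the printed rates
#' of such studies are scaled by 1e4, so the physical defaults here are the
#' tabulated values times 1e-4). Noise SDs default to the replicate scatter
#' reported for each response.
#'
#' @param seed Integer seed; mandatory for any stochastic output.
#' @param erh_levels Storage humidities, percent.
#' @param T_storage Storage temperature, degC.
#' @param replicates Replicate trays per condition.
#' @return A list of class `study_config`.
#' @export
study_config <- function(seed, erh_levels = c(11, 32, 65), T_storage = 20,
                         replicates = 3) {
  if (missing(seed) || !is.numeric(seed))
    stop("'seed' is mandatory", call. = FALSE)
  if (any(erh_levels <= 0) || any(erh_levels >= 100))
    stop("'erh_levels' must lie in (0, 100)", call. = FALSE)
  cfg <- list(
    seed = as.integer(seed),
    erh_levels = erh_levels,
    T_storage = T_storage,
    replicates = replicates,
    gab = gab_params(m0 = 0.06, C = 1.10, b = 0.99),
    gt = gordon_taylor_params(Tgi = 47.8, epsilon = 7.2, Tgw = -135),
    tg_erh_levels = c(1, 11, 23, 32, 43, 54, 65),
    moisture = list(
      `11` = afo_params(3.5, 2.8, 0.08),
      `32` = afo_params(3.5, 5.8, 0.18),
      `65` = afo_params(3.3, 14.7, 0.15)
    ),
    abs420 = list(
      `11` = afo_params(0.008, 0.124, 0.13),
      `32` = afo_params(0.005, 0.118, 0.08),
      `65` = afo_params(0.002, 0.101, 0.07)
    ),
    ph = list(
      `11` = exp_decay_params(5.07, 0.38e-4),
      `32` = exp_decay_params(5.07, 0.72e-4),
      `65` = exp_decay_params(5.08, 2.11e-4)
    ),
    times = list(moisture = 0:19, abs420 = c(3, 10, 20, 30, 45, 60, 120),
                 ph = seq(0, 180, by = 15)),
    noise_sd = list(moisture = 0.15, abs420 = 0.003, ph = 0.03,
                    isotherm = 0.002, tg = 1),
    image = list(size = 100, ranges = rgb_ranges(),
                 schedule = list(`11` = c(1, 0.99, 0.98, 0.97),
                                 `32` = c(1, 0.97, 0.95, 0.93),
                                 `65` = c(1, 0.31, 0.20, 0.15)),
                 times = c(0, 7, 14, 21))
  )
  structure(cfg, class = "study_config")
}

#' Generate a synthetic sorption isotherm
#'
#' Moisture from the GAB curve plus additive Gaussian noise, truncated at 0.
#' With `noise_sd = 0` the points lie exactly on the model.
#'
#' @param gab A [gab_params()] object.
#' @param aw_grid Water activities in \[0, 0.95\], strictly increasing.
#' @param noise_sd Noise SD, g/g dry basis.
#' @param seed Integer seed.
#' @return Data frame `aw,moisture_db` accepted by [fit_gab()].
#' @export
gen_isotherm <- function(gab, aw_grid = seq(0.1, 0.9, by = 0.1),
                         noise_sd = 0, seed = 1) {
  stopifnot(inherits(gab, "gab_params"))
  if (any(aw_grid < 0) || any(aw_grid > 0.95) || any(diff(aw_grid) <= 0))
    stop("invalid 'aw_grid': strictly increasing within [0, 0.95]",
         call. = FALSE)
  M <- gab_moisture(gab, aw_grid)
  if (noise_sd > 0) {
    set.seed(seed)
    M <- pmax(M + stats::rnorm(length(M), 0, noise_sd), 0)
  }
  data.frame(aw = aw_grid, moisture_db = M)
}

#' Generate synthetic glass-transition points
#'
#' T_g at the water fractions implied by the salt-series humidities through
#' the sorption isotherm, with additive Gaussian noise on T_g.
#'
#' @param gt A [gordon_taylor_params()] object.
#' @param gab A [gab_params()] object supplying moisture at each a_w.
#' @param erh_levels Salt-series humidities, percent.
#' @param noise_sd Noise SD on T_g, degC.
#' @param seed Integer seed.
#' @return Data frame `water_fraction,tg_c` accepted by
#'   [fit_gordon_taylor()].
#' @export
gen_tg_points <- function(gt, gab, erh_levels = c(1, 11, 23, 32, 43, 54, 65),
                          noise_sd = 0, seed = 1) {
  stopifnot(inherits(gt, "gordon_taylor_params"), inherits(gab, "gab_params"))
  aw <- erh_levels / 100
  M <- gab_moisture(gab, aw)
  W <- M / (1 + M)
  tg <- gordon_taylor_tg(gt, W)
  if (noise_sd > 0) {
    set.seed(seed)
    tg <- tg + stats::rnorm(length(tg), 0, noise_sd)
  }
  data.frame(water_fraction = W, tg_c = tg)
}

#' Generate replicated kinetic series
#'
#' Forward-simulates one of the three kinetic laws at the given times and
#' adds independent Gaussian noise per replicate; pH series are truncated to
#' (0, 14).
#'
#' @param params [afo_params()] (moisture, abs420) or [exp_decay_params()]
#'   (ph), matching `response`.
#' @param times Sampling times (days, or seconds for dissolution).
#' @param noise_sd Additive noise SD in response units.
#' @param replicates Number of replicate series.
#' @param seed Integer seed.
#' @param response One of `"moisture"`, `"abs420"`, `"ph"`.
#' @param erh ERH condition label carried on each series.
#' @return List of [kinetic_series()], one per replicate.
#' @export
gen_kinetic_series <- function(params, times, noise_sd = 0, replicates = 3,
                               seed = 1,
                               response = c("moisture", "abs420", "ph"),
                               erh = NA) {
  response <- match.arg(response)
  if (response == "ph") stopifnot(inherits(params, "exp_decay_params"))
  else stopifnot(inherits(params, "afo_params"))
  mu <- if (response == "ph") exp_decay(params, times)
        else asymptotic_first_order(params, times)
  unit <- if (response == "abs420") "seconds" else "days"
  set.seed(seed)
  lapply(seq_len(replicates), function(r) {
    v <- mu + if (noise_sd > 0) stats::rnorm(length(mu), 0, noise_sd) else 0
    if (response == "ph") v <- pmin(pmax(v, 1e-6), 14 - 1e-6)
    if (response == "abs420") v <- pmax(v, 0)
    kinetic_series(times, v, response = response, unit = unit,
                   erh = erh, replicate = r)
  })
}

#' Generate a series of synthetic powder images
#'
#' Each image has exactly `round(fraction * n_total)` pixels drawn uniformly
#' inside the baseline RGB ranges and the remainder drawn brighter than every
#' range maximum, so the freshness index of image t against the first image
#' is exactly `100 * fraction_t`. This makes the index analytically known —
#' the generator emulates the loss of in-range ("fresh") pixels as the powder
#' darkens and cakes, not the optics of a real photograph.
#'
#' @param baseline_ranges [rgb_ranges()]; all maxima must be < 255 so an
#'   out-of-range (brightened) draw exists.
#' @param schedule In-range pixel fractions over time; the first must be 1.
#' @param size Image side length in pixels (square images).
#' @param seed Integer seed.
#' @return List of integer RGB arrays (`size x size x 3`).
#' @export
gen_powder_images <- function(baseline_ranges = rgb_ranges(),
                              schedule = c(1, 0.31), size = 100, seed = 1) {
  stopifnot(inherits(baseline_ranges, "rgb_ranges"))
  if (length(schedule) == 0) stop("empty schedule", call. = FALSE)
  if (any(schedule < 0) || any(schedule > 1) || schedule[1] != 1)
    stop("'schedule' must be fractions in [0, 1] with first element 1",
         call. = FALSE)
  r <- baseline_ranges
  if (r$r_max >= 255 || r$g_max >= 255 || r$b_max >= 255)
    stop("range maxima must be < 255 to leave room for out-of-range pixels",
         call. = FALSE)
  n <- size * size
  set.seed(seed)
  lapply(schedule, function(f) {
    k <- round(f * n)
    pos <- sample.int(n, k)               # which pixels stay fresh
    ch <- function(lo_in, hi_in, hi_out) {
      x <- sample((hi_out + 1L):255L, n, replace = TRUE)   # brightened
      x[pos] <- sample(lo_in:hi_in, k, replace = TRUE)     # in-range
      x
    }
    img <- array(0L, dim = c(size, size, 3))
    img[, , 1] <- ch(r$r_min, r$r_max, r$r_max)
    img[, , 2] <- ch(r$g_min, r$g_max, r$g_max)
    img[, , 3] <- ch(r$b_min, r$b_max, r$b_max)
    img
  })
}

#' In-range fraction from simulated moisture (logistic link)
#'
#' Secondary "brightness drift" mode: couples the fresh-pixel fraction to
#' simulated wet-basis moisture through a logistic link
#' `f(M) = 1 / (1 + exp(slope * (M - midpoint)))`, rescaled so f equals 1 at
#' the initial moisture. A midpoint near the monolayer-equivalent moisture
#' makes image degradation accelerate once the monolayer is crossed.
#'
#' @param moisture Wet-basis moisture percent values, first = time zero.
#' @param midpoint Moisture percent at which half the pixels have left the
#'   fresh ranges (default 8).
#' @param slope Steepness of the link, per percent moisture (default 1.2).
#' @return Fractions in \[0, 1\], first element 1.
#' @export
freshness_fraction_from_moisture <- function(moisture, midpoint = 8,
                                             slope = 1.2) {
  f <- 1 / (1 + exp(slope * (moisture - midpoint)))
  f / f[1]
}

#' Generate a complete on-disk synthetic study
#'
#' Writes everything the analysis pipeline consumes: `isotherm.csv`
#' (`aw,moisture_db`), `tg.csv` (`water_fraction,tg_c`), a tidy
#' `kinetics.csv` (`time,value,unit,response,erh,replicate`), PNG powder
#' images per condition and time, and `manifest.json` recording the seed,
#' a hash of the configuration and MD5 checksums of every file. Identical
#' (config, seed) pairs produce byte-identical output.
#'
#' @param cfg A [study_config()].
#' @param out_dir Target directory (created if missing).
#' @return The manifest as a list, invisibly.
#' @export
gen_study <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "study_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create '", out_dir, "'", call. = FALSE)

  iso <- gen_isotherm(cfg$gab, seq(0.1, 0.9, by = 0.1),
                      cfg$noise_sd$isotherm, seed = cfg$seed)
  utils::write.csv(iso, file.path(out_dir, "isotherm.csv"), row.names = FALSE)

  tg <- gen_tg_points(cfg$gt, cfg$gab, cfg$tg_erh_levels,
                      cfg$noise_sd$tg, seed = cfg$seed + 1L)
  utils::write.csv(tg, file.path(out_dir, "tg.csv"), row.names = FALSE)

  rows <- list()
  for (resp in c("moisture", "abs420", "ph")) {
    for (i in seq_along(cfg$erh_levels)) {
      erh <- cfg$erh_levels[i]
      pars <- cfg[[if (resp == "ph") "ph" else resp]][[as.character(erh)]]
      series <- gen_kinetic_series(
        pars, cfg$times[[resp]], cfg$noise_sd[[resp]],
        replicates = cfg$replicates,
        seed = cfg$seed + 10L * i + match(resp, c("moisture", "abs420", "ph")),
        response = resp, erh = erh
      )
      for (s in series) {
        rows[[length(rows) + 1L]] <- data.frame(
          time = s$times, value = s$values, unit = s$unit,
          response = s$response, erh = s$erh, replicate = s$replicate)
      }
    }
  }
  kin <- do.call(rbind, rows)
  utils::write.csv(kin, file.path(out_dir, "kinetics.csv"), row.names = FALSE)

  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  img_files <- character(0)
  for (i in seq_along(cfg$erh_levels)) {
    erh <- cfg$erh_levels[i]
    sched <- cfg$image$schedule[[as.character(erh)]]
    imgs <- gen_powder_images(cfg$image$ranges, sched, cfg$image$size,
                              seed = cfg$seed + 100L + i)
    for (j in seq_along(imgs)) {
      f <- file.path(img_dir, sprintf("erh%02d_t%03d.png", erh,
                                      cfg$image$times[j]))
      png::writePNG(imgs[[j]] / 255, f)
      img_files <- c(img_files, f)
    }
  }

  files <- c(file.path(out_dir, c("isotherm.csv", "tg.csv", "kinetics.csv")),
             img_files)
  cfg_json <- jsonlite::toJSON(config_as_list(cfg), auto_unbox = TRUE,
                               digits = NA)
  cfg_file <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_file)
  manifest <- list(
    seed = cfg$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    files = as.list(stats::setNames(
      unname(tools::md5sum(files)),
      sub(paste0(out_dir, "/"), "", files, fixed = TRUE)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' @keywords internal
#' @noRd
config_as_list <- function(cfg) {
  strip <- function(x) if (is.list(x)) lapply(unclass(x), strip) else x
  strip(unclass(cfg))
}
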