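#' Run the full shelf-life analysis on a study dataset
#'
#' Orchestrates the whole analysis on a directory laid out like the output of
#' [gen_study()]:
#'
#' 1. fit the GAB isotherm and derive the monolayer moisture and activity;
#' 2. fit the Gordon–Taylor curve, build the state diagram at the storage
#'    temperature, derive critical a_w / critical moisture, and classify the
#'    physical state at each storage humidity (a_w = ERH/100 at equilibrium);
#' 3. fit the three kinetic laws per condition (moisture uptake, dissolution
#'    absorbance, brew pH);
#' 4. solve the failure clocks per condition: time for wet-basis moisture to
#'    reach the monolayer equivalent, and time for brew pH to fall below the
#'    configured thresholds (default 5.0, acceptability 5.1);
#' 5. compute the freshness-index trajectory from the powder images and its
#'    correlation with model moisture;
#' 6. run the group statistics (between-condition ANOVA + Tukey letters at
#'    the final shared moisture time; repeated-measures across time per
#'    condition).
#'
#' Stage failures do not abort the run: the report is marked partial and
#' carries a per-stage status.
#'
#' @param config A [study_config()] (supplies ERH levels, storage
#'   temperature, thresholds and provenance; model parameters inside it are
#'   NOT used — everything is re-fitted from the data).
#' @param data_dir Directory with `isotherm.csv`, `tg.csv`, `kinetics.csv`
#'   and an `images/` folder.
#' @param ph_thresholds pH failure thresholds to solve for.
#' @return Object of class `shelf_life_report`.
#' @export
run_study <- function(config, data_dir, ph_thresholds = c(5.0, 5.1)) {
  stopifnot(inherits(config, "study_config"), dir.exists(data_dir))
  status <- list()
  report <- list(erh_levels = config$erh_levels,
                 T_storage = config$T_storage)

  stage <- function(name, expr) {
    r <- tryCatch(list(ok = TRUE, value = expr),
                  error = function(e) list(ok = FALSE,
                                           value = conditionMessage(e)))
    status[[name]] <<- if (r$ok) "ok" else paste("failed:", r$value)
    if (r$ok) r$value else NULL
  }

  # 1. sorption isotherm
  gabfit <- stage("isotherm", {
    fit_gab(read_isotherm_csv(file.path(data_dir, "isotherm.csv")))
  })
  if (!is.null(gabfit)) {
    report$gab <- gabfit
    report$monolayer <- list(
      m0_db = gabfit$params$m0,
      m0_wet_percent = db_to_wb(gabfit$params$m0),
      aw0 = tryCatch(monolayer_activity(gabfit$params),
                     error = function(e) NA_real_)
    )
  }

  # 2. glass transition + state diagram
  gtfit <- stage("glass_transition", {
    fit_gordon_taylor(read_tg_csv(file.path(data_dir, "tg.csv"),
                                  gab = gabfit$params))
  })
  if (!is.null(gtfit) && !is.null(gabfit)) {
    sd <- state_diagram(gabfit$params, gtfit$params, config$T_storage)
    caw <- tryCatch(critical_aw(sd), error = function(e) NA_real_)
    report$gordon_taylor <- gtfit
    report$state_diagram <- list(
      diagram = sd,
      critical_aw = caw,
      critical_moisture_db = if (is.na(caw)) NA_real_
                             else gab_moisture(gabfit$params, caw),
      conditions = lapply(config$erh_levels, function(erh) {
        tg <- tg_at_aw(sd, erh / 100)
        c(list(erh = erh, aw = erh / 100, tg_c = tg),
          classify_state(config$T_storage, tg))
      })
    )
  }

  # 3. kinetics per condition (replicates pooled per fit)
  kin <- stage("kinetics", {
    series <- read_kinetics_csv(file.path(data_dir, "kinetics.csv"))
    fits <- list()
    for (erh in config$erh_levels) {
      key <- as.character(erh)
      for (resp in c("moisture", "abs420", "ph")) {
        grp <- series[vapply(series, function(s)
          s$response == resp && s$erh == erh, logical(1))]
        if (length(grp) == 0) next
        pooled <- pool_replicates(grp)
        fits[[key]][[resp]] <- if (resp == "ph") fit_exp_decay(pooled)
                               else fit_asymptotic_first_order(pooled)
      }
    }
    fits
  })
  report$kinetics <- kin

  # 4. failure clocks
  if (!is.null(kin) && !is.null(gabfit)) {
    report$thresholds <- stage("thresholds", {
      m0_wet <- db_to_wb(gabfit$params$m0)
      lapply(stats::setNames(nm = names(kin)), function(key) {
        out <- list(erh = as.numeric(key))
        mf <- kin[[key]]$moisture
        out$t_monolayer_days <- if (is.null(mf)) NA_real_ else
          tryCatch(time_to_level_asymptotic(mf$params, m0_wet),
                   error = function(e) Inf)   # never reached
        pf <- kin[[key]]$ph
        for (thr in ph_thresholds) {
          nm <- sprintf("t_ph_below_%.1f_days", thr)
          out[[nm]] <- if (is.null(pf)) NA_real_ else
            tryCatch(suppressWarnings(time_to_level_decay(pf$params, thr)),
                     error = function(e) Inf)
        }
        out
      })
    })
  }

  # 5. freshness trajectory + correlation with model moisture
  report$freshness <- stage("freshness", {
    img_dir <- file.path(data_dir, "images")
    if (!dir.exists(img_dir)) stop("no images/ directory", call. = FALSE)
    ranges <- config$image$ranges
    lapply(stats::setNames(nm = as.character(config$erh_levels)),
           function(key) {
      erh <- as.numeric(key)
      files <- sort(list.files(img_dir, sprintf("^erh%02d_", erh),
                               full.names = TRUE))
      if (length(files) == 0) return(NULL)
      t_img <- as.numeric(sub(".*_t(\\d+)\\.png$", "\\1", files))
      base <- read_image_rgb(files[1])
      base_n <- sum(fresh_mask(base, ranges))
      idx <- vapply(files, function(f)
        freshness_index(read_image_rgb(f), ranges, base_n)$index, numeric(1))
      traj <- data.frame(time = t_img, index_pct = unname(idx))
      mf <- report$kinetics[[key]]$moisture
      r_moist <- if (!is.null(mf) && stats::sd(idx) > 0) {
        m_at <- asymptotic_first_order(mf$params, t_img)
        if (stats::sd(m_at) > 0) pearson_r(m_at, idx) else NA_real_
      } else NA_real_
      list(trajectory = traj, r_moisture_index = r_moist)
    })
  })

  # 6. group statistics on the moisture response
  report$stats <- stage("group_stats", {
    kin_csv <- utils::read.csv(file.path(data_dir, "kinetics.csv"))
    m <- kin_csv[kin_csv$response == "moisture", ]
    t_final <- max(m$time)
    between <- tukey_hsd_groups(data.frame(
      value = m$value[m$time == t_final],
      group = paste0("ERH", m$erh[m$time == t_final])))
    within <- lapply(stats::setNames(nm = as.character(config$erh_levels)),
                     function(key) {
      d <- m[m$erh == as.numeric(key), ]
      # a handful of evenly spaced times keeps the letter display readable
      tt <- unique(d$time)
      keep <- tt[unique(round(seq(1, length(tt), length.out = min(5, length(tt)))))]
      d <- d[d$time %in% keep, ]
      tukey_hsd_groups(data.frame(value = d$value,
                                  group = sprintf("t%03d", d$time),
                                  subject = d$replicate))
    })
    list(between_erh_final_time = between, within_erh_over_time = within)
  })

  report$provenance <- list(
    package_version = as.character(utils::packageVersion("hygrostab")),
    seed = config$seed,
    data_dir = normalizePath(data_dir),
    generated_at = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  manifest <- file.path(data_dir, "manifest.json")
  if (file.exists(manifest))
    report$provenance$config_hash <-
      jsonlite::read_json(manifest)$config_hash

  report$stage_status <- status
  report$partial <- any(vapply(status, function(s) s != "ok", logical(1)))
  structure(report, class = "shelf_life_report")
}

# average replicate series point-wise onto the shared time grid
#' @keywords internal
#' @noRd
pool_replicates <- function(series_list) {
  t0 <- series_list[[1]]$times
  for (s in series_list)
    if (!identical(s$times, t0))
      stop("replicates disagree on the time grid", call. = FALSE)
  vals <- rowMeans(vapply(series_list, function(s) s$values,
                          numeric(length(t0))))
  kinetic_series(t0, vals, response = series_list[[1]]$response,
                 unit = series_list[[1]]$unit, erh = series_list[[1]]$erh,
                 replicate = "pooled")
}

#' @export
print.shelf_life_report <- function(x, ...) {
  cat("Shelf-life report", if (x$partial) "(PARTIAL)" else "", "\n")
  if (!is.null(x$gab))
    cat(sprintf("  GAB: m0 = %.4g g/g db (%.3g%% wb), C = %.4g, b = %.4g, aw0 = %.3f\n",
                x$gab$params$m0, x$monolayer$m0_wet_percent,
                x$gab$params$C, x$gab$params$b, x$monolayer$aw0))
  if (!is.null(x$state_diagram)) {
    cat(sprintf("  critical a_w at %g degC: %.3f (moisture %.4g g/g db)\n",
                x$T_storage, x$state_diagram$critical_aw,
                x$state_diagram$critical_moisture_db))
    for (cnd in x$state_diagram$conditions)
      cat(sprintf("    ERH %g%%: Tg = %.1f degC -> %s (deltaT = %.1f)\n",
                  cnd$erh, cnd$tg_c, cnd$label, cnd$deltaT))
  }
  if (!is.null(x$thresholds)) {
    for (th in x$thresholds) {
      fmt <- function(v) {
        if (is.null(v) || is.na(v)) "n/a"
        else if (is.infinite(v)) "never" else sprintf("%.1f d", v)
      }
      ph_keys <- grep("^t_ph_below_", names(th), value = TRUE)
      ph_txt <- paste(vapply(ph_keys, function(k) sprintf(
        "pH<%s in %s", sub("t_ph_below_(.*)_days", "\\1", k), fmt(th[[k]])),
        character(1)), collapse = "; ")
      cat(sprintf("    ERH %g%%: monolayer in %s; %s\n", th$erh,
                  fmt(th$t_monolayer_days), ph_txt))
    }
  }
  cat("  stages:", paste(names(x$stage_status), unlist(x$stage_status),
                         sep = "=", collapse = "; "), "\n")
  invisible(x)
}

#' Export a shelf-life report
#'
#' `json` writes the full report losslessly; `csv-bundle` writes one
#' parameter table per kinetic model (one row per ERH condition, the layout
#' of the parameter tables in storage studies) plus the state-diagram and
#' threshold summaries; `markdown` writes a human-readable summary. Partial
#' reports are flagged in every format.
#'
#' @param report A `shelf_life_report`.
#' @param format `"json"`, `"csv-bundle"`, or `"markdown"`.
#' @param out Output file (json, markdown) or directory (csv-bundle).
#' @return Paths of the files written, invisibly.
#' @export
export_report <- function(report, format = c("json", "csv-bundle", "markdown"),
                          out) {
  stopifnot(inherits(report, "shelf_life_report"))
  format <- match.arg(format)
  if (format == "json") {
    jsonlite::write_json(report_as_list(report), out, auto_unbox = TRUE,
                         digits = NA, na = "null", null = "null")
    return(invisible(out))
  }
  if (format == "csv-bundle") {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    for (resp in c("moisture", "abs420", "ph")) {
      rows <- lapply(names(report$kinetics), function(key) {
        f <- report$kinetics[[key]][[resp]]
        if (is.null(f)) return(NULL)
        p <- f$params
        if (resp == "ph")
          data.frame(erh = key, pH0 = p$pH0, k_per_day = p$k,
                     k_x1e4 = p$k * 1e4, rmse = f$diagnostics$rmse)
        else
          data.frame(erh = key, Y0 = p$Y0, Yinf = p$Yinf, k = p$k,
                     rmse = f$diagnostics$rmse)
      })
      rows <- do.call(rbind, rows)
      if (!is.null(rows)) {
        fp <- file.path(out, paste0("kinetics_", resp, ".csv"))
        utils::write.csv(cbind(rows, partial = report$partial), fp,
                         row.names = FALSE)
        paths <- c(paths, fp)
      }
    }
    if (!is.null(report$state_diagram)) {
      cond <- do.call(rbind, lapply(report$state_diagram$conditions,
                                    as.data.frame))
      fp <- file.path(out, "state_diagram.csv")
      utils::write.csv(cbind(cond, critical_aw = report$state_diagram$critical_aw,
                             partial = report$partial), fp, row.names = FALSE)
      paths <- c(paths, fp)
    }
    if (!is.null(report$thresholds)) {
      fp <- file.path(out, "thresholds.csv")
      utils::write.csv(cbind(do.call(rbind, lapply(report$thresholds,
                                                   as.data.frame)),
                             partial = report$partial), fp, row.names = FALSE)
      paths <- c(paths, fp)
    }
    return(invisible(paths))
  }
  # markdown
  lines <- c(
    paste("# Shelf-life report", if (report$partial) "**(partial)**" else ""),
    "",
    utils::capture.output(print(report))
  )
  writeLines(lines, out)
  invisible(out)
}

#' @keywords internal
#' @noRd
report_as_list <- function(report) {
  strip <- function(x) {
    if (inherits(x, c("aov", "aovlist", "lm", "nls"))) return(NULL)
    if (is.environment(x) || is.function(x) || is.call(x) ||
        inherits(x, "formula")) return(NULL)
    if (is.data.frame(x)) return(x)
    if (is.list(x)) {
      x <- lapply(unclass(x), strip)
      return(x[!vapply(x, is.null, logical(1))])
    }
    x
  }
  strip(unclass(report))
}
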