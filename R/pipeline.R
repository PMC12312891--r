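#' End-to-end pipeline run
#'
#' Chains the stages of the monitoring analysis on a synthetic scene pack:
#' simulate, classify every scene, per-scene accuracy against the truth,
#' area accounting with descriptive statistics / outlier screening /
#' correlations / annual and monthly shares, and the pixel-wise frequency,
#' stability and transfer analytics. All artifacts are written under
#' `out_dir` as CSV/JSON/ASCII-grid files plus a JSON run report; identical
#' config and seed reproduce identical outputs.
#'
#' @param config A [sim_config()]; its `seed` drives every random draw.
#' @param out_dir Output directory.
#' @param method Classifier deployed per scene: `"fused"` (default),
#'   `"mlc"`, `"svm"`, or `"auto"` (per-scene winner by [select_method()]).
#' @param per_class_n Training samples drawn per class from the first
#'   scene.
#' @param kernel A [kernel_spec()].
#' @param C SVM box bound.
#' @param alpha Significance level for the outlier test.
#' @param write_rasters Write per-scene class maps (off by default to keep
#'   runs light).
#' @return The run report, invisibly (also written to `report.json`).
#' @export
run_pipeline <- function(config, out_dir,
                         method = c("fused", "mlc", "svm", "auto"),
                         per_class_n = 100, kernel = kernel_spec(), C = 1,
                         alpha = 0.05, write_rasters = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  tick <- function(name, expr) {
    s <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[name]] <<- round(proc.time()[["elapsed"]] - s, 3)
    res
  }

  pack <- tick("simulate", simulate_scenes(config))
  counts <- table(factor(pack$scenes[[1]]$truth$labels, levels = 1:4))
  n_roi <- min(per_class_n, counts[counts > 0])
  if (n_roi < per_class_n) {
    lake_log(sprintf("ROI sample capped at %d per class (rarest class size)",
                     n_roi), "warning")
  }
  train <- sample_rois(pack$scenes[[1]]$truth, pack$scenes[[1]]$image,
                       n_roi, seed = derive_seed(config$seed, 7L))
  sep <- separability_matrix(train)

  maps <- tick("classify", {
    models <- fit_mlc(train)
    tree <- train_svm_tree(train, kernel = kernel, C = C)
    lapply(seq_along(pack$scenes), function(i) {
      sc <- pack$scenes[[i]]
      switch(method,
        mlc = mlc_classify(sc$image, models),
        svm = svm_tree_classify(sc$image, tree),
        fused = fuse_classify(sc$image, train, kernel = kernel, C = C,
                              seed = derive_seed(config$seed, 200L + i))$map,
        auto = {
          a <- mlc_classify(sc$image, models)
          b <- svm_tree_classify(sc$image, tree)
          ref <- as.vector(sc$truth$labels)
          ca <- confusion(as.vector(a$labels), ref)
          cb <- confusion(as.vector(b$labels), ref)
          mc <- mcnemar(as.vector(a$labels), as.vector(b$labels), ref)
          if (select_method(ca, cb, mc$p_value,
                            names = c("mlc", "svm"))$choice == 1) a else b
        })
    })
  })

  accuracy <- tick("evaluate", {
    oa <- vapply(seq_along(maps), function(i) {
      confusion(as.vector(maps[[i]]$labels),
                as.vector(pack$scenes[[i]]$truth$labels))$oa
    }, 0)
    data.frame(date = pack$levels$date, oa = oa)
  })

  series <- tick("areas", area_series(maps))
  write.csv(series, file.path(out_dir, "area_series.csv"), row.names = FALSE)

  stats_out <- tick("stats", {
    list(
      descriptive = lapply(series_classes, function(cl)
        descriptive_stats(series, cl)),
      grubbs = lapply(series_classes, function(cl) {
        g <- grubbs(series_column(series, cl), alpha)
        list(class = cl, statistic = g$statistic, critical = g$critical,
             outlier = g$outlier)
      }),
      correlations = series_correlations(series),
      annual = annual_share(series),
      monthly = monthly_share(series))
  })
  write.csv(stats_out$correlations, file.path(out_dir, "correlations.csv"),
            row.names = FALSE)
  write.csv(stats_out$annual, file.path(out_dir, "annual_share.csv"),
            row.names = FALSE)
  write.csv(stats_out$monthly, file.path(out_dir, "monthly_share.csv"),
            row.names = FALSE)

  freq_out <- tick("frequency", {
    years <- pack$levels$year
    res <- list()
    for (target in c("water", "vegetation")) {
      annual <- lapply(unique(years), function(y) {
        annual_presence(lapply(maps[years == y], binarize, target = target))
      })
      fr <- accumulate_frequency(annual)
      fmap <- classify_frequency(fr, scheme = target)
      cv <- cv_map(annual)
      stab <- stability_classes(cv)
      write_asc(unclass(fr), file.path(out_dir, paste0("frequency_", target, ".asc")),
                pixel_size = config$pixel_size, integer = TRUE, nodata = -1)
      write_asc(unclass(cv), file.path(out_dir, paste0("cv_", target, ".asc")),
                pixel_size = config$pixel_size)
      stab_counts <- tabulate(stab[!is.na(stab)], length(attr(stab, "labels")))
      res[[target]] <- list(
        share = frequency_share(fmap),
        stability = list(breaks = attr(stab, "breaks"),
                         labels = attr(stab, "labels"),
                         proportions = stab_counts / max(sum(stab_counts), 1)))
    }
    res
  })

  transfer <- tick("transfer", {
    half <- ceiling(length(maps) / 2)
    tm <- transfer_matrix(modal_map(maps[seq_len(half)]),
                          modal_map(maps[(half + 1):length(maps)]))
    write_transfer_csv(tm, file.path(out_dir, "transfer_matrix.csv"))
    tm
  })

  if (write_rasters) {
    for (i in seq_along(maps)) {
      write_class_map(maps[[i]],
                      file.path(out_dir, sprintf("classmap_%03d.asc", i)))
    }
  }

  report <- list(
    package_version = as.character(utils::packageVersion("lakecover")),
    seed = config$seed, method = method,
    config = list(grid = c(config$grid_rows, config$grid_cols),
                  n_years = config$n_years,
                  scenes_per_year = config$scenes_per_year,
                  band_count = config$band_count, noise_sd = config$noise_sd),
    separability = sep,
    mean_oa = mean(accuracy$oa), min_oa = min(accuracy$oa),
    grubbs = stats_out$grubbs,
    correlations = stats_out$correlations,
    frequency = lapply(freq_out, function(f)
      list(proportions = as.list(f$share$proportions),
           covered_fraction = f$share$covered_fraction,
           stability = f$stability)),
    transfer_grand_total_km2 = transfer$grand_total_km2,
    timings = timings,
    elapsed = round(proc.time()[["elapsed"]] - t0, 3))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  lake_log(sprintf("pipeline done in %.1fs, mean OA %.3f",
                   report$elapsed, report$mean_oa))
  invisible(report)
}
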