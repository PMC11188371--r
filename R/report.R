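#' Evaluation record for one model
#'
#' Bundles the paired true/predicted weights of a model with its R^2, RMSE
#' (grams) and optional per-image inference time.
#'
#' @param model_id label for the model
#' @param true_g,predicted_g paired weights, grams
#' @param inference_ms_per_image optional latency (informational)
#' @return object of class `fw_eval`
#' @export
eval_report <- function(model_id, true_g, predicted_g,
                        inference_ms_per_image = NA_real_) {
  check_paired(true_g, predicted_g)
  structure(list(model_id = model_id,
                 r_squared = r_squared(true_g, predicted_g),
                 rmse_g = rmse(true_g, predicted_g),
                 inference_ms_per_image = inference_ms_per_image,
                 predictions = data.frame(true_g = true_g,
                                          predicted_g = predicted_g)),
            class = "fw_eval")
}

#' @export
print.fw_eval <- function(x, ...) {
  cat(sprintf("%s: R^2 = %.3f, RMSE = %.2f g (n = %d)%s\n", x$model_id,
              x$r_squared, x$rmse_g, nrow(x$predictions),
              if (is.finite(x$inference_ms_per_image))
                sprintf(", %.3g ms/image", x$inference_ms_per_image) else ""))
  invisible(x)
}

#' Assemble the full model-comparison report
#'
#' Collects the conventional subset-by-degree grid, the deep-model
#' evaluations (R^2, RMSE, inference time), kernel-density overlays of
#' predicted versus true weights per deep model, and the feature/weight
#' Pearson correlation matrix into one bundle. When `out_dir` is given the
#' bundle is also written as `report.json`, `regression_results.csv`,
#' `deep_results.csv` and PNG figures (correlation heatmap, KDE overlays).
#' Rerunning on identical inputs yields byte-identical JSON.
#'
#' @param grid an `fw_reggrid` from [fit_regression_grid()] (or NULL)
#' @param deep_reports list of `fw_eval` objects (or empty)
#' @param corr correlation matrix from [pearson_corr_matrix()] (or NULL;
#'   the heatmap is then omitted with a notice)
#' @param out_dir optional output directory
#' @param notes character vector of free-form notes stored in the report
#' @return object of class `fw_report`
#' @export
build_comparison_report <- function(grid = NULL, deep_reports = list(),
                                    corr = NULL, out_dir = NULL,
                                    notes = character()) {
  if (is.null(grid) && !length(deep_reports))
    fw_domain_error("need at least one model result")
  deep_tab <- if (length(deep_reports)) {
    do.call(rbind, lapply(deep_reports, function(r)
      data.frame(model = r$model_id, r2 = r$r_squared, rmse_g = r$rmse_g,
                 inference_ms_per_image = r$inference_ms_per_image)))
  }
  kde <- lapply(deep_reports, function(r) {
    rng <- range(c(r$predictions$true_g, r$predictions$predicted_g))
    bw <- sd(r$predictions$true_g) * nrow(r$predictions)^(-1 / 5)
    grid_x <- seq(rng[1] - 3 * bw, rng[2] + 3 * bw, length.out = 256)
    list(model = r$model_id,
         true = kde_curve(r$predictions$true_g, grid_x),
         predicted = kde_curve(r$predictions$predicted_g, grid_x))
  })
  names(kde) <- vapply(deep_reports, `[[`, character(1), "model_id")
  if (is.null(corr)) message("correlation matrix absent; heatmap omitted")
  rep <- structure(list(conventional = if (!is.null(grid)) grid$results,
                        deep = deep_tab, kde = kde, correlation = corr,
                        notes = notes),
                   class = "fw_report")
  if (!is.null(out_dir)) write_report(rep, out_dir)
  rep
}

#' @export
print.fw_report <- function(x, ...) {
  if (!is.null(x$conventional)) {
    best <- x$conventional[which.max(x$conventional$r2), ]
    cat(sprintf("Conventional grid: %d models; best degree %d on (%s): R^2 %.3f, RMSE %.2f g\n",
                nrow(x$conventional), best$degree, best$subset, best$r2, best$rmse_g))
  }
  if (!is.null(x$deep)) {
    cat("Deep models:\n")
    for (i in seq_len(nrow(x$deep)))
      cat(sprintf("  %-6s R^2 %.3f, RMSE %.2f g%s\n", x$deep$model[i],
                  x$deep$r2[i], x$deep$rmse_g[i],
                  if (is.finite(x$deep$inference_ms_per_image[i]))
                    sprintf(", %.3g ms/image", x$deep$inference_ms_per_image[i])
                  else ""))
  }
  for (n in x$notes) cat("note:", n, "\n")
  invisible(x)
}

write_report <- function(rep, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  js <- list(conventional = rep$conventional, deep = rep$deep,
             correlation = if (!is.null(rep$correlation))
               list(variables = colnames(rep$correlation),
                    matrix = unname(rep$correlation)),
             notes = rep$notes)
  jsonlite::write_json(js, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       null = "null")
  if (!is.null(rep$conventional))
    write.csv(rep$conventional, file.path(out_dir, "regression_results.csv"),
              row.names = FALSE)
  if (!is.null(rep$deep))
    write.csv(rep$deep, file.path(out_dir, "deep_results.csv"),
              row.names = FALSE)
  if (!is.null(rep$correlation))
    plot_heatmap(rep$correlation, file.path(out_dir, "heatmap.png"))
  for (k in rep$kde)
    plot_kde_overlay(k, file.path(out_dir, sprintf("kde_%s.png", k$model)))
  invisible(out_dir)
}

plot_heatmap <- function(corr, path) {
  grDevices::png(path, width = 640, height = 560)
  on.exit(grDevices::dev.off())
  n <- ncol(corr)
  pal <- grDevices::hcl.colors(64, "Blue-Red 2")
  graphics::image(seq_len(n), seq_len(n), t(corr[n:1, ]), zlim = c(-1, 1),
                  col = pal, axes = FALSE, xlab = "", ylab = "",
                  main = "Pearson correlation")
  graphics::axis(1, seq_len(n), colnames(corr), las = 2)
  graphics::axis(2, seq_len(n), rev(rownames(corr)), las = 2)
  for (i in seq_len(n)) for (j in seq_len(n))
    graphics::text(j, n + 1 - i, sprintf("%.2f", corr[i, j]), cex = 0.9)
  invisible(path)
}

plot_kde_overlay <- function(k, path) {
  grDevices::png(path, width = 640, height = 480)
  on.exit(grDevices::dev.off())
  yl <- range(0, k$true$density, k$predicted$density)
  graphics::plot(k$true$x, k$true$density, type = "l", lwd = 2, col = "grey25",
                 ylim = yl, xlab = "fresh weight (g)", ylab = "density",
                 main = sprintf("%s: true vs predicted weight density", k$model))
  graphics::lines(k$predicted$x, k$predicted$density, lwd = 2, col = "forestgreen")
  graphics::legend("topright", c("true", "predicted"), lwd = 2,
                   col = c("grey25", "forestgreen"), bty = "n")
  invisible(path)
}

plot_pairs <- function(data, path,
                       columns = c(unname(FEATURE_NAMES), "weight_g")) {
  grDevices::png(path, width = 720, height = 720)
  on.exit(grDevices::dev.off())
  graphics::pairs(data[, intersect(columns, names(data))], pch = 16,
                  cex = 0.5, col = grDevices::adjustcolor("darkgreen", 0.5))
  invisible(path)
}
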