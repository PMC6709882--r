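#' Generate and persist a simulated blob dataset
#'
#' Wraps [simulate_blob_dataset()] and writes the blob tables plus a run
#' manifest (all parameters and the master seed) so the dataset can be
#' reproduced bitwise.
#'
#' @param params a [simulation_params()].
#' @param out_dir output directory (created if needed).
#' @return the `cav_blob_set`, invisibly; files `simulated.points.csv`,
#'   `simulated.annotations.csv`, `simulated.manifest.yaml`,
#'   `run_manifest.yaml` under `out_dir`.
#' @export
run_simulate <- function(params = simulation_params(), out_dir) {
  bs <- simulate_blob_dataset(params)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_blobs(bs, file.path(out_dir, "simulated"))
  yaml::write_yaml(
    list(command = "simulate",
         params = lapply(unclass(params), function(v)
           if (is.matrix(v)) as.numeric(diag(v)) else v),
         n_blobs = length(bs)),
    file.path(out_dir, "run_manifest.yaml"))
  invisible(bs)
}

#' Validate the feature + random-forest model on simulated data
#'
#' The desk-scale validation study: generate the two-class simulated dataset,
#' extract the 28 hand-crafted features per blob, and score a 100-tree bagged
#' random forest by stratified 10-fold cross-validation (pooled confusion
#' counts). The isotropic class is the positive.
#'
#' @param params a [simulation_params()].
#' @param k cross-validation folds.
#' @param n_trees trees per forest.
#' @param cv_seed seed for fold assignment and forests.
#' @param out_dir optional directory for the report (JSON), per-blob
#'   predictions (CSV), and manifest.
#' @return list: `report` (pooled `cav_report`), `fold_reports`,
#'   `predictions`, `features`, `threshold_nm`, `params`.
#' @export
validate_simulated <- function(params = simulation_params(), k = 10L,
                               n_trees = 100L, cv_seed = 1L, out_dir = NULL) {
  bs <- simulate_blob_dataset(params)
  features <- featurize_blobs(bs)
  labels <- blob_field(bs, "class")
  cv <- cross_validate_rf(features, labels, k = k, n_trees = n_trees,
                          seed = cv_seed)
  out <- list(report = cv$report, fold_reports = cv$fold_reports,
              predictions = cv$predictions, features = features,
              threshold_nm = attr(features, "threshold_nm"), params = params)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(cv$predictions, file.path(out_dir, "cv_predictions.csv"),
              row.names = FALSE)
    write_features(features, file.path(out_dir, "features.csv"))
    jsonlite::write_json(
      list(accuracy = cv$report$accuracy,
           sensitivity = cv$report$sensitivity,
           specificity = cv$report$specificity,
           counts = as.list(cv$report$counts),
           fold_accuracies = vapply(cv$fold_reports, `[[`, numeric(1), "accuracy"),
           k = k, n_trees = n_trees, cv_seed = cv_seed,
           sim_seed = params$seed, threshold_nm = out$threshold_nm),
      file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Generate a synthetic multi-cell SMLM experiment fixture
#'
#' Builds eventlists and PTRF masks emulating the real acquisition at reduced
#' scale, so the full real-data workflow can be exercised without any
#' download: per cell, caveola-like clusters (dense, >= 60 molecules after
#' reconstruction, under a painted mask disk in PTRF cells) and scaffold-like
#' clusters (smaller, anisotropic), each molecule emitting 1-3 localizations
#' within a few nm (multi-blink), plus uniform background. PTRF-absent cells
#' get no mask.
#'
#' @param n_ptrf_cells,n_pc3_cells number of mask-bearing / mask-free cells.
#' @param n_caveolae,n_scaffolds clusters per cell.
#' @param cell_size_nm lateral cell extent (z spans +/- 200 nm).
#' @param n_background uniform background localizations per cell.
#' @param mask_pixel_nm mask raster pixel size.
#' @param seed master seed.
#' @return list with `eventlists` (named list of localization data frames),
#'   `masks` (named list of [mask_image()] or `NULL`), and `truth` (data
#'   frame of planted cluster centers and types).
#' @export
simulate_experiment_fixture <- function(n_ptrf_cells = 3L, n_pc3_cells = 2L,
                                        n_caveolae = 12L, n_scaffolds = 15L,
                                        cell_size_nm = 4000,
                                        n_background = 300L,
                                        mask_pixel_nm = 20, seed = 1L) {
  cells <- c(sprintf("ptrf%d", seq_len(n_ptrf_cells)),
             sprintf("pc3%d", seq_len(n_pc3_cells)))
  seeds <- spawn_seeds(seed, length(cells))
  eventlists <- list()
  masks <- list()
  truth <- NULL

  # molecules with a minimum separation, placed by dart throwing
  place_molecules <- function(n, center, radii, min_sep = 32) {
    pts <- matrix(NA_real_, 0, 3)
    tries <- 0
    while (nrow(pts) < n && tries < 20000) {
      tries <- tries + 1
      cand <- center + rnorm(3) * radii
      if (nrow(pts) == 0 ||
          min(sqrt(rowSums(sweep(pts, 2, cand)^2))) > min_sep)
        pts <- rbind(pts, cand)
    }
    pts
  }

  for (ci in seq_along(cells)) {
    cell <- cells[ci]
    is_ptrf <- startsWith(cell, "ptrf")
    rows <- with_seed(seeds[ci], {
      # caveolae require CAVIN1/PTRF: mask-free cells get only scaffolds
      n_cav <- if (is_ptrf) n_caveolae else 0L
      n_clusters <- n_cav + n_scaffolds
      centers <- cbind(runif(n_clusters, 600, cell_size_nm - 600),
                       runif(n_clusters, 600, cell_size_nm - 600),
                       runif(n_clusters, -120, 120))
      type <- rep(c("caveola", "scaffold"), c(n_cav, n_scaffolds))
      locs <- list()
      for (b in seq_len(n_clusters)) {
        if (type[b] == "caveola") {
          mols <- place_molecules(sample(80:105, 1), centers[b, ],
                                  radii = c(60, 60, 50))
        } else {
          mols <- place_molecules(sample(15:40, 1), centers[b, ],
                                  radii = c(75, 35, 30))
        }
        blinks <- lapply(seq_len(nrow(mols)), function(m) {
          k <- 1L + stats::rpois(1, 0.8)
          sweep(matrix(rnorm(3 * k, sd = 2), k, 3), 2, mols[m, ], `+`)
        })
        locs[[b]] <- do.call(rbind, blinks)
      }
      bg <- cbind(runif(n_background, 0, cell_size_nm),
                  runif(n_background, 0, cell_size_nm),
                  runif(n_background, -200, 200))
      list(locs = do.call(rbind, locs), bg = bg, centers = centers, type = type)
    })
    pts <- rbind(rows$locs, rows$bg)
    eventlists[[cell]] <- data.frame(
      x = pts[, 1], y = pts[, 2], z = pts[, 3],
      cell_id = cell, source_row = seq_len(nrow(pts)))
    truth <- rbind(truth, data.frame(
      cell_id = cell, type = rows$type,
      x = rows$centers[, 1], y = rows$centers[, 2], z = rows$centers[, 3]))
    if (is_ptrf) {
      npx <- ceiling(cell_size_nm / mask_pixel_nm)
      px <- matrix(0L, npx, npx)
      cav <- rows$centers[rows$type == "caveola", , drop = FALSE]
      xs <- (seq_len(npx) - 0.5) * mask_pixel_nm
      for (b in seq_len(nrow(cav))) {
        jj <- which(abs(xs - cav[b, 1]) <= 300)
        ii <- which(abs(xs - cav[b, 2]) <= 300)
        dd <- outer((xs[ii] - cav[b, 2])^2, (xs[jj] - cav[b, 1])^2, `+`)
        px[ii, jj][dd <= 300^2] <- 1L
      }
      masks[[cell]] <- mask_image(px, mask_pixel_nm)
    } else {
      masks[cell] <- list(NULL)
    }
  }
  list(eventlists = eventlists, masks = masks, truth = truth)
}

#' Run the full real-data workflow
#'
#' Executes the three-step pipeline on user-supplied (or fixture) eventlists
#' and masks: per cell, iterative merging, noise filtering, and segmentation;
#' then PTRF-mask labeling, the >= 60 molecule stratification, and class
#' balancing; then 28-feature extraction and random-forest training and
#' evaluation under both the mixed and the cell-wise split. Stage
#' input/output counts are logged in the result.
#'
#' @param eventlists named list (by cell id) of localization data frames or
#'   CSV paths readable by [read_eventlist()].
#' @param masks named list of [mask_image()] objects, aligned with
#'   `eventlists`; a `NULL` entry declares the cell PTRF-free (all blobs
#'   PTRF-).
#' @param config a [preprocess_config()].
#' @param n_test,n_val mixed-split sizes.
#' @param test_cell,val_cell cell-wise split cells; default: the two
#'   positive-bearing cells with most blobs.
#' @param n_trees,seed random-forest settings.
#' @param min_blob_points blobs below this size are dropped before labeling
#'   (tiny background fragments).
#' @param out_dir optional output directory (blob tables, features, reports,
#'   manifest).
#' @return list: `blobs` (balanced labeled set), `features`, `reports`
#'   (mixed / cell_wise `cav_report`s), `predictions`, `splits`, `log`.
#' @export
run_real_pipeline <- function(eventlists, masks,
                              config = preprocess_config(),
                              n_test = 20L, n_val = 10L,
                              test_cell = NULL, val_cell = NULL,
                              n_trees = 100L, seed = 1L,
                              min_blob_points = 3L, out_dir = NULL) {
  if (is.null(names(eventlists)) || is.null(names(masks)))
    abort("eventlists and masks must be named by cell id")
  log <- list()
  labeled <- list()
  for (cell in names(eventlists)) {
    ev <- eventlists[[cell]]
    if (is.character(ev))
      ev <- read_eventlist(ev, column_map = c(x = "x", y = "y", z = "z"))
    if (!"cell_id" %in% names(ev) || all(is.na(ev$cell_id))) ev$cell_id <- cell
    if (!"source_row" %in% names(ev)) ev$source_row <- seq_len(nrow(ev))
    n0 <- nrow(ev)
    merged <- merge_localizations(ev, config$merge_radius_nm)
    kept <- filter_noise(merged, config$noise_neighbor_radius_nm, config$noise_k)
    bs <- segment_blobs(kept, config$segmentation_radius_nm)
    bs <- bs[blob_counts(bs) >= min_blob_points]
    bs <- label_with_mask(bs, masks[[cell]], config$mask_overlap_threshold)
    log[[cell]] <- c(localizations = n0, merged = nrow(merged),
                     filtered = nrow(kept), blobs = length(bs))
    labeled <- c(labeled, unclass(bs))
  }
  bs <- blob_set(labeled)
  bs <- stratify_classes(bs, config$caveolae_min_molecules)
  balanced <- balance_classes(bs, seed = config$balance_seed)
  log$classes <- table(blob_field(balanced, "class"))

  features <- featurize_blobs(balanced)
  labels <- blob_field(balanced, "class")
  cells <- blob_field(balanced, "cell_id")
  ids <- names(balanced)

  if (is.null(test_cell)) {
    pos_cells <- names(sort(table(cells[labels == "positive"]), decreasing = TRUE))
    if (length(pos_cells) < 2)
      abort("need two positive-bearing cells for the cell-wise split")
    test_cell <- pos_cells[1]
    val_cell <- pos_cells[2]
  }
  splits <- list(
    mixed = split_mixed(ids, labels, n_test = n_test, n_val = n_val, seed = seed),
    cell_wise = split_cellwise(ids, cells, test_cell, val_cell)
  )

  reports <- list()
  predictions <- list()
  for (mode in names(splits)) {
    sp <- splits[[mode]]
    tr <- ids %in% sp$train_ids
    te <- ids %in% sp$test_ids
    model <- train_rf(features[tr, , drop = FALSE], labels[tr],
                      n_trees = n_trees, seed = seed)
    pred <- predict(model, features[te, , drop = FALSE])
    reports[[mode]] <- report_from_labels(pred, labels[te])
    predictions[[mode]] <- data.frame(blob_id = ids[te], truth = labels[te],
                                      predicted = pred, split = mode)
  }

  out <- list(blobs = balanced, features = features, reports = reports,
              predictions = do.call(rbind, predictions), splits = splits,
              log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_blobs(balanced, file.path(out_dir, "blobs"))
    write_features(features, file.path(out_dir, "features.csv"))
    write.csv(out$predictions, file.path(out_dir, "predictions.csv"),
              row.names = FALSE)
    jsonlite::write_json(
      lapply(reports, function(r) list(
        accuracy = r$accuracy, sensitivity = r$sensitivity,
        specificity = r$specificity, counts = as.list(r$counts))),
      file.path(out_dir, "reports.json"), auto_unbox = TRUE, digits = NA)
    yaml::write_yaml(
      list(command = "run_real", seed = seed, n_trees = n_trees,
           config = unclass(config),
           stage_counts = lapply(log, as.list)),
      file.path(out_dir, "run_manifest.yaml"))
  }
  out
}
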