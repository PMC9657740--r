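# End-to-end pipeline: fixtures -> soft maps -> training -> prediction ->
# metrics report. This is the desk-scale profile: mean-reduced loss,
# lr 1e-3, momentum 0.9, thin network widths — the full-scale recipe
# (sum reduction, lr 1e-10, momentum 0.99) is available via train_config().

#' Assemble training samples from fields and softened maps
#'
#' @param fields list of [generate_field()] results.
#' @param soft result of [soften_dataset()] for the same images.
#' @return List of `list(image, labels, weights)` samples for [fit_slfcn()].
#' @export
make_training_samples <- function(fields, soft) {
  lapply(seq_along(fields), function(k) {
    list(image = fields[[k]]$image,
         labels = soft$maps[[k]]$labels,
         weights = soft$maps[[k]]$weights)
  })
}

#' Run the full pipeline on synthetic fixtures
#'
#' Generates a seeded fixture dataset, builds soft-label weight maps (and,
#' when requested, the hard-label reference with identity kernels), trains
#' a desk-scale network per weighting mode, predicts the held-out images
#' and writes a metric report. All artifacts (fixtures, weight maps,
#' predictions, report.csv, config echo) land in `out_dir`. Reproducible
#' from (config, seed).
#'
#' @param out_dir output directory.
#' @param seed master seed for fixtures, initialization and training.
#' @param n_train,n_test fixture counts.
#' @param image_size fixture side length.
#' @param steps training steps per mode.
#' @param width_multiplier network width factor.
#' @param modes subset of `c("soft", "hard")`: three-tier weights versus
#'   the hard-label limit (identity kernels, core weight on the whole
#'   annotation).
#' @param target_class annotated class to segment (default `"nucleus"`).
#' @param synth_overrides named list of [synth_params()] overrides.
#' @param lr,momentum desk-profile optimizer settings.
#' @return List: `report` (aggregated tibble), `per_image` rows,
#'   `psi_star`, `kernels`, `histories`, `out_dir`.
#' @export
run_demo <- function(out_dir = file.path(tempdir(), "slfcn-demo"),
                     seed = 1L, n_train = 4L, n_test = 2L,
                     image_size = 64L, steps = 12L,
                     width_multiplier = 1 / 16,
                     modes = c("soft", "hard"),
                     target_class = "nucleus",
                     synth_overrides = list(),
                     lr = 1e-3, momentum = 0.9) {
  modes <- match.arg(modes, c("soft", "hard"), several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sp_args <- utils::modifyList(list(
    image_size = c(image_size, image_size),
    n_nuclei = 2L,
    nucleus_radius = round(c(0.18, 0.28) * image_size),
    blur_sigma = 1.5, dots_dark = 2L, dots_red = 1L,
    dot_radius = c(1, 2), noise_sigma = 0.04, style = "dish",
    seed = seed), synth_overrides)
  params <- do.call(synth_params, sp_args)
  ds <- generate_dataset(n_train, n_test, params, out_dir = file.path(out_dir, "data"))
  is_train <- ds$manifest$split == "train"

  ann <- lapply(ds$fields, function(f) filter_classes(f$annotations, target_class))
  names(ann) <- ds$manifest$id
  train_ann <- ann[is_train]

  diags <- unlist(lapply(train_ann, function(a) {
    vapply(a$instances, function(i) bbox_diagonal(bounding_box(i)), numeric(1))
  }))
  psi_star <- median_diagonal(diags)
  soft_kernels <- kernel_sizes(psi_star)

  per_image <- list(); histories <- list()
  for (mode in modes) {
    kern <- if (mode == "hard") list(kappa_e = 1L, kappa_d = 1L) else soft_kernels
    softened <- soften_dataset(train_ann, class_table = target_class,
                               kernels = kern)
    wm_dir <- file.path(out_dir, paste0("weights_", mode))
    dir.create(wm_dir, showWarnings = FALSE)
    for (nm in names(softened$maps)) {
      write_weight_map(softened$maps[[nm]]$weights,
                       file.path(wm_dir, paste0(nm, ".tif")))
    }
    samples <- make_training_samples(ds$fields[is_train], softened)
    net <- build_slfcn(network_config(num_classes = 2L,
                                      width_multiplier = width_multiplier))
    net <- init_network(net, "kaiming", seed = seed)
    net <- init_bilinear_deconv(net)
    net <- zero_score_layer(net)
    tc <- train_config(optimizer = "sgd_momentum", lr = lr, momentum = momentum,
                       steps = steps, seed = seed, reduction = "mean")
    fit <- fit_slfcn(net, samples, tc)
    histories[[mode]] <- fit$history
    pred_dir <- file.path(out_dir, paste0("pred_", mode))
    dir.create(pred_dir, showWarnings = FALSE)
    for (k in which(!is_train)) {
      pr <- predict(fit$network, ds$fields[[k]]$image)
      write_label_map(pr$labels, file.path(pred_dir,
                                           paste0(ds$manifest$id[k], ".png")))
      ref <- build_target_labels(ann[[k]], class_table = target_class)
      row <- evaluate_labels(pr$labels, ref, classes = 1L)
      row <- row[row$class == "foreground", ]
      row$method <- mode
      row$id <- ds$manifest$id[k]
      per_image[[length(per_image) + 1L]] <- row
    }
  }
  per_image <- do.call(rbind, per_image)
  report <- aggregate_metrics(per_image)
  write.csv(report, file.path(out_dir, "report.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = seed, n_train = n_train, n_test = n_test,
         image_size = image_size, steps = steps,
         width_multiplier = width_multiplier, modes = modes,
         psi_star = psi_star,
         kappa_e = soft_kernels$kappa_e, kappa_d = soft_kernels$kappa_d,
         version = as.character(utils::packageVersion("slfcn"))),
    file.path(out_dir, "config.json"), auto_unbox = TRUE, digits = NA)
  list(report = report, per_image = per_image,
       psi_star = psi_star, kernels = soft_kernels,
       histories = histories, out_dir = out_dir)
}
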