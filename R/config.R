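# Run configuration (YAML) and dataset manifests.

#' Default run configuration
#'
#' Seeds, geometry, preprocessing parameters, per-model and escalation
#' thresholds, and training hyperparameters, with the study's operating
#' points as defaults.
#'
#' @return Named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    image_side = 512L,
    clahe = list(clip_limit = 2, tile_grid = c(8L, 8L)),
    roi_factor = 2.0,
    heatmap_sigma = 0.08,
    thresholds = default_thresholds(),
    escalation = as.list(default_escalation()),
    training = list(lr = 1e-4, batch_size = 8L, epochs = 10L),
    paths = list()
  ), class = "run_config")
}

check_config <- function(cfg) {
  th <- unlist(cfg$thresholds)
  if (any(th < 0 | th > 1)) stop("thresholds must lie in [0, 1]")
  esc <- unlist(cfg$escalation)
  if (any(esc < 0 | esc > 1)) stop("escalation thresholds must lie in [0, 1]")
  if (cfg$image_side < 64) stop("image_side must be at least 64")
  cfg
}

#' Load a run configuration from YAML
#'
#' Missing keys are filled with defaults; unknown keys are rejected. An
#' empty file yields the full default configuration.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
load_config <- function(path) {
  user <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop("malformed YAML in ", path, ": ", conditionMessage(e))
  })
  cfg <- default_config()
  if (length(user)) {
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
    }
    for (nm in names(user)) {
      if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
        sub_unknown <- setdiff(names(user[[nm]]), names(cfg[[nm]]))
        if (length(sub_unknown)) {
          stop(
            "unknown configuration keys: ",
            paste(paste(nm, sub_unknown, sep = "."), collapse = ", ")
          )
        }
        cfg[[nm]][names(user[[nm]])] <- user[[nm]]
      } else {
        cfg[[nm]] <- user[[nm]]
      }
    }
  }
  check_config(cfg)
}

#' Save a run configuration to YAML
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Build a dataset manifest from a phantom cohort directory
#'
#' Scans a directory written by [generate_cohort()], validates image/mask
#' pairing, joins labels from the truth table, and returns a deterministic
#' (sorted) manifest. Orphan images or masks are reported by name.
#'
#' @param data_dir Directory containing `*_mask.png`, image PNGs, and
#'   `truth.csv`.
#' @return data.frame with image path, mask path, and labels.
#' @export
build_manifest <- function(data_dir) {
  if (!dir.exists(data_dir)) stop("no such directory: ", data_dir)
  files <- sort(list.files(data_dir, pattern = "\\.png$"))
  masks <- files[grepl("_mask\\.png$", files)]
  images <- setdiff(files, masks)
  expect_mask <- sub("\\.png$", "_mask.png", images)
  missing_mask <- images[!expect_mask %in% masks]
  if (length(missing_mask)) {
    stop("images without masks: ", paste(missing_mask, collapse = ", "))
  }
  orphan_mask <- masks[!masks %in% expect_mask]
  if (length(orphan_mask)) {
    stop("masks without images: ", paste(orphan_mask, collapse = ", "))
  }
  man <- data.frame(
    image = file.path(data_dir, images),
    mask = file.path(data_dir, sub("\\.png$", "_mask.png", images))
  )
  truth_path <- file.path(data_dir, "truth.csv")
  if (file.exists(truth_path)) {
    truth <- utils::read.csv(truth_path)
    key <- match(basename(man$image), truth$image)
    man$glaucoma <- truth$glaucoma[key]
    man$dh_positive <- truth$dh_positive[key]
    man$rnfld_positive <- truth$rnfld_positive[key]
  }
  man
}
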