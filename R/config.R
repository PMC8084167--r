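#' Run configuration and defaults
#'
#' Returns the fully-resolved configuration of the training pipeline.  The
#' defaults reproduce the published full-scale setting: 224x224 bicubic
#' input, autoencoder pretrained for 10 epochs at batch size 128 with
#' Adadelta, subnetworks fine-tuned for 25 epochs (early stopping, patience
#' 5) at batch size 50 with Adam at learning rate 0.001, 33 subnetworks,
#' candidate grid 1..37 in steps of 2, five-fold cross-validation, and a
#' stratified 75/25 train/test split.  `decay_rate = NULL` leaves the
#' optimizer's own decay defaults in place (no validated published value).
#'
#' @param ... Named overrides of any default field.
#' @return A validated `randnet_config` list.
#' @examples
#' randnet_config()$n_subnetworks
#' randnet_config(input_size = 64)$input_size
#' @export
randnet_config <- function(...) {
  cfg <- list(
    paths = list(unlabeled = NULL, labeled = NULL, out = NULL),
    input_size = 224L,
    filters = c(16L, 32L, 64L, 64L, 32L),
    kernel = 3L,
    ae_epochs = 10L,
    ae_batch = 128L,
    ae_optimizer = "adadelta",
    subnet_epochs = 25L,
    subnet_batch = 50L,
    subnet_optimizer = "adam",
    learning_rate = 0.001,
    decay_rate = NULL,
    patience = 5L,
    topper_hidden = 64L,
    topper_pool = "gap",
    stacker_hidden = 64L,
    stacker_epochs = 25L,
    joint_finetune = FALSE,
    joint_epochs = 3L,
    n_subnetworks = 33L,
    grid = seq(1L, 37L, by = 2L),
    k_folds = 5L,
    split_fraction = 0.75,
    seed = 1L,
    synthetic = NULL
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1]]) &&
      is.null(names(overrides)))
    overrides <- overrides[[1]]
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  validate_config(cfg)
  structure(cfg, class = "randnet_config")
}

validate_config <- function(cfg) {
  chk_count <- function(field, min = 0L) {
    v <- cfg[[field]]
    if (!is_count(v, min))
      stopf("config field '%s' must be an integer >= %d (got %s)",
            field, min, deparse(v))
  }
  chk_count("input_size", 8L)
  if (cfg$input_size %% 8L != 0L)
    stopf("config field 'input_size' must be a multiple of 8")
  for (f in c("ae_epochs", "subnet_epochs", "stacker_epochs", "joint_epochs"))
    chk_count(f, 0L)
  for (f in c("ae_batch", "subnet_batch", "n_subnetworks", "patience",
              "topper_hidden", "stacker_hidden"))
    chk_count(f, 1L)
  chk_count("k_folds", 2L)
  if (!is.numeric(cfg$learning_rate) || cfg$learning_rate <= 0)
    stopf("config field 'learning_rate' must be positive")
  if (cfg$split_fraction <= 0 || cfg$split_fraction >= 1)
    stopf("config field 'split_fraction' must lie in (0, 1)")
  if (length(cfg$filters) != 5L || !all(vapply(cfg$filters, is_count,
                                               logical(1), min = 1L)))
    stopf("config field 'filters' must be 5 positive integers")
  if (!all(vapply(cfg$grid, is_count, logical(1), min = 1L)))
    stopf("config field 'grid' must be positive integers")
  if (!cfg$topper_pool %in% c("gap", "flatten"))
    stopf("config field 'topper_pool' must be 'gap' or 'flatten'")
  if (!is_count(abs(cfg$seed))) stopf("config field 'seed' must be an integer")
  invisible(cfg)
}

#' Desk-scale configuration
#'
#' The reduced setting used for seeded synthetic runs on a single CPU:
#' 64x64 inputs, a narrower encoder (8, 16, 32, 32, 32 filters), shortened
#' training (2 autoencoder epochs at batch 32, 10 fine-tuning epochs with
#' patience 3, 15 stacker epochs), 5 subnetworks, and a flattened (rather
#' than average-pooled) 8x8 latent block feeding the topper.  All other
#' fields keep the full-scale defaults.
#'
#' @param ... Further overrides, as in [randnet_config()].
#' @return A `randnet_config`.
#' @export
desk_config <- function(...) {
  randnet_config(input_size = 64L, filters = c(8L, 16L, 32L, 32L, 32L),
                 ae_epochs = 2L, ae_batch = 32L,
                 subnet_epochs = 10L, patience = 3L, stacker_epochs = 15L,
                 topper_pool = "flatten",
                 n_subnetworks = 5L, grid = c(1L, 3L, 5L), k_folds = 2L, ...)
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file of config fields, applies the [randnet_config()]
#' defaults for everything absent, and rejects unknown keys.  An empty file
#' yields the all-defaults configuration.
#'
#' @param path YAML file path.
#' @return A `randnet_config`.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stopf("config file must be a YAML mapping")
  if (length(raw) && is.null(names(raw)))
    stopf("config file must be a YAML mapping with named fields")
  int_fields <- c("input_size", "ae_epochs", "ae_batch", "subnet_epochs",
                  "subnet_batch", "patience", "topper_hidden",
                  "stacker_hidden", "stacker_epochs", "joint_epochs",
                  "n_subnetworks", "k_folds", "seed", "kernel")
  for (f in intersect(names(raw), int_fields)) {
    if (!is.numeric(raw[[f]]))
      stopf("config field '%s' must be numeric", f)
    raw[[f]] <- as.integer(raw[[f]])
  }
  if (!is.null(raw$filters)) raw$filters <- as.integer(raw$filters)
  if (!is.null(raw$grid)) raw$grid <- as.integer(raw$grid)
  do.call(randnet_config, raw)
}

config_hash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}
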