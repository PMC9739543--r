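#' Default pipeline configuration
#'
#' Nested list of every tunable in the pipeline with its default value.
#' The post-processing thresholds default to the standard operating point of the method:
#' objects must persist through at least 5 z-slices, move no more than 15 px
#' between consecutive slices, and keep at least 100 voxels after a
#' radius-1 opening. Tiles default to 320 x 320 px with 5% overlap
#' (stride 304). All values are user-overridable via [load_config()].
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    tiling = list(
      tile_side = 320L,
      overlap_fraction = 0.05
    ),
    model = list(
      down_filters = c(10L, 20L, 30L),
      kernel = 5L,
      stride = 2L,
      n_classes = 2L,
      threshold = 0.5
    ),
    training = list(
      train_fraction = 0.90,
      augment_fraction = 0.50,
      batch_size = 8L,
      learning_rate = 1e-3,
      max_epochs = 30L,
      patience = 3L,
      w0 = 10,
      sigma = 5,
      class_weights = c(background = 1, bleb = 5)
    ),
    postprocess = list(
      min_slices = 5L,
      max_shift = 15,
      min_size = 100L,
      opening_radius = 1L,
      connectivity = 26L
    ),
    scene = list(
      shape = c(20L, 128L, 128L),
      n_axons = 10L,
      axon_intensity = c(90, 130),
      n_blebs = 6L,
      bleb_intensity = c(150, 230),
      bleb_radius = c(4, 6),
      bleb_span = c(6, 10),
      n_travel = 3L,
      travel_shift = 20,
      travel_radius = 4,
      n_specks = 10L,
      speck_size = c(2L, 8L),
      background = c(mean = 40, sd = 8)
    )
  )
}

#' Load a pipeline configuration from YAML
#'
#' Reads a flat-or-nested YAML file and merges it over [default_config()].
#' Every overridden key is echoed to the log so runs are auditable.
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  assert_that(file.exists(path), "no such config file: %s", path)
  user <- yaml::read_yaml(path)
  merge_cfg <- function(base, over, prefix = "") {
    for (key in names(over)) {
      full <- if (nzchar(prefix)) paste0(prefix, ".", key) else key
      if (is.list(over[[key]]) && is.list(base[[key]])) {
        base[[key]] <- merge_cfg(base[[key]], over[[key]], full)
      } else {
        bk_log("config override: %s = %s", full,
               paste(unlist(over[[key]]), collapse = ", "))
        base[[key]] <- over[[key]]
      }
    }
    base
  }
  validate_config(merge_cfg(cfg, user))
}

validate_config <- function(cfg) {
  pp <- cfg$postprocess
  assert_that(pp$min_slices >= 1, "min_slices must be >= 1")
  assert_that(pp$max_shift >= 0, "max_shift must be >= 0")
  assert_that(pp$min_size >= 1, "min_size must be >= 1")
  assert_that(cfg$tiling$tile_side >= 1, "tile_side must be >= 1")
  assert_that(cfg$tiling$overlap_fraction >= 0 && cfg$tiling$overlap_fraction < 1,
              "overlap_fraction must be in [0, 1)")
  tr <- cfg$training
  assert_that(tr$train_fraction > 0 && tr$train_fraction < 1,
              "train_fraction must be in (0, 1)")
  assert_that(tr$patience >= 1, "patience must be >= 1")
  cfg
}
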