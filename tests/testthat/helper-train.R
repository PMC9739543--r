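# Trained-network fixture, built once per test session and memoized:
# several acceptance properties (training improvement, end-to-end recovery)
# share the same fit so the suite trains only once.

.train_cache <- new.env(parent = emptyenv())

training_scene_tiles <- function(seeds, per_scene = 40L, side = 48L) {
  out <- list()
  for (s in seeds) {
    sc <- generate_scene(scene_spec(shape = c(12L, 96L, 96L), n_axons = 8L,
                                    n_blebs = 5L, n_specks = 4L, seed = s))
    tiles <- stack_tiles(sc$stack, sc$mask, side)
    fg <- vapply(tiles, function(t) sum(t$mask), numeric(1))
    keep <- order(-fg)[seq_len(min(per_scene, length(tiles)))]
    out <- c(out, tiles[keep])
  }
  out
}

cached_training_run <- function() {
  if (!is.null(.train_cache$fit)) return(.train_cache$fit)
  dataset <- training_scene_tiles(1:5, 40L)
  net <- build_network(architecture_spec(), seed = 7L)
  fit <- train_network(net, dataset, list(max_epochs = 10L, batch_size = 10L,
                                          learning_rate = 2e-3, seed = 11L))
  fit$n_tiles <- length(dataset)
  .train_cache$fit <- fit
  fit
}

# held-out scene with all object classes, plus its qualifying-bleb reference
evaluation_scene <- function(seed) {
  sc <- generate_scene(scene_spec(shape = c(14L, 128L, 128L), n_axons = 8L,
                                  n_blebs = 6L, n_travel = 2L, n_specks = 6L,
                                  n_sub_span_blebs = 1L, seed = seed))
  qual_ids <- sc$catalog$id[sc$catalog$qualifies_as_bleb]
  ref_mask <- array(0, dim(sc$labels))
  ref_mask[sc$labels %in% qual_ids] <- 1
  list(scene = sc, ref_objects = assemble_objects(ref_mask),
       n_qualifying = length(qual_ids))
}
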