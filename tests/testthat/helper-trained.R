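# One tiny model trained on the synthetic study conditions, shared across
# test files (training runs once per session, on first use).

.trained_cache <- new.env()

trained_tiny_model <- function() {
  if (!is.null(.trained_cache$fit)) return(.trained_cache$fit)
  d <- generate_fixture("tiny", n_per_class = 100L, seed = 7L)
  tr <- dataset_split(d, "train")
  va <- dataset_split(d, "val")
  te <- dataset_split(d, "test")
  m <- ect_bofm_tiny(n_classes = 3L, seed = 1L)
  fit <- train_model(m, tr, val = va, epochs = 20L, optimizer = "psam",
                     seed = 1L, augment = TRUE)
  .trained_cache$fit <- list(model = fit$model, history = fit$history,
                             train = tr, val = va, test = te, data = d)
  .trained_cache$fit
}

# overall-heatmap window rankings of the shared model's test images
trained_tiny_rankings <- function() {
  if (!is.null(.trained_cache$rankings)) return(.trained_cache$rankings)
  fit <- trained_tiny_model()
  .trained_cache$rankings <- lapply(fit$test$images, function(img) {
    hm <- heatmaps(fit$model, img)
    rank_windows(hm$overall, 9L, 8L)
  })
  .trained_cache$rankings
}
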