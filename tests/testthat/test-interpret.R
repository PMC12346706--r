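test_that("alpha weights partition the rectified classifier mass", {
  al <- alpha_weights(rep(2, 10))
  expect_equal(al$alpha_cti, 0.5)
  expect_equal(al$alpha_ei, 0.5)
  set.seed(14)
  for (i in 1:100) {
    w <- rnorm(16)
    if (all(pmax(w, 0) == 0)) next
    al <- alpha_weights(w)
    expect_equal(al$alpha_cti + al$alpha_ei, 1, tolerance = 1e-12)
  }
  al <- alpha_weights(c(rep(0, 5), runif(5) + 0.1))
  expect_equal(al$alpha_cti, 0)
  expect_equal(al$alpha_ei, 1)
  expect_warning(al <- alpha_weights(rep(-1, 8)), "equal shares")
  expect_equal(c(al$alpha_cti, al$alpha_ei), c(0.5, 0.5))
  expect_error(alpha_weights(rep(1, 7)), "halves")
})

test_that("stride-1 per-patch scores cover every pixel and decompose the logit", {
  m <- ect_bofm_tiny(n_classes = 3, seed = 21)
  img <- rand_image(57, seed = 50)
  sc <- per_patch_scores(m, img, k = 2L)
  expect_identical(dim(sc$logit), c(57L, 57L))
  expect_true(all(is.finite(sc$logit)))
  expect_true(all(sc$a_cti > 0 & sc$a_cti < 1))
  expect_true(all(sc$a_ei > 0 & sc$a_ei < 1))
  expect_error(per_patch_scores(m, img, k = 9L), "range")
  # grid-aligned positions (offset pad = 4, stride 8) average to the logit
  cc <- dermbag:::ect_forward(m, list(img), with_decoders = FALSE)
  aligned <- 4L + 8L * (0:6) + 1L
  expect_equal(mean(sc$logit[aligned, aligned]), cc$logits[1, 2],
               tolerance = 1e-4)
})

test_that("windowed scoring equals explicit patch extraction (padding contract)", {
  m <- ect_bofm_tiny(n_classes = 3, seed = 22)
  set.seed(60)
  for (rep in 1:2) {
    img <- rand_image(57)
    sc <- per_patch_scores(m, img, k = 1L)
    pos <- rbind(c(1L, 1L), c(1L, 57L), c(57L, 29L),
                 cbind(sample(57, 4), sample(57, 4)))
    ex <- per_patch_scores_explicit(m, img, k = 1L, positions = pos)
    for (i in seq_len(nrow(pos))) {
      r <- pos[i, 1]; cl <- pos[i, 2]
      expect_equal(ex$logit[r, cl], sc$logit[r, cl], tolerance = 1e-8)
      expect_equal(ex$a_ei[r, cl], sc$a_ei[r, cl], tolerance = 1e-8)
    }
  }
})

test_that("heatmaps obey the min-max contract and the convex combination", {
  m <- ect_bofm_tiny(n_classes = 3, seed = 23)
  img <- rand_image(57, seed = 70)
  hm <- heatmaps(m, img)
  for (nm in c("cti", "ei", "overall")) {
    expect_identical(dim(hm[[nm]]), c(57L, 57L))
    expect_equal(min(hm[[nm]]), 0)
    expect_equal(max(hm[[nm]]), 1)
  }
  expect_equal(hm$raw$overall,
               hm$alpha_cti * hm$raw$cti + hm$alpha_ei * hm$raw$ei,
               tolerance = 1e-12)
  expect_true(hm$k %in% 1:3)
  # determinism
  hm2 <- heatmaps(m, img)
  expect_identical(hm$overall, hm2$overall)
})

test_that("constant raw heatmaps normalize to zero with a warning", {
  m <- ect_bofm_tiny(n_classes = 3, seed = 24)
  # constant per-patch logit (zero classifier weights) and constant gates
  m$cls$W <- m$cls$W * 0
  for (nm in c("gate_cti_c1", "gate_cti_c2", "gate_ei_c1", "gate_ei_c2")) {
    m[[nm]]$W <- m[[nm]]$W * 0
    m[[nm]]$b <- m[[nm]]$b * 0
  }
  img <- rand_image(57, seed = 71)
  w <- capture_warnings(hm <- heatmaps(m, img, k = 1L))
  expect_true(any(grepl("constant raw heatmap", w)))
  expect_true(all(hm$cti == 0))
})

test_that("heatmap export writes images, raw scores, and the sidecar", {
  m <- ect_bofm_tiny(n_classes = 3, seed = 25)
  img <- rand_image(57, seed = 72)
  hm <- heatmaps(m, img)
  dir <- file.path(tempdir(), "hm_out")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  write_heatmaps(hm, dir)
  expect_true(all(file.exists(file.path(dir,
    c("cti.png", "ei.png", "overall.png", "overall_raw.csv",
      "heatmaps.json")))))
  side <- jsonlite::read_json(file.path(dir, "heatmaps.json"))
  expect_equal(side$alpha_cti + side$alpha_ei, 1, tolerance = 1e-9)
})
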