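# Model harness: census conformance, width scaling, end-to-end features,
# dataset round-trip.

reference_counts <- c(
  sagittal_3d_encoder_1 = 1216, sagittal_3d_encoder_2 = 73856,
  sagittal_3d_encoder_3 = 295168,
  axial_3d_encoder_1 = 1216, axial_3d_encoder_2 = 73856,
  axial_3d_encoder_3 = 295168,
  coronal_3d_encoder_1 = 1216, coronal_3d_encoder_2 = 73856,
  coronal_3d_encoder_3 = 295168,
  hpmrs_2d_encoder_1 = 80, hpmrs_2d_encoder_2 = 1168,
  time_elapsed_attention_1 = 786432, time_elapsed_attention_2 = 786432,
  time_elapsed_attention_3 = 786432,
  classification_1 = 1770240, hp_rnn = 52480, nmr_rnn = 180,
  classification_2 = 1818)

test_that("the full-width census reproduces every reference layer count", {
  cen <- model_census(model_config(width_scale = 1))
  got <- setNames(cen$params, cen$layer)
  for (nm in names(reference_counts))
    expect_identical(unname(got[nm]), as.integer(reference_counts[[nm]]))
  # every attention unit counts 4 d^2
  expect_true(all(got[grepl("_attention$", names(got))] == 262144L))
})

test_that("width scaling shrinks every layer and the census total is additive", {
  c1 <- model_census(model_config(width_scale = 1))
  c8 <- model_census(model_config(width_scale = 1/8))
  both <- merge(c1, c8, by = "layer")
  shrunk <- both$layer != "nmr_rnn"           # panel width is pinned at 9
  expect_true(all(both$params.y[shrunk] < both$params.x[shrunk]))
  expect_identical(sum(c8$params), sum(as.integer(c8$params)))
  m <- tiny_model()
  expect_identical(m$census, c8)
  expect_error(model_config(width_scale = 0), "width_scale")
})

test_that("feature extraction yields the configured layout and ablations zero blocks", {
  fx <- bench_fixture()
  m <- tiny_model()
  X <- model_features(fx$cohort[1:4] |>
                        structure(class = "tefuse_cohort",
                                  config = attr(fx$cohort, "config"),
                                  rendered = TRUE),
                      m, structure(fx$encoding[1:4],
                                   days = attr(fx$encoding, "days"),
                                   class = "tefuse_encoding"),
                      feature_days = c(8, 11, 14),
                      table = nmr_cohort_table(fx$cohort))
  b <- attr(X, "blocks")
  expect_identical(unname(b), c(m$config$fused_width, m$config$hp_rnn$hidden, 9L, 3L))
  expect_identical(ncol(X), as.integer(sum(b)))
  # HPMRS-only ablation: all non-HPMRS blocks zero, HPMRS block active
  Xh <- model_features(structure(fx$cohort[1:4], class = "tefuse_cohort",
                                 config = attr(fx$cohort, "config"),
                                 rendered = TRUE),
                       m, structure(fx$encoding[1:4],
                                    days = attr(fx$encoding, "days"),
                                    class = "tefuse_encoding"),
                       feature_days = c(8, 11, 14), modalities = "hpmrs",
                       table = nmr_cohort_table(fx$cohort))
  expect_true(all(Xh[, seq_len(b["fused"])] == 0))
  expect_true(any(Xh[, b["fused"] + seq_len(b["hp"])] != 0))
  expect_true(all(Xh[, (b["fused"] + b["hp"] + 1):ncol(Xh)] == 0))
})

test_that("a cohort written to disk reads back value-identical", {
  coh <- small_rendered()
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort(dir)
  expect_length(back, length(coh))
  for (i in seq_along(coh)) {
    expect_identical(back[[i]]$mouse_id, coh[[i]]$mouse_id)
    expect_identical(back[[i]]$cohort, coh[[i]]$cohort)
    expect_equal(back[[i]]$volumes, coh[[i]]$volumes, tolerance = 1e-6)
    expect_equal(back[[i]]$nmr[[1]]$values, coh[[i]]$nmr[[1]]$values,
                 tolerance = 1e-12)
    expect_identical(back[[i]]$nmr[[1]]$observed, coh[[i]]$nmr[[1]]$observed)
    d <- as.character(coh[[i]]$plane_days[1])
    expect_equal(back[[i]]$planes[[d]]$axial, coh[[i]]$planes[[d]]$axial,
                 tolerance = 1e-6)
    expect_equal(back[[i]]$hpmrs[[d]], coh[[i]]$hpmrs[[d]], tolerance = 1e-12)
  }
})
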